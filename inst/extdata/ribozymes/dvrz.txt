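# Delta (hepatitis-delta-virus family) ribozyme (DVRz), simplified
# descriptor. GC-rich conserved core around the catalytic cytosine with
# three of the nested helices of the delta fold (the pseudoknot cannot be
# expressed in this flat format). Approximation, editable; not a
# covariance model.
class DVRz
min_score 0.7
element coreC segment GGGCAUC 1,1,1,0.5,1,1,1
element P1o   helix  P1 6 7
element L1    spacer 3 6
element P1c   helix  P1 6 7
element coreJ segment CUUCGGGUCGGC 1,1,0.2,1,1,1,1,1,1,0.2,1,1
element P2o   helix  P2 6 7
element L2    spacer 3 6
element P2c   helix  P2 6 7
element S1    spacer 2 4
element P3o   helix  P3 6 7
element L3    spacer 3 6
element P3c   helix  P3 6 7
cleavage coreC 0
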