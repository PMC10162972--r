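# Twister ribozyme (TWRz, P1 architecture), simplified descriptor.
# Conserved T-loop-like segments and three stems of the twister fold.
# Approximation of the class consensus, editable; not a covariance model.
class TWRz
min_score 0.7
element coreT1 segment UAACUAG 1,1,1,0.5,1,1,0.2
element P1o    helix  P1 6 7
element L1     spacer 3 6
element P1c    helix  P1 6 7
element coreT2 segment GGUAUACCAGCC 1,1,1,0.2,1,1,1,1,1,0.5,1,1
element P2o    helix  P2 6 7
element L2     spacer 3 6
element P2c    helix  P2 6 7
element S1     spacer 2 4
element P4o    helix  P4 6 7
element L4     spacer 3 6
element P4c    helix  P4 6 7
cleavage coreT1 2
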