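# Hammerhead ribozyme (HHRz), simplified descriptor.
# Conserved catalytic boxes (CUGAUGA / GAAA-C) flanked by the three helical
# stems of the minimal hammerhead fold. Approximation of the class
# consensus, editable; not a covariance model.
class HHRz
min_score 0.7
element core1 segment CUGAUGA 1,1,1,1,0.2,1,1
element H2o   helix  H2 6 7
element L2    spacer 3 6
element H2c   helix  H2 6 7
element core2 segment GAAAC 1,1,1,1,0.5
element H1o   helix  H1 6 7
element L1    spacer 3 6
element H1c   helix  H1 6 7
element S1    spacer 2 4
element H3o   helix  H3 6 7
element L3    spacer 3 6
element H3c   helix  H3 6 7
cleavage core2 4
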