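# Varkud satellite ribozyme (VSRz), simplified descriptor.
# The VS ribozyme is the largest of the five classes, built almost
# entirely of helices; conserved A730-loop-like and cleavage-loop segments
# with three stems. Approximation, editable; not a covariance model.
class VSRz
min_score 0.7
element loopC segment GACUUAG 1,1,1,1,0.5,1,0.2
element H2o   helix  H2 6 7
element L2    spacer 3 6
element H2c   helix  H2 6 7
element loopA segment AGUCAGUUGACA 1,1,1,0.2,1,1,1,1,0.5,1,1,1
element H3o   helix  H3 6 7
element L3    spacer 3 6
element H3c   helix  H3 6 7
element S1    spacer 2 4
element H6o   helix  H6 6 7
element L6    spacer 3 6
element H6c   helix  H6 6 7
cleavage loopA 1
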