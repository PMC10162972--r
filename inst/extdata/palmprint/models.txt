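# RdRp palmprint motif models (A, B, C).
#
# These are simplified, editable position-weight models built around the
# canonical catalytic residues of the RdRp palm domain (the aspartates of
# motifs A and C and the glycine anchor of motif B). They are derived
# approximations for descriptor-style matching, not published consensus
# matrices; replace this file to use your own models.
#
# Format:
#   gap <from> <to> <min_aa> <max_aa>   inter-motif gap bounds (end->start)
#   motif <name> ... end                one block per motif
#     min_score <fraction>              fraction of attainable weight
#     pos AA:weight [AA:weight ...]     one line per motif position;
#                                       unlisted residues score 0

gap A B 15 40
gap B C 10 30

motif A
min_score 0.8
pos D:3
pos Y:2 F:2
pos S:1 T:1 K:1
pos K:1 R:1 Q:1
pos W:2 F:1
pos D:3
end

motif B
min_score 0.8
pos S:2 T:1
pos G:3
pos Q:1 N:1 E:1
pos P:1 A:1 S:1
pos E:1 D:1 K:1
pos T:2 S:1
end

motif C
min_score 0.8
pos S:1 G:1 N:1
pos G:3
pos D:3
pos D:3
end
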