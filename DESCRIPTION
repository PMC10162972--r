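Package: viroidscan
Title: Discovery of Viroid-Like Circular RNA Elements in Assembled Contigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering viroid-like circular RNA
    elements and RdRp-encoding circular hybrids (ambivirus- and
    mitovirus-like) from assembled nucleotide contigs. Detects circular
    molecules from terminal repeats, scans both polarities for self-cleaving
    ribozyme motifs of five classes (hammerhead, hairpin, delta, twister,
    Varkud satellite), filters repetitive candidates, clusters circular
    sequences into species-like operational taxonomic units with a rotation-
    and strand-invariant identity, detects RdRp palmprint motifs A/B/C in
    ambisense open reading frames, and classifies genome secondary
    structures as rod-like or branched. Ships a seeded synthetic-data
    generator with planted ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
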