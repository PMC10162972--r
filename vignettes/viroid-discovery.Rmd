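---
title: "Discovering viroid-like circular RNAs in assembled contigs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering viroid-like circular RNAs in assembled contigs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viroidscan)
```

## The biological problem

Viroids, viroid-like satellite RNAs, and related agents (deltavirus-like
and ambivirus-like elements) are covalently closed circular RNAs that
replicate through a rolling-circle mechanism. Their hallmarks in
sequence data are:

1. **Assembly circularity.** A rolling-circle template assembled by a
   linear assembler comes out as a monomer (or multimer) whose start is
   repeated at its end — a *terminal repeat*.
2. **Paired ambisense self-cleaving ribozymes.** Rolling-circle
   replication of both polarities requires a self-cleavage site on each
   strand. Finding a ribozyme motif on the plus strand *and* one on the
   minus strand of the same circle is the key biological filter.
3. **Low repetitiveness.** Tandem arrays and dispersed repeats produce
   spurious assembly circularity; genuine agents are sequence-diverse.
4. Optionally, an RdRp-like open reading frame whose protein carries the
   ordered palmprint motifs A, B, C, and a rod-like predicted secondary
   structure in the viroid-sized class.

`viroidscan` implements this discovery pipeline end to end on assembled
contigs, plus a seeded synthetic data generator with planted ground
truth for validating every stage.

## Pipeline stages and parameter rationale

### Circularity (`detect_circles`)

For each contig the largest terminal repeat `r` with
`k_min <= r <= floor(L / 2)` is found (exact matching by default;
`max_mismatch` relaxes it). `k_min = 20` makes a chance terminal match
on random sequence vanishingly unlikely (`4^-20`), while staying well
below the shortest genuine overlaps produced by assemblers. Concatemers
are reduced to the monomer via the smallest period of the de-duplicated
sequence, and every monomer is reported in a canonical rotation (the
lexicographically least rotation, by default taken over both strands) so
downstream results do not depend on the arbitrary assembly start.

### Ribozyme scanning and ambisense pairing

Ribozyme classes (HHRz, HPRz, DVRz, TWRz, VSRz) are described by
plain-text motif descriptors: conserved sequence segments with
per-position weights, helices that must close by Watson-Crick or G·U
pairing, and length-flexible spacers. Each segment — and the complete
placement — must reach the descriptor's `min_score` (0.7): requiring
every segment to clear the threshold individually is stricter than a
total-only rule and suppresses placements that ace one box while
degrading another. Scanning happens on the doubled monomer so motifs
spanning the origin are found, and minus-strand hits are mapped back to
plus-strand coordinates. These descriptors are deliberately lightweight
approximations of covariance models; hits from an external
covariance-model search can be ingested with `load_cm_hits()` and fed to
the same pairing logic.

Note that a descriptor whose first or last element is a
length-flexible spacer admits several equally scoring placements that
differ by a few nucleotides at the ends; the cleavage site, anchored to
a conserved segment, is the coordinate that is stable.

`find_ambisense_pairs()` keeps the best hit per polarity (score, then
leftmost) and requires one on each strand. Mixed-class pairs are
reported with an alphabetically sorted combination label;
`same_class_only = TRUE` restricts to same-class pairs.

### Repetitiveness filter

Three masks are computed on the doubled monomer and unioned modulo the
monomer length: a dust-style triplet-composition mask (window 64,
threshold 2.0, slid one position at a time so the mask is exactly
rotation-invariant), exact-period tandem runs (period ≤ 10, ≥ 3 copies,
≥ 24 nt), and dispersed self-repeats on both strands (12-mer seeded,
extended to ≥ 30 nt exact matches). Monomers with ≥ 25% of positions
masked are rejected: genuine viroid-like genomes are sequence-diverse,
whereas tandem arrays readily produce artifactual terminal repeats.

### Rotation- and strand-invariant clustering

Monomers are compared by a glocal alignment of one monomer against the
doubled other (match +1, mismatch −1, gap open 2, extend 1; identity =
matches / aligned pattern columns), maximized over strands. For
substitution-diverged rotation/strand images of a common ancestor —
the regime the 90% species-level threshold operates in — this score is
exactly the maximum identity over all rotations (the package also ships
`circular_identity_brute()`, the explicit rotation-enumeration oracle,
for verification). On unrelated sequence pairs the glocal alignment may
score somewhat above the best rotation, but both remain far below the
0.90 decision threshold, so cluster assignments are unaffected. Greedy
centroid clustering (longest first, ties by id; inclusive threshold)
yields the sequence-based operational taxonomic units (sOTUs). The same
machinery clusters palmprint proteins with a plain global alignment
(`mode = "linear-aa"`).

### ORFs and palmprints

ORFs (≥ 100 aa, stop-to-stop by default) are called in all six frames of
the doubled monomer so origin-spanning genes are recovered, then
de-duplicated modulo the monomer length. The palmprint caller places
motifs A, B and C in order, each above its own `min_score` (0.8), with
gap ranges A→B of 15–40 aa and B→C of 10–30 aa, and reports the A–C
span. The shipped motif models are didactic toys sized for synthetic
benchmarks; drop in real profiles via `read_palm_models()`.

### Fold architecture

`nussinov_fold()` (exact base-pair maximization, minimum loop 3, WC and
G·U pairs, deterministic traceback) provides structures for monomers up
to `fold_max_length` (800 nt in the pipeline; cap 1500 nt — beyond
that, supply structures from a thermodynamic folder). `classify_fold()`
reduces a structure to its helix tree: a single unbranched backbone is a
**rod**; if removing side hairpins of ≤ 30 nt attached at *internal*
loops leaves a single backbone, it is a **quasi-rod**; anything else —
including several small hairpins hanging off the exterior loop, which
are never pruned — is **branched**. Circular molecules count one extra
terminal loop for the closed exterior. One caveat: classification is
applied to the canonical rotation; a rod whose arbitrary linearization
cuts mid-arm can legitimately fold into a branched-looking layout, so
designed-structure checks pin the rotation.

### Size classes

Monomer lengths map to half-open bands chosen around the known agent
families: below-min (< 200), small (200–800, classical
viroid/satellite sizes), medium (800–1200), medium-large (1200–2200,
deltavirus-like), large (2200–4000, mitovirus-like), very-large
(≥ 4000, ambivirus-like).

## Synthetic data with planted truth

`make_dataset()` generates, under a single seed, a byte-reproducible
contig set: by default 50 true circles (ambisense ribozyme pairs;
lengths drawn across the size bands; larger genomes carry a
palmprint ORF), 20 linear decoys, 15 circles with a ribozyme on only
one polarity, and 15 circles that are > 30% tandem-repetitive. The
truth table records each monomer, rotation, terminal-repeat length,
copy number, planted motif classes and positions, ORF/palmprint, and
the expected pipeline outcome.

Two design notes. Mutations are substitution-only, which is exactly the
regime where the clustering identity is provably rotation-exact.
Rod-biased backgrounds (`rod_bias = TRUE` in `make_circular_genome()`)
are by construction one long inverted self-repeat and therefore trip the
dispersed-repeat mask — so the default dataset uses uniform backgrounds,
and rod-architecture behavior is validated on dedicated constructions.

## Running the pipeline

```r
ds  <- make_dataset(seed = 42)
res <- run_pipeline(ds$contigs)
table(res$records$status)
res$summary$combo
```

`res$records` holds one row per contig with the stage-by-stage
annotations and a final status (`candidate` or the first failing stage);
`res$summary` tabulates ribozyme combinations, size classes, coding
fraction and fold classes over one representative per sOTU.

## Practical limits

All stages are pure R (plus a small compiled folding kernel) and are
sized for contig sets of hundreds of sequences and monomers up to a few
kilobases. The folding kernel is cubic in length; clustering is
quadratic in the number of candidates. For assembler-scale surveys,
run circularity and repeat filtering first (they are linear-ish and
prune most input), and consider external covariance-model scans via
`load_cm_hits()` for sensitivity beyond the shipped descriptors.
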