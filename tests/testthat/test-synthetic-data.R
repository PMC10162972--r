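test_that("dataset generation is byte-identical under a fixed seed", {
  a <- make_dataset(spec = list(n_true = 3L, n_linear = 2L, n_single_rz = 1L,
                                n_repetitive = 1L), seed = 101L)
  b <- make_dataset(spec = list(n_true = 3L, n_linear = 2L, n_single_rz = 1L,
                                n_repetitive = 1L), seed = 101L)
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$truth, b$truth)
  c <- make_dataset(spec = list(n_true = 3L, n_linear = 2L, n_single_rz = 1L,
                                n_repetitive = 1L), seed = 102L)
  expect_false(identical(a$contigs$sequence, c$contigs$sequence))
})

test_that("the default composition has the documented counts and labels", {
  ds <- default_dataset()
  expect_equal(nrow(ds$contigs), 100L)
  expect_equal(nrow(ds$truth), 100L)
  expect_equal(sum(ds$truth$kind == "true_circle"), 50L)
  expect_equal(sum(ds$truth$kind == "linear_decoy"), 20L)
  expect_equal(sum(ds$truth$kind == "single_ribozyme"), 15L)
  expect_equal(sum(ds$truth$kind == "repetitive"), 15L)
  expect_setequal(unique(ds$truth$expected),
                  c("candidate", "rejected:not_circular",
                    "rejected:no_ribozyme_pair", "rejected:repetitive"))
  expect_equal(ds$contigs$id, ds$truth$id)
})

test_that("planted contigs round-trip through circularity detection", {
  g <- make_circular_genome(700, "HHRz", "DVRz", seed = 103)
  ctg <- make_contig(g$monomer, rotation = 250, r = 64, id = "rt")
  circ <- detect_circles(ctg)
  expect_equal(nrow(circ), 1L)
  expect_equal(circ$repeat_length, 64L)
  expect_equal(circ$monomer_length, 700L)
  expect_equal(canonical_rotation(circ$monomer, strand_insensitive = TRUE),
               canonical_rotation(g$monomer, strand_insensitive = TRUE))
})

test_that("concatemers are reduced to single-copy monomers", {
  g <- make_circular_genome(400, "TWRz", "TWRz", seed = 104)
  ctg <- make_contig(g$monomer, rotation = 10, r = 30, copies = 2, id = "cc")
  circ <- detect_circles(ctg)
  expect_equal(circ$copy_number, 2L)
  expect_equal(circ$monomer_length, 400L)
})

test_that("mutated contigs are recovered in mismatch-tolerant mode", {
  g <- make_circular_genome(600, "HPRz", "HHRz", seed = 105)
  ctg <- make_contig(g$monomer, rotation = 90, r = 80,
                     substitution_rate = 0.02, id = "mt", seed = 106)
  tol <- detect_circles(ctg, max_mismatch = 4L)
  expect_equal(nrow(tol), 1L)
  expect_equal(tol$repeat_length, 80L)
})

test_that("planted ribozyme truth matches the scanner output", {
  g <- make_circular_genome(800, "VSRz", "HHRz", seed = 107)
  circ <- tibble::tibble(id = "g", monomer = g$monomer, monomer_length = 800L)
  hits <- scan_ribozymes(circ, load_descriptors())
  plus <- hits[hits$strand == "+", ]
  minus <- hits[hits$strand == "-", ]
  # flexible terminal spacers allow equally-scoring placements shifted by
  # a few nt, so the segment-anchored cleavage site is the exact invariant
  expect_true(any(plus$class == "VSRz" &
                    plus$cleavage_site == g$truth$rz_plus$cleavage))
  expect_true(any(minus$class == "HHRz" &
                    minus$cleavage_site == g$truth$rz_minus$cleavage))
  expect_true(any(abs(plus$start - g$truth$rz_plus$start) <= 5 &
                    plus$class == "VSRz"))
})

test_that("infeasible packing and invalid contig parameters raise errors", {
  expect_error(make_circular_genome(100, "HHRz", "HHRz", seed = 108),
               "infeasible packing")
  expect_error(make_contig("ACGTACGTAC", r = 11L), "terminal repeat")
  expect_error(make_contig("ACGTACGTAC", r = 0L), "terminal repeat")
  expect_error(make_contig("ACGTACGTAC", r = 4L, copies = 0L), "copies")
})

test_that("decoy groups can be switched off", {
  ds <- make_dataset(spec = list(n_true = 2L, n_linear = 0L, n_single_rz = 0L,
                                 n_repetitive = 0L), seed = 109L)
  expect_equal(nrow(ds$contigs), 2L)
  expect_true(all(ds$truth$expected == "candidate"))
})

test_that("repetitive decoys carry at least a 30% repeat fraction and true circles do not", {
  ds <- default_dataset()
  rep_ids <- ds$truth$id[ds$truth$kind == "repetitive"]
  withr::with_seed(110, sample_true <- sample(ds$truth$id[ds$truth$kind == "true_circle"], 5))
  for (id in rep_ids[1:5]) {
    mono <- ds$truth$monomer[ds$truth$id == id]
    expect_gte(apply_repeat_filter(mono)$masked_fraction, 0.30)
  }
  for (id in sample_true) {
    mono <- ds$truth$monomer[ds$truth$id == id]
    expect_lt(apply_repeat_filter(mono)$masked_fraction, 0.25)
  }
})

test_that("planted ORFs translate cleanly and contain the palmprint", {
  ds <- default_dataset()
  coding <- ds$truth[which(ds$truth$has_orf), ]
  if (nrow(coding)) {
    row <- coding[1, ]
    expect_false(grepl("\\*", row$palmprint))
    orfs <- find_orfs_circular(row$monomer, min_aa = 100)
    expect_true(any(grepl(row$palmprint, orfs$aa, fixed = TRUE)))
  }
  g <- make_circular_genome(2500, "HHRz", "HHRz", with_orf = TRUE, seed = 111)
  expect_equal((g$truth$orf$end - g$truth$orf$start) %% 3L, 0L)
  expect_true(grepl(g$truth$orf$palmprint, g$truth$orf$aa, fixed = TRUE))
})
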