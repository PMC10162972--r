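models <- load_palm_models()
consensus_of <- function(m) {
  paste(vapply(m$weights, function(w) names(w)[which.max(w)], ""), collapse = "")
}
A <- consensus_of(models$motifs$A)
B <- consensus_of(models$motifs$B)
C <- consensus_of(models$motifs$C)
aa_filler <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("E", "F", "H", "I", "K", "L", "P",
                                        "Q", "R", "V", "W", "Y"), n,
                                      replace = TRUE), collapse = ""))
}

test_that("an ordered A-B-C protein yields a palmprint with the exact span", {
  prot <- paste0(aa_filler(40, 61), A, aa_filler(20, 62), B, aa_filler(15, 63),
                 C, aa_filler(40, 64))
  hit <- detect_palmprint(prot, models)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$a_start, 40L)
  expect_equal(hit$c_end, 40L + nchar(A) + 20L + nchar(B) + 15L + nchar(C))
  expect_equal(hit$palmprint, substr(prot, hit$a_start + 1, hit$c_end))
  expect_equal(hit$total_score, 3)
})

test_that("motif order violations are rejected", {
  prot <- paste0(aa_filler(40, 65), C, aa_filler(20, 66), B, aa_filler(15, 67),
                 A, aa_filler(40, 68))
  expect_equal(nrow(detect_palmprint(prot, models)), 0L)
})

test_that("gap-bound violations are rejected", {
  prot <- paste0(aa_filler(40, 69), A, aa_filler(20, 70), B, aa_filler(60, 71),
                 C, aa_filler(40, 72))
  expect_equal(nrow(detect_palmprint(prot, models)), 0L)
})

test_that("a substitution pushing a motif below min_score removes the hit", {
  a_bad <- paste0("L", substr(A, 2, nchar(A)))   # catalytic D lost
  prot <- paste0(aa_filler(40, 73), a_bad, aa_filler(20, 74), B, aa_filler(15, 75),
                 C, aa_filler(40, 76))
  expect_equal(nrow(detect_palmprint(prot, models)), 0L)
  # a low-weight substitution keeps the hit
  a_ok <- A
  substr(a_ok, 3, 3) <- "L"
  prot2 <- paste0(aa_filler(40, 73), a_ok, aa_filler(20, 74), B, aa_filler(15, 75),
                  C, aa_filler(40, 76))
  hit <- detect_palmprint(prot2, models)
  expect_equal(nrow(hit), 1L)
  expect_lt(hit$score_a, 1)
  expect_gte(hit$score_a, models$motifs$A$min_score)
})

test_that("ORFs are found across the circular origin with exact protein sequence", {
  g <- make_circular_genome(1500, with_orf = TRUE, seed = 81)
  rot <- rotate(g$monomer, (g$truth$orf$start + g$truth$orf$end) %/% 2)
  orfs <- find_orfs_circular(rot, min_aa = 100)
  expect_true(g$truth$orf$aa %in% orfs$aa)
  w <- which(orfs$aa == g$truth$orf$aa)
  expect_true(orfs$wraps_origin[w])
  expect_equal(orfs$end[w] - orfs$start[w], 3L * nchar(g$truth$orf$aa))
})

test_that("ORFs are reported once per circle and on both strands", {
  g <- make_circular_genome(1500, with_orf = TRUE, seed = 82)
  plus <- find_orfs_circular(g$monomer, min_aa = 100)
  minus <- find_orfs_circular(revcomp(g$monomer), min_aa = 100)
  expect_equal(sum(plus$aa == g$truth$orf$aa), 1L)
  w <- which(minus$aa == g$truth$orf$aa)
  expect_equal(minus$strand[w], "-")
  expect_equal(anyDuplicated(paste(plus$strand, plus$start, plus$aa_length)), 0L)
})

test_that("short monomers yield no ORFs at the length cutoff", {
  expect_equal(nrow(find_orfs_circular(rand_dna(90, seed = 83), min_aa = 100)), 0L)
})

test_that("palmprint detection is rotation-invariant", {
  g <- make_circular_genome(1600, with_orf = TRUE, seed = 84)
  h0 <- detect_palmprints(find_orfs_circular(g$monomer, min_aa = 100), models)
  withr::with_seed(85, ks <- sample(0:1599, 3))
  for (k in ks) {
    hk <- detect_palmprints(find_orfs_circular(rotate(g$monomer, k), min_aa = 100), models)
    expect_equal(sort(hk$palmprint), sort(h0$palmprint))
  }
})

test_that("decoy ORFs without planted motifs yield no palmprints", {
  withr::with_seed(86, {
    for (i in 1:5) {
      orfs <- find_orfs_circular(rand_dna(3000), min_aa = 100)
      if (nrow(orfs)) {
        expect_equal(nrow(detect_palmprints(orfs, models)), 0L)
      }
    }
  })
})

test_that("palmprint clustering groups identical sequences and splits diverged ones", {
  pp <- detect_palmprint(paste0(aa_filler(30, 87), A, aa_filler(20, 88), B,
                                aa_filler(15, 89), C, aa_filler(30, 90)),
                         models)$palmprint
  far <- aa_filler(nchar(pp), 91)
  hits <- tibble::tibble(orf_id = paste0("o", 1:4), palmprint = c(pp, pp, pp, far))
  cl <- cluster_palmprints(hits)
  expect_equal(length(unique(cl$sotu)), 2L)
  expect_equal(length(unique(cl$sotu[cl$id %in% c("o1", "o2", "o3")])), 1L)
  single <- cluster_palmprints(tibble::tibble(orf_id = "o", palmprint = pp))
  expect_equal(single$sotu, 1L)
})
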