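plant_monomer <- function(motif_seq, L, at, seed) {
  withr::with_seed(seed, {
    bg <- rand_dna(L - nchar(motif_seq))
    paste0(substr(bg, 1, at), motif_seq, substr(bg, at + 1, nchar(bg)))
  })
}

test_that("a planted motif spanning the origin is found with wrapped coordinates", {
  descs <- load_descriptors()
  withr::with_seed(21, {
    m <- instantiate_motif(descs$HHRz)
    mono <- plant_monomer(m$seq, 600, at = 300, seed = 22)
    # rotate so the motif crosses position 0
    rot <- rotate(mono, 300 + nchar(m$seq) %/% 2)
    h <- scan_strand(tibble::tibble(id = "x", monomer = rot), descs$HHRz, "+")
    expect_equal(nrow(h), 1L)
    expect_equal(h$score, 1)
    expect_gt(h$end, 600L)          # wraps the origin
    expect_equal((h$start + nchar(m$seq) %/% 2) %% 600, 0)
  })
})

test_that("hit coordinates are invariant (mod L) under rotation", {
  descs <- load_descriptors()
  withr::with_seed(23, {
    m <- instantiate_motif(descs$TWRz)
    mono <- plant_monomer(m$seq, 500, at = 120, seed = 24)
    h0 <- scan_strand(tibble::tibble(id = "x", monomer = mono), descs$TWRz, "+")
    for (k in c(37, 250, 499)) {
      hk <- scan_strand(tibble::tibble(id = "x", monomer = rotate(mono, k)),
                        descs$TWRz, "+")
      expect_equal(nrow(hk), nrow(h0))
      expect_equal(hk$start, (h0$start - k) %% 500)
    }
  })
})

test_that("scanning the minus strand equals scanning the reverse complement", {
  descs <- load_descriptors()
  withr::with_seed(25, {
    m <- instantiate_motif(descs$HPRz)
    mono <- plant_monomer(revcomp(m$seq), 400, at = 90, seed = 26)
    h_minus <- scan_strand(tibble::tibble(id = "x", monomer = mono), descs$HPRz, "-")
    h_plus_rc <- scan_strand(tibble::tibble(id = "x", monomer = revcomp(mono)),
                             descs$HPRz, "+")
    expect_equal(nrow(h_minus), 1L)
    expect_equal(nrow(h_plus_rc), 1L)
    expect_equal(h_minus$score, h_plus_rc$score)
    # plus-strand span of the minus hit maps onto the rc-strand span
    expect_equal(h_minus$start, (400 - h_plus_rc$end) %% 400)
  })
})

test_that("a monomer without the motif yields no hits", {
  descs <- load_descriptors()
  mono <- rand_dna(800, seed = 27)
  h <- scan_ribozymes(tibble::tibble(id = "x", monomer = mono), descs)
  expect_equal(nrow(h), 0L)
})

test_that("scores below min_score are rejected (weight arithmetic)", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "class STRICT",
    "min_score 0.9",
    "element core segment ACGTACGTAC 0.2,0.2,0.05,0.05,0.05,0.05,0.05,0.05,0.15,0.15",
    "cleavage core 0"
  ), p)
  d <- read_descriptor(p)
  expect_equal(d$total_weight, 1)
  # substitute the first position (weight 0.2): score drops to 0.8 < 0.9
  mono_bad <- plant_monomer("TCGTACGTAC", 200, at = 80, seed = 28)
  h <- scan_strand(tibble::tibble(id = "x", monomer = mono_bad), d, "+")
  expect_equal(nrow(h), 0L)
  mono_ok <- plant_monomer("ACGTACGTAC", 200, at = 80, seed = 28)
  h2 <- scan_strand(tibble::tibble(id = "x", monomer = mono_ok), d, "+")
  expect_gte(nrow(h2), 1L)
  expect_true(any(h2$score == 1))
})

test_that("cmsearch tabular hits are parsed, filtered and strand-resolved", {
  line <- function(target, model, from, to, evalue) {
    paste(target, "-", model, "-", "cm", 1, 70, from, to,
          if (from > to) "-" else "+", "no", 1, 0.5, 0, 50, evalue, "!", "desc")
  }
  p <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c(
    "# comment header",
    line("ctgA", "RF00008", 120, 51, 1e-5),
    line("ctgA", "RF00173", 10, 80, 1e-4),
    line("ctgB", "RF00008", 5, 75, 0.01)
  ), p)
  hits <- load_cm_hits(p, c(RF00008 = "HHRz", RF00173 = "HPRz"))
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$class, c("HHRz", "HPRz"))
  expect_equal(hits$strand, c("-", "+"))
  expect_equal(hits$start[1], 50L)
  expect_equal(hits$end[1], 120L)
  expect_true(all(hits$source == "cm_tabular"))
  expect_true(all(hits$score >= 0 & hits$score <= 1))
})

test_that("cm ingestion warns on unmapped models and errors on malformed lines", {
  p <- withr::local_tempfile(fileext = ".tbl")
  writeLines(paste("ctgA - UNKNOWN - cm 1 70 10 80 + no 1 0.5 0 50 1e-5 ! d"), p)
  expect_warning(h <- load_cm_hits(p, c(RF00008 = "HHRz")), "not in model map")
  expect_equal(nrow(h), 0L)
  p2 <- withr::local_tempfile(fileext = ".tbl")
  writeLines("ctgA RF00008 10", p2)
  expect_error(load_cm_hits(p2, c(RF00008 = "HHRz")), "line 1")
})

test_that("empty tblout (comments only) yields no hits", {
  p <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c("# hit table", "#"), p)
  expect_equal(nrow(load_cm_hits(p, c(RF00008 = "HHRz"))), 0L)
})

test_that("ambisense pairing follows the stated tie-breaks", {
  h <- function(class, strand, start, score) {
    tibble::tibble(contig_id = "c", class = class, strand = strand,
                   start = start, end = start + 60L, score = score,
                   cleavage_site = start + 5L, source = "descriptor")
  }
  pair <- find_ambisense_pairs(rbind(h("HHRz", "+", 10L, 0.95), h("HPRz", "-", 200L, 0.9)))
  expect_equal(pair$combo, "HHRz/HPRz")
  expect_equal(nrow(find_ambisense_pairs(h("HHRz", "+", 10L, 0.95))), 0L)
  pair2 <- find_ambisense_pairs(rbind(
    h("HHRz", "+", 10L, 0.9), h("HHRz", "+", 100L, 0.95), h("HHRz", "-", 300L, 0.8)))
  expect_equal(pair2$plus_start, 100L)
  expect_equal(pair2$combo, "HHRz/HHRz")
  # score tie: leftmost start wins
  pair3 <- find_ambisense_pairs(rbind(
    h("HHRz", "+", 50L, 0.9), h("TWRz", "+", 10L, 0.9), h("HHRz", "-", 300L, 0.8)))
  expect_equal(pair3$plus_class, "TWRz")
})

test_that("same-class-only pairing rejects mixed pairs", {
  h <- function(class, strand, score) {
    tibble::tibble(contig_id = "c", class = class, strand = strand,
                   start = 10L, end = 70L, score = score,
                   cleavage_site = 15L, source = "descriptor")
  }
  mixed <- rbind(h("HHRz", "+", 0.95), h("HPRz", "-", 0.9))
  expect_equal(nrow(find_ambisense_pairs(mixed, same_class_only = TRUE)), 0L)
  expect_equal(nrow(find_ambisense_pairs(mixed)), 1L)
})
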