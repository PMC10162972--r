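small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_dataset(
        spec = list(n_true = 4L, n_linear = 2L, n_single_rz = 2L,
                    n_repetitive = 2L),
        seed = 9L)
    }
    cache
  }
})

test_that("size classes map the documented boundaries exactly", {
  expect_equal(
    assign_size_class(c(150L, 500L, 1000L, 1500L, 3000L, 5000L)),
    c("below-min", "small", "medium", "medium-large", "large", "very-large"))
  # boundary values belong to the upper class (half-open intervals)
  expect_equal(assign_size_class(c(199L, 200L, 800L, 1200L, 2200L, 4000L)),
               c("below-min", "small", "medium", "medium-large", "large",
                 "very-large"))
  expect_error(assign_size_class(0L))
})

test_that("empty input yields an empty, well-formed result", {
  res <- run_pipeline(tibble::tibble(id = character(), sequence = character()))
  expect_equal(nrow(res$records), 0L)
  expect_named(res, c("records", "hits", "clusters", "palm_clusters", "summary"))
})

test_that("each contig receives exactly one status and statuses partition the input", {
  ds <- small_dataset()
  res <- run_pipeline(ds$contigs)
  expect_equal(nrow(res$records), nrow(ds$contigs))
  expect_false(any(is.na(res$records$status)))
  tab <- table(res$records$status)
  expect_equal(sum(tab), nrow(ds$contigs))
  expect_true(all(names(tab) %in% c("candidate", "rejected:not_circular",
                                    "rejected:no_ribozyme_pair",
                                    "rejected:repetitive")))
})

test_that("statuses match the planted truth on a small set", {
  ds <- small_dataset()
  res <- run_pipeline(ds$contigs)
  m <- match(ds$truth$id, res$records$contig_id)
  expect_equal(res$records$status[m], ds$truth$expected)
  cand <- res$records[res$records$status == "candidate", ]
  expect_equal(cand$combo,
               ds$truth$combo[match(cand$contig_id, ds$truth$id)])
  expect_false(any(is.na(cand$sotu)))
  expect_false(any(is.na(cand$size_class)))
})

test_that("pipeline output is invariant under input row permutation", {
  ds <- small_dataset()
  res1 <- run_pipeline(ds$contigs)
  withr::with_seed(11, perm <- sample.int(nrow(ds$contigs)))
  res2 <- run_pipeline(ds$contigs[perm, ])
  r1 <- res1$records[order(res1$records$contig_id), ]
  r2 <- res2$records[order(res2$records$contig_id), ]
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("full evaluation reports repeat fractions even for unpaired circles", {
  ds <- small_dataset()
  res <- run_pipeline(ds$contigs, config = list(full_evaluation = TRUE))
  single <- res$records[grepl("^single_rz", res$records$contig_id), ]
  expect_false(any(is.na(single$repeat_fraction)))
  expect_equal(unique(single$status), "rejected:no_ribozyme_pair")
})

test_that("summaries tabulate combos and sizes at the sOTU level", {
  records <- tibble::tibble(
    contig_id = sprintf("c%02d", 1:12),
    circular = c(rep(TRUE, 10), FALSE, TRUE),
    r = NA_integer_,
    monomer_length = c(300L, 310L, 320L, 330L, 340L, 900L, 910L, 1500L, 2500L,
                       4200L, NA, 600L),
    copy_number = 1L,
    combo = c(rep("HHRz/HHRz", 6), rep("HHRz/HPRz", 3), "DVRz/TWRz", NA, NA),
    plus_class = NA_character_, minus_class = NA_character_,
    repeat_fraction = 0, repeat_pass = TRUE,
    sotu = c(1:10, NA, NA),
    size_class = c(rep("small", 5), "medium", "medium", "medium-large",
                   "large", "very-large", NA, NA),
    has_palmprint = c(rep(FALSE, 8), TRUE, TRUE, NA, NA),
    palm_sotu = NA_integer_,
    fold_class = c(rep("rod", 4), rep("branched", 6), NA, NA),
    status = c(rep("candidate", 10), "rejected:not_circular",
               "rejected:repetitive"))
  s <- summarize_discovery(records)
  expect_equal(s$n_candidates, 10L)
  expect_equal(s$n_sotu, 10L)
  expect_equal(s$combo$fraction[s$combo$level == "HHRz/HHRz"], 0.6)
  expect_equal(s$combo$fraction[s$combo$level == "HHRz/HPRz"], 0.3)
  expect_equal(s$combo$fraction[s$combo$level == "DVRz/TWRz"], 0.1)
  expect_equal(s$coding_fraction, 0.2)
  expect_equal(sum(s$size$n), 10L)
  expect_equal(s$rejections$n[s$rejections$status == "candidate"], 10L)
})

test_that("sOTU representatives deduplicate multi-member clusters in summaries", {
  records <- tibble::tibble(
    contig_id = c("a", "b", "c"),
    circular = TRUE, r = NA_integer_,
    monomer_length = c(400L, 390L, 1000L),
    copy_number = 1L,
    combo = c("HHRz/HHRz", "HHRz/HHRz", "DVRz/DVRz"),
    plus_class = NA_character_, minus_class = NA_character_,
    repeat_fraction = 0, repeat_pass = TRUE,
    sotu = c(1L, 1L, 2L),
    size_class = c("small", "small", "medium"),
    has_palmprint = FALSE, palm_sotu = NA_integer_,
    fold_class = "branched", status = "candidate")
  s <- summarize_discovery(records)
  expect_equal(s$n_candidates, 3L)
  expect_equal(s$n_sotu, 2L)
  # one representative per sOTU: combos weighted 1/2 each
  expect_equal(sort(s$combo$fraction), c(0.5, 0.5))
})
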