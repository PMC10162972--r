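#' Default size-class boundaries
#'
#' Half-open `[lo, hi)` intervals in nt: below-min under 200, small
#' 200-800 (viroid-like), medium 800-1200, medium-large 1200-2200
#' (deltavirus-like), large 2200-4000 (mitovirus-like), very-large from
#' 4000 (ambivirus-like).
#'
#' @return named integer vector of lower bounds.
#' @export
default_size_classes <- function() {
  c("below-min" = 0L, "small" = 200L, "medium" = 800L,
    "medium-large" = 1200L, "large" = 2200L, "very-large" = 4000L)
}

#' Assign a monomer length to a size class
#'
#' @param monomer_length length in nt (> 0); vectorized.
#' @param config named integer vector of strictly increasing lower
#'   bounds starting at 0 (see [default_size_classes()]).
#' @return character vector of class labels.
#' @export
assign_size_class <- function(monomer_length, config = default_size_classes()) {
  stopifnot(all(monomer_length > 0), config[1] == 0L, !is.unsorted(config, strictly = TRUE))
  names(config)[findInterval(monomer_length, config)]
}

default_pipeline_config <- function() {
  list(
    k_min = 20L, max_mismatch = 0L, strand_insensitive = TRUE,
    same_class_only = FALSE, max_repeat_fraction = 0.25,
    cluster_threshold = 0.90, palm_threshold = 0.90,
    min_aa = 100L, genetic_code = "1",
    fold_max_length = 800L, side_hairpin_max = 30L,
    size_classes = default_size_classes(),
    full_evaluation = FALSE,
    descriptors = NULL, palm_models = NULL
  )
}

#' Run the full discovery pipeline
#'
#' Applies the stages in order: circularity detection, ambisense
#' ribozyme pair calling, repetitiveness filtering, circular sOTU
#' clustering, palmprint detection and amino-acid clustering, fold
#' classification (monomers up to `fold_max_length` nt, via the
#' fallback folder), and size-class assignment. A contig is a candidate
#' iff it is circular, carries a ribozyme pair, and passes the repeat
#' filter; every non-candidate records its first failing stage (with
#' `full_evaluation = TRUE` the remaining filter stages are still
#' evaluated for reporting). Clustering and annotation stages run on
#' candidates only.
#'
#' @param contigs tibble with `id`, `sequence` (e.g. from
#'   [read_fasta()]).
#' @param config named list overriding entries of the default
#'   configuration: `k_min`, `max_mismatch`, `strand_insensitive`,
#'   `same_class_only`, `max_repeat_fraction`, `cluster_threshold`,
#'   `palm_threshold`, `min_aa`, `genetic_code`, `fold_max_length`,
#'   `side_hairpin_max`, `size_classes`, `full_evaluation`,
#'   `descriptors`, `palm_models`.
#' @return list with `records` (one row per input contig), `hits`
#'   (ribozyme hits on circular contigs), `clusters` (nt sOTU table),
#'   `palm_clusters` (aa sOTU table), and `summary` (see
#'   [summarize_discovery()]).
#' @export
run_pipeline <- function(contigs, config = list()) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (is.null(cfg$descriptors)) cfg$descriptors <- load_descriptors()
  if (is.null(cfg$palm_models)) cfg$palm_models <- load_palm_models()

  records <- tibble(
    contig_id = contigs$id,
    circular = FALSE, r = NA_integer_, monomer_length = NA_integer_,
    copy_number = NA_integer_,
    combo = NA_character_, plus_class = NA_character_, minus_class = NA_character_,
    repeat_fraction = NA_real_, repeat_pass = NA,
    sotu = NA_integer_, size_class = NA_character_,
    has_palmprint = NA, palm_sotu = NA_integer_,
    fold_class = NA_character_,
    status = NA_character_
  )
  empty <- list(records = records[0, ], hits = empty_hits(),
                clusters = NULL, palm_clusters = NULL, summary = NULL)
  if (nrow(contigs) == 0L) return(empty)

  circles <- detect_circles(contigs, k_min = cfg$k_min,
                            max_mismatch = cfg$max_mismatch,
                            strand_insensitive = cfg$strand_insensitive)
  ci <- match(records$contig_id, circles$id)
  records$circular <- !is.na(ci)
  records$r <- circles$repeat_length[ci]
  records$monomer_length <- circles$monomer_length[ci]
  records$copy_number <- circles$copy_number[ci]
  records$status[!records$circular] <- "rejected:not_circular"

  hits <- scan_ribozymes(circles, cfg$descriptors)
  for (i in seq_len(nrow(circles))) {
    id <- circles$id[i]
    k <- which(records$contig_id == id)
    pair <- find_ambisense_pairs(hits[hits$contig_id == id, , drop = FALSE],
                                 same_class_only = cfg$same_class_only)
    if (nrow(pair)) {
      records$combo[k] <- pair$combo
      records$plus_class[k] <- pair$plus_class
      records$minus_class[k] <- pair$minus_class
    } else {
      records$status[k] <- "rejected:no_ribozyme_pair"
      if (!cfg$full_evaluation) next
    }
    rf <- apply_repeat_filter(circles[i, ], max_fraction = cfg$max_repeat_fraction)
    records$repeat_fraction[k] <- rf$masked_fraction
    records$repeat_pass[k] <- rf$pass
    if (!rf$pass && is.na(records$status[k])) {
      records$status[k] <- "rejected:repetitive"
    }
  }
  records$status[is.na(records$status)] <- "candidate"

  cand_ids <- records$contig_id[records$status == "candidate"]
  cand <- circles[match(cand_ids, circles$id), , drop = FALSE]
  clusters <- NULL
  palm_clusters <- NULL
  if (nrow(cand)) {
    clusters <- greedy_cluster(
      tibble(id = cand$id, sequence = cand$monomer),
      threshold = cfg$cluster_threshold, mode = "circular-nt",
      strand_insensitive = cfg$strand_insensitive)
    records$sotu <- clusters$sotu[match(records$contig_id, clusters$id)]
    records$size_class[records$status == "candidate"] <-
      assign_size_class(cand$monomer_length, cfg$size_classes)
    palm_hits <- NULL
    for (i in seq_len(nrow(cand))) {
      k <- which(records$contig_id == cand$id[i])
      orfs <- find_orfs_circular(cand[i, ], min_aa = cfg$min_aa,
                                 genetic_code = cfg$genetic_code)
      ph <- detect_palmprints(orfs, cfg$palm_models)
      records$has_palmprint[k] <- nrow(ph) > 0L
      if (nrow(ph)) palm_hits <- rbind(palm_hits, ph)
      if (cand$monomer_length[i] <= cfg$fold_max_length) {
        db <- nussinov_fold(cand$monomer[i], max_length = cfg$fold_max_length)
        records$fold_class[k] <- classify_fold(
          db, circular = TRUE, side_hairpin_max = cfg$side_hairpin_max)$class
      }
    }
    if (!is.null(palm_hits) && nrow(palm_hits)) {
      palm_clusters <- cluster_palmprints(palm_hits, threshold = cfg$palm_threshold)
      pk <- match(palm_hits$contig_id[match(palm_clusters$id, palm_hits$orf_id)],
                  records$contig_id)
      # a contig's aa sOTU is that of its best palmprint ORF (first listed)
      for (j in seq_along(pk)) {
        if (is.na(records$palm_sotu[pk[j]])) {
          records$palm_sotu[pk[j]] <- palm_clusters$sotu[j]
        }
      }
    }
  }
  list(records = records, hits = hits, clusters = clusters,
       palm_clusters = palm_clusters,
       summary = summarize_discovery(records))
}

#' Summaries over a discovery record table
#'
#' Produces the headline tabulations at the sOTU level (one
#' representative — the cluster centroid's record — per nt sOTU):
#' ribozyme class-combination frequencies, size-class histogram, coding
#' (palmprint-bearing) fraction, and fold-class fractions among folded
#' representatives.
#'
#' @param records record table from [run_pipeline()].
#' @return list with `combo` (tibble: combo, n, fraction), `size`
#'   (tibble: size_class, n, fraction), `coding_fraction`, `fold`
#'   (tibble: fold_class, n, fraction), `n_candidates`, `n_sotu`,
#'   `rejections` (tibble: status, n).
#' @export
summarize_discovery <- function(records) {
  cand <- records[records$status == "candidate", , drop = FALSE]
  rej <- as.data.frame(table(records$status), stringsAsFactors = FALSE)
  names(rej) <- c("status", "n")
  if (nrow(cand) == 0L) {
    return(list(combo = NULL, size = NULL, coding_fraction = NA_real_,
                fold = NULL, n_candidates = 0L, n_sotu = 0L,
                rejections = tibble::as_tibble(rej)))
  }
  # one representative per sOTU: its centroid (the longest member,
  # ties by id, matching the greedy_cluster centroid rule)
  cand_ord <- cand[order(-cand$monomer_length, cand$contig_id), , drop = FALSE]
  reps <- cand_ord[!duplicated(cand_ord$sotu), , drop = FALSE]
  tab <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NULL)
    d <- as.data.frame(table(x), stringsAsFactors = FALSE)
    names(d) <- c("level", "n")
    d$fraction <- d$n / sum(d$n)
    tibble::as_tibble(d[order(-d$n), ])
  }
  list(
    combo = tab(reps$combo),
    size = tab(reps$size_class),
    coding_fraction = mean(reps$has_palmprint, na.rm = TRUE),
    fold = tab(reps$fold_class),
    n_candidates = nrow(cand),
    n_sotu = length(unique(cand$sotu)),
    rejections = tibble::as_tibble(rej)
  )
}
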