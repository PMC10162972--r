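#' Rotation- and strand-invariant identity between circular sequences
#'
#' Aligns `a` end-to-end against the doubled candidate (glocal: global in
#' `a`, free ends on the doubled target), so every rotation of `b` is an
#' available alignment window. In strand-insensitive mode the better of
#' `b` and its reverse complement is taken. Identity is matches divided by
#' alignment columns spanned by `a` (gaps count as columns). Alignment
#' scoring is match +1, mismatch -1, gap open -2, gap extend -1.
#'
#' In `mode = "linear-aa"` a plain global alignment is used (no doubling,
#' no reverse complement), with unit scoring on the amino-acid alphabet;
#' identity remains count-based.
#'
#' @param a,b non-empty sequences.
#' @param strand_insensitive also try `revcomp(b)` (circular mode only;
#'   default TRUE).
#' @param mode `"circular-nt"` (default) or `"linear-aa"`.
#' @return identity fraction in `[0, 1]`.
#' @export
circular_identity <- function(a, b, strand_insensitive = TRUE, mode = "circular-nt") {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  if (mode == "linear-aa") {
    return(aln_identity(a, b, type = "global", alphabet = "AA"))
  }
  cands <- b
  if (strand_insensitive) cands <- c(cands, revcomp(b))
  max(vapply(cands, function(bb) {
    aln_identity(a, paste0(bb, bb), type = "global-local", alphabet = "DNA")
  }, 0))
}

# pairwise alignment identity: matches / alignment columns spanned by the
# pattern, under unit scoring (+1/-1, gap open 2, gap extend 1)
aln_identity <- function(a, b, type, alphabet) {
  if (alphabet == "DNA") {
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      substitutionMatrix = sm, gapOpening = 2, gapExtension = 1, type = type)
  } else {
    letters_aa <- c(Biostrings::AA_STANDARD, "X", "*")
    sm <- matrix(-1, length(letters_aa), length(letters_aa),
                 dimnames = list(letters_aa, letters_aa))
    diag(sm) <- 1
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = sm, gapOpening = 2, gapExtension = 1, type = type)
  }
  cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
  Biostrings::nmatch(pa) / cols
}

#' Brute-force circular identity oracle
#'
#' Enumerates every rotation of `b` (and of its reverse complement in
#' strand-insensitive mode) and takes the best global-alignment identity.
#' Exact but quadratic in rotations; intended for small sequences and for
#' cross-checking [circular_identity()].
#'
#' @inheritParams circular_identity
#' @return identity fraction in `[0, 1]`.
#' @export
circular_identity_brute <- function(a, b, strand_insensitive = TRUE) {
  cands <- b
  if (strand_insensitive) cands <- c(cands, revcomp(b))
  best <- 0
  for (bb in cands) {
    for (k in 0:(nchar(bb) - 1L)) {
      best <- max(best, aln_identity(a, rotate(bb, k), type = "global", alphabet = "DNA"))
    }
  }
  best
}

#' Greedy centroid clustering into species-like OTUs
#'
#' Items are sorted by length descending (ties broken by id); each joins
#' the first existing centroid with identity at or above the threshold,
#' otherwise it founds a new cluster. Deterministic for a given input set.
#'
#' @param items tibble with `id` and `sequence` columns (monomers or
#'   palmprint amino-acid sequences).
#' @param threshold identity threshold in (0, 1]; membership is inclusive
#'   (`>=`). Default 0.90.
#' @param mode `"circular-nt"` (rotation/strand-invariant) or
#'   `"linear-aa"`.
#' @param strand_insensitive passed to [circular_identity()].
#' @param min_length_ratio sequences whose length ratio (shorter /
#'   longer) falls below this are never conspecific and their alignment
#'   is skipped (default 0.9, matching the identity threshold; under a
#'   substitution-dominated divergence model conspecific circles have
#'   near-identical lengths, and for linear global alignment identity
#'   is itself bounded by the length ratio).
#' @return tibble with one row per item: `id`, `centroid_id`, `sotu`
#'   (integer cluster index, by order of founding), `identity_to_centroid`.
#' @export
greedy_cluster <- function(items, threshold = 0.90, mode = "circular-nt",
                           strand_insensitive = TRUE, min_length_ratio = 0.9) {
  stopifnot(nrow(items) > 0L, threshold > 0, threshold <= 1)
  ord <- order(-nchar(items$sequence), items$id)
  items <- items[ord, ]
  centroids <- integer(0)          # row indices of centroids
  assign_sotu <- integer(nrow(items))
  assign_ident <- numeric(nrow(items))
  lens <- nchar(items$sequence)
  for (i in seq_len(nrow(items))) {
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      lc <- lens[centroids[ci]]
      if (min(lens[i], lc) < min_length_ratio * max(lens[i], lc)) next
      ident <- circular_identity(items$sequence[i], items$sequence[centroids[ci]],
                                 strand_insensitive = strand_insensitive, mode = mode)
      if (ident >= threshold) {
        assign_sotu[i] <- ci
        assign_ident[i] <- ident
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, i)
      assign_sotu[i] <- length(centroids)
      assign_ident[i] <- 1
    }
  }
  tibble(
    id = items$id,
    centroid_id = items$id[centroids[assign_sotu]],
    sotu = assign_sotu,
    identity_to_centroid = assign_ident
  )
}
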