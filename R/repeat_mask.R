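#' Low-complexity masking by triplet composition
#'
#' A dust-style score is computed per sliding window: with `c_t` the count
#' of triplet `t` among the `k` overlapping triplets of the window, the
#' score is `sum(c_t * (c_t - 1) / 2) / (k - 1)`. Windows whose score
#' exceeds `score_threshold` are masked in full; adjacent masked windows
#' merge.
#'
#' @param seq nucleotide string.
#' @param window window size in nt (>= 8; default 64). Sequences shorter
#'   than the window are scored as a single window.
#' @param score_threshold mask windows scoring above this (default 2.0).
#' @return interval matrix (0-based half-open), merged.
#' @export
low_complexity_mask <- function(seq, window = 64L, score_threshold = 2.0) {
  stopifnot(window >= 8L)
  L <- nchar(seq)
  if (L < 3L) return(merge_intervals(NULL))
  ch <- seq_chars(seq)
  ntrip <- L - 2L
  trip <- paste0(ch[1:ntrip], ch[2:(ntrip + 1L)], ch[3:(ntrip + 2L)])
  tid <- as.integer(factor(trip))
  win <- min(window, L)
  k <- win - 2L
  # slide one position at a time with incremental triplet counts, so the
  # masked set is exact (and, on a doubled circular monomer, independent
  # of the rotation presented)
  counts <- integer(max(tid))
  raw <- 0
  for (i in 1:k) {
    c0 <- counts[tid[i]]
    raw <- raw + c0
    counts[tid[i]] <- c0 + 1L
  }
  iv <- list()
  if (raw / (k - 1L) > score_threshold) iv[[length(iv) + 1L]] <- c(0L, win)
  s <- 0L
  while (s < L - win) {
    out <- tid[s + 1L]
    counts[out] <- counts[out] - 1L
    raw <- raw - counts[out]
    inn <- tid[s + k + 1L]
    raw <- raw + counts[inn]
    counts[inn] <- counts[inn] + 1L
    s <- s + 1L
    if (raw / (k - 1L) > score_threshold) iv[[length(iv) + 1L]] <- c(s, s + win)
  }
  merge_intervals(do.call(rbind, iv))
}

#' Tandem-repeat masking by exact-period run detection
#'
#' For each period `p <= max_period`, maximal runs of positions where
#' `seq[i] == seq[i + p]` define a repeated span; spans of at least
#' `min_span` nt containing at least `min_copies` copies of the unit are
#' masked.
#'
#' @param seq nucleotide string.
#' @param max_period largest unit length considered (default 10).
#' @param min_copies minimum copy number of the unit (default 3).
#' @param min_span minimum repeat span in nt (default 24).
#' @return interval matrix (0-based half-open), merged.
#' @export
tandem_mask <- function(seq, max_period = 10L, min_copies = 3L, min_span = 24L) {
  stopifnot(max_period >= 1L)
  L <- nchar(seq)
  ch <- seq_chars(seq)
  iv <- list()
  for (p in seq_len(min(max_period, L - 1L))) {
    eq <- ch[1:(L - p)] == ch[(p + 1L):L]
    r <- rle(eq)
    pos <- cumsum(c(0L, r$lengths[-length(r$lengths)]))  # 0-based run starts
    for (j in seq_along(r$lengths)) {
      if (!r$values[j]) next
      span <- r$lengths[j] + p       # matched run plus one unit
      if (span >= min_span && span / p >= min_copies) {
        iv[[length(iv) + 1L]] <- c(pos[j], pos[j] + span)
      }
    }
  }
  merge_intervals(do.call(rbind, iv))
}

# forward self-match intervals on the diagonals that carry shared k-mers;
# exclude_mod drops diagonals that are multiples of it (trivial copy-copy
# images on a doubled circular monomer); diagonals examined are capped —
# heavily repetitive input saturates the mask long before the cap matters
self_hits_forward <- function(seq, k, min_hit_len, exclude_mod = NULL, max_diagonals = 200L) {
  L <- nchar(seq)
  if (L < min_hit_len || L < k + 1L) return(merge_intervals(NULL))
  ch <- seq_chars(seq)
  nk <- L - k + 1L
  kmers <- substring(seq, 1:nk, k:L)
  groups <- split(seq_len(nk) - 1L, kmers)
  groups <- groups[lengths(groups) > 1L]
  diags <- integer(0)
  for (g in groups) {
    d <- diff(g)             # adjacent occurrences are enough to seed a diagonal
    diags <- c(diags, d)
  }
  diags <- sort(unique(diags))
  if (!is.null(exclude_mod)) diags <- diags[diags %% exclude_mod != 0L]
  diags <- head(diags, max_diagonals)
  iv <- list()
  for (d in diags) {
    n <- L - d
    eq <- ch[1:n] == ch[(d + 1L):(d + n)]
    r <- rle(eq)
    pos <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
    for (j in seq_along(r$lengths)) {
      if (!r$values[j] || r$lengths[j] < min_hit_len) next
      s <- pos[j]; e <- pos[j] + r$lengths[j]
      iv[[length(iv) + 1L]] <- c(s, e)          # first copy
      iv[[length(iv) + 1L]] <- c(s + d, e + d)  # second copy
    }
  }
  merge_intervals(do.call(rbind, iv))
}

# inverted (reverse-complement) self-match intervals, by anti-diagonal
self_hits_inverted <- function(seq, k, min_hit_len, max_diagonals = 200L) {
  L <- nchar(seq)
  if (L < min_hit_len || L < k + 1L) return(merge_intervals(NULL))
  ch <- seq_chars(seq)
  rc <- revcomp(seq)
  rch <- seq_chars(rc)
  nk <- L - k + 1L
  fw <- split(seq_len(nk) - 1L, substring(seq, 1:nk, k:L))
  rv <- split(seq_len(nk) - 1L, substring(rc, 1:nk, k:L))
  common <- intersect(names(fw), names(rv))
  diags <- integer(0)
  for (km in common) {
    # matching ch[i + t] == rch[j + t]: diagonal is j - i
    diags <- c(diags, as.vector(outer(rv[[km]], fw[[km]], `-`)))
  }
  diags <- sort(unique(diags))
  diags <- head(diags, max_diagonals)
  iv <- list()
  for (d in diags) {
    if (d >= 0L) { i0 <- 0L; j0 <- d } else { i0 <- -d; j0 <- 0L }
    n <- L - max(i0, j0)
    if (n < min_hit_len) next
    eq <- ch[(i0 + 1L):(i0 + n)] == rch[(j0 + 1L):(j0 + n)]
    r <- rle(eq)
    pos <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
    for (jj in seq_along(r$lengths)) {
      if (!r$values[jj] || r$lengths[jj] < min_hit_len) next
      s <- pos[jj]; len <- r$lengths[jj]
      fs <- i0 + s                       # plus-strand span of the forward copy
      rs <- j0 + s                       # rc-coordinate span of the partner
      ps <- L - (rs + len)               # partner back in plus coordinates
      # a self-palindromic stretch maps onto itself; mask it once
      iv[[length(iv) + 1L]] <- c(fs, fs + len)
      iv[[length(iv) + 1L]] <- c(ps, ps + len)
    }
  }
  merge_intervals(do.call(rbind, iv))
}

#' Dispersed self-repeat masking by seeded exact matching
#'
#' Finds k-mers shared between the sequence and itself (both strands),
#' excludes the trivial self-diagonal, extends seeds to maximal exact
#' matches along each diagonal, and masks matches of at least
#' `min_hit_len` nt on both copies.
#'
#' @param seq nucleotide string.
#' @param k seed length (>= 8; default 12).
#' @param min_hit_len minimum extended match length to mask (default 30).
#' @return interval matrix (0-based half-open), merged.
#' @export
self_repeat_mask <- function(seq, k = 12L, min_hit_len = 30L) {
  stopifnot(k >= 8L)
  merge_intervals(rbind(
    self_hits_forward(seq, k, min_hit_len),
    self_hits_inverted(seq, k, min_hit_len)
  ))
}

#' Compute masked regions of a circular monomer and apply the 25% filter
#'
#' Low-complexity, tandem and dispersed self-repeats are detected on the
#' doubled monomer (so origin-spanning repeats are caught; forward
#' self-matches at diagonal offsets that are multiples of the monomer
#' length are the two copies seeing each other and are excluded), intervals
#' are reduced modulo the monomer length, and the union fraction decides
#' the filter: a candidate fails when at least `max_fraction` of its
#' monomer is repetitive.
#'
#' @param circ one-row tibble with `id` and `monomer` (or a bare monomer
#'   string).
#' @param max_fraction rejection threshold on the union masked fraction
#'   (default 0.25; fail when `masked_fraction >= max_fraction`).
#' @param lc_window,lc_threshold low-complexity parameters.
#' @param td_max_period,td_min_copies,td_min_span tandem parameters.
#' @param sr_k,sr_min_hit_len self-repeat parameters.
#' @return list with `pass` (logical), `masked_fraction`, `intervals`
#'   (union, monomer coordinates), and per-source fractions
#'   `fraction_dust`, `fraction_tandem`, `fraction_self`.
#' @export
apply_repeat_filter <- function(circ, max_fraction = 0.25,
                                lc_window = 64L, lc_threshold = 2.0,
                                td_max_period = 10L, td_min_copies = 3L, td_min_span = 24L,
                                sr_k = 12L, sr_min_hit_len = 30L) {
  m <- if (is.character(circ)) circ else circ$monomer
  L <- nchar(m)
  dd <- paste0(m, m)
  iv_lc <- reduce_intervals_mod(low_complexity_mask(dd, lc_window, lc_threshold), L)
  iv_td <- reduce_intervals_mod(tandem_mask(dd, td_max_period, td_min_copies, td_min_span), L)
  iv_sr <- reduce_intervals_mod(merge_intervals(rbind(
    self_hits_forward(dd, sr_k, sr_min_hit_len, exclude_mod = L),
    self_hits_inverted(dd, sr_k, sr_min_hit_len)
  )), L)
  union <- merge_intervals(rbind(iv_lc, iv_td, iv_sr))
  frac <- interval_span(union) / L
  list(
    pass = frac < max_fraction,
    masked_fraction = frac,
    intervals = union,
    fraction_dust = interval_span(iv_lc) / L,
    fraction_tandem = interval_span(iv_td) / L,
    fraction_self = interval_span(iv_sr) / L
  )
}
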