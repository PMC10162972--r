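#' Detect a terminal repeat suggestive of a circular molecule
#'
#' A linear contig assembled from a circular template typically carries the
#' same sequence at both ends. This scans repeat lengths from
#' `floor(L / 2)` down to `k_min` and returns the largest `r` such that the
#' length-`r` prefix matches the length-`r` suffix with at most
#' `max_mismatch` mismatches (Hamming distance; no indels). Ambiguity codes,
#' including `N`, never count as a match (conservative).
#'
#' @param contig one-row tibble (or list) with `sequence`; a bare character
#'   scalar is also accepted.
#' @param k_min smallest repeat length considered (nt; default 20).
#' @param max_mismatch mismatches tolerated between the two copies
#'   (default 0, exact).
#' @return a list with `r` (repeat length, or `NA_integer_` if none) and
#'   `reason` (`"ok"`, `"too_short"` or `"no_overlap"`).
#' @export
find_terminal_overlap <- function(contig, k_min = 20L, max_mismatch = 0L) {
  seq <- if (is.character(contig)) contig else contig$sequence
  L <- nchar(seq)
  if (L < 2L * k_min) return(list(r = NA_integer_, reason = "too_short"))
  ch <- seq_chars(seq)
  acgt <- ch %in% c("A", "C", "G", "T")
  r_max <- L %/% 2L
  for (r in seq(r_max, k_min)) {
    pre <- ch[1:r]
    suf <- ch[(L - r + 1L):L]
    mism <- sum(!(pre == suf & acgt[1:r] & acgt[(L - r + 1L):L]))
    if (mism <= max_mismatch) return(list(r = as.integer(r), reason = "ok"))
  }
  list(r = NA_integer_, reason = "no_overlap")
}

# smallest period p of s such that s is exactly (nchar/p) tandem copies of
# its length-p prefix; returns nchar(s) when s is primitive
smallest_period <- function(s) {
  n <- nchar(s)
  for (p in seq_len(n %/% 2L)) {
    if (n %% p != 0L) next
    unit <- substr(s, 1L, p)
    if (paste(rep(unit, n %/% p), collapse = "") == s) return(p)
  }
  n
}

#' Trim a terminal repeat and canonicalise the circular monomer
#'
#' Removes one copy of the terminal repeat, collapses exact tandem
#' concatemers (rolling-circle multimers) to their repeat unit, and stores
#' the canonical rotation of the monomer.
#'
#' @param contig one-row tibble with `id` and `sequence`.
#' @param r terminal repeat length as returned by [find_terminal_overlap()].
#' @param strand_insensitive canonicalise over both strands (default TRUE).
#' @return one-row tibble: `id`, `monomer` (canonical), `monomer_length`,
#'   `repeat_length`, `copy_number`, `source_id`, `source_length`,
#'   `evidence`.
#' @export
circularize <- function(contig, r, strand_insensitive = TRUE) {
  seq <- contig$sequence
  L <- nchar(seq)
  if (is.na(r) || r < 1L || r > L %/% 2L) {
    stop("invalid terminal repeat length r=", r, " for contig ", contig$id, " (L=", L, ")")
  }
  raw <- substr(seq, 1L, L - r)
  p <- smallest_period(raw)
  copies <- nchar(raw) %/% p
  unit <- substr(raw, 1L, p)
  canon <- canonical_rotation(unit, strand_insensitive = strand_insensitive)
  tibble(
    id = contig$id,
    monomer = canon,
    monomer_length = nchar(canon),
    repeat_length = as.integer(r),
    copy_number = as.integer(copies),
    source_id = contig$id,
    source_length = L,
    evidence = paste0("terminal_repeat:", r, "nt;copies:", copies)
  )
}

#' Canonical rotation of a circular sequence
#'
#' Returns the lexicographically minimal rotation (Booth's algorithm); in
#' strand-insensitive mode the minimum is additionally taken over the
#' reverse complement, so identical circles sequenced from any rotation or
#' strand compare equal. Idempotent.
#'
#' @param monomer non-empty character scalar.
#' @param strand_insensitive also consider the reverse complement.
#' @return the canonical rotation.
#' @export
canonical_rotation <- function(monomer, strand_insensitive = FALSE) {
  if (nchar(monomer) == 0L) stop("empty monomer")
  fwd <- least_rotation(monomer)
  if (!strand_insensitive) return(fwd)
  rev <- least_rotation(revcomp(monomer))
  if (rev < fwd) rev else fwd
}

# Booth's least-rotation: O(n) failure-function variant
least_rotation <- function(s) {
  n <- nchar(s)
  if (n == 1L) return(s)
  ss <- seq_chars(paste0(s, s))
  f <- rep(-1L, 2L * n)
  k <- 0L  # 0-based start of least rotation so far
  for (j in 1L:(2L * n - 1L)) {       # 0-based index j over ss
    sj <- ss[j + 1L]
    i <- f[j - k]                      # f is 0-based indexed via +1 shift
    while (i != -1L && sj != ss[k + i + 2L]) {
      if (sj < ss[k + i + 2L]) k <- j - i - 1L
      i <- f[i + 1L]
    }
    if (sj != ss[k + i + 2L]) {
      if (sj < ss[k + 1L]) k <- j
      f[j - k + 1L] <- -1L
    } else {
      f[j - k + 1L] <- i + 1L
    }
  }
  paste(ss[(k + 1L):(k + n)], collapse = "")
}

#' Detect circular contigs in a contig set
#'
#' Applies [find_terminal_overlap()] and [circularize()] to every contig.
#'
#' @param contigs tibble from [read_fasta()].
#' @inheritParams find_terminal_overlap
#' @inheritParams circularize
#' @return tibble of circular contigs (possibly 0 rows), one row per
#'   detected circle, plus attribute `"reasons"`: a named character vector
#'   giving, for every input contig, `"circular"` or the failure reason.
#' @export
detect_circles <- function(contigs, k_min = 20L, max_mismatch = 0L,
                           strand_insensitive = TRUE) {
  out <- list()
  reasons <- setNames(character(nrow(contigs)), contigs$id)
  for (i in seq_len(nrow(contigs))) {
    row <- contigs[i, ]
    ov <- find_terminal_overlap(row, k_min = k_min, max_mismatch = max_mismatch)
    if (is.na(ov$r)) {
      reasons[row$id] <- ov$reason
    } else {
      reasons[row$id] <- "circular"
      out[[length(out) + 1L]] <- circularize(row, ov$r, strand_insensitive = strand_insensitive)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else tibble(
    id = character(0), monomer = character(0), monomer_length = integer(0),
    repeat_length = integer(0), copy_number = integer(0),
    source_id = character(0), source_length = integer(0), evidence = character(0)
  )
  attr(res, "reasons") <- reasons
  res
}
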