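#' @useDynLib viroidscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames runif
#' @importFrom utils head tail write.table read.table
NULL

# IUPAC nucleotide codes -> set of concrete bases (DNA alphabet, U stored as T)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_SETS)

#' Rotate a sequence left by k positions
#'
#' `rotate("ABCDE", 2)` is `"CDEAB"`; negative `k` rotates right.
#'
#' @param seq character scalar.
#' @param k integer offset (any sign; taken mod nchar).
#' @return rotated character scalar.
#' @export
rotate <- function(seq, k) {
  n <- nchar(seq)
  if (n == 0L) return(seq)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(seq)
  paste0(substr(seq, k + 1L, n), substr(seq, 1L, k))
}

# split a sequence into a character vector of single letters
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# random sequence helper (uses the current RNG stream)
random_seq <- function(n, alphabet = c("A", "C", "G", "T"), prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# merge a two-column start/end (0-based half-open) matrix of intervals
# into disjoint sorted intervals, via IRanges
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = iv[, 1L] + 1L, end = iv[, 2L]))
  cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# total length covered by a merged interval matrix
interval_span <- function(iv) {
  if (nrow(iv) == 0L) return(0L)
  sum(iv[, 2L] - iv[, 1L])
}

# map intervals detected on a doubled sequence back onto the monomer
# (mod L), splitting intervals that cross the origin, then merge
reduce_intervals_mod <- function(iv, L) {
  if (is.null(iv) || nrow(iv) == 0L) return(merge_intervals(NULL))
  out <- list()
  for (i in seq_len(nrow(iv))) {
    s <- iv[i, 1L]; e <- iv[i, 2L]
    if (e - s >= L) { out[[length(out) + 1L]] <- c(0L, L); next }
    s0 <- s %% L
    e0 <- s0 + (e - s)
    if (e0 <= L) {
      out[[length(out) + 1L]] <- c(s0, e0)
    } else {
      out[[length(out) + 1L]] <- c(s0, L)
      out[[length(out) + 1L]] <- c(0L, e0 - L)
    }
  }
  merge_intervals(do.call(rbind, out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
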