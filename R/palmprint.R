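#' Read RdRp palmprint motif models
#'
#' Parses the plain-text motif model format shipped in
#' `inst/extdata/palmprint/models.txt`: per-motif position weight lines
#' (`pos AA:weight ...`, unlisted residues score 0), a `min_score`
#' fraction per motif, and `gap <from> <to> <min> <max>` lines giving
#' inter-motif gap bounds in amino acids (gap = next motif start minus
#' previous motif end).
#'
#' @param path model file path.
#' @return list with `motifs` (named list; each has `name`, `min_score`,
#'   `weights` — a list of named numeric vectors per position — and
#'   `width`, `attainable`) and `gaps` (named list `"A->B"` etc. with
#'   `min`, `max`).
#' @export
read_palm_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  motifs <- list()
  gaps <- list()
  cur <- NULL
  for (ln in lines) {
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "gap") {
      if (length(tok) != 5L) stop(path, ": malformed gap line: ", ln)
      gaps[[paste0(tok[2], "->", tok[3])]] <-
        list(min = as.integer(tok[4]), max = as.integer(tok[5]))
    } else if (tok[1] == "motif") {
      cur <- list(name = tok[2], min_score = NA_real_, weights = list())
    } else if (tok[1] == "min_score") {
      cur$min_score <- as.numeric(tok[2])
    } else if (tok[1] == "pos") {
      pairs <- strsplit(tok[-1], ":", fixed = TRUE)
      w <- vapply(pairs, function(p) as.numeric(p[2]), 0)
      names(w) <- vapply(pairs, `[`, "", 1L)
      cur$weights[[length(cur$weights) + 1L]] <- w
    } else if (tok[1] == "end") {
      cur$width <- length(cur$weights)
      cur$attainable <- sum(vapply(cur$weights, max, 0))
      if (cur$width < 4L) stop(path, ": motif ", cur$name, " has width < 4")
      if (is.na(cur$min_score) || cur$min_score <= 0 || cur$min_score > 1) {
        stop(path, ": motif ", cur$name, " needs min_score in (0,1]")
      }
      motifs[[cur$name]] <- cur
      cur <- NULL
    } else {
      stop(path, ": unrecognized directive: ", ln)
    }
  }
  for (m in c("A", "B", "C")) {
    if (is.null(motifs[[m]])) stop(path, ": missing motif ", m)
  }
  for (g in c("A->B", "B->C")) {
    if (is.null(gaps[[g]])) stop(path, ": missing gap bounds ", g)
    if (gaps[[g]]$min <= 0 || gaps[[g]]$max < gaps[[g]]$min) {
      stop(path, ": gap bounds ", g, " must be positive and ordered")
    }
  }
  list(motifs = motifs[c("A", "B", "C")], gaps = gaps)
}

#' Load the palmprint motif models shipped with the package
#'
#' @param path model file; defaults to the packaged toy models.
#' @return see [read_palm_models()].
#' @export
load_palm_models <- function(path = system.file("extdata", "palmprint", "models.txt",
                                                package = "viroidscan")) {
  read_palm_models(path)
}

# score fraction of one motif at 0-based offset `at` in the aa character
# vector; NA when the window does not fit
motif_score_at <- function(aa_chars, motif, at) {
  if (at < 0L || at + motif$width > length(aa_chars)) return(NA_real_)
  got <- 0
  for (j in seq_len(motif$width)) {
    w <- motif$weights[[j]][aa_chars[at + j]]
    if (!is.na(w)) got <- got + w
  }
  got / motif$attainable
}

# all 0-based offsets where the motif scores >= its min_score
motif_placements <- function(aa_chars, motif) {
  n <- length(aa_chars) - motif$width
  if (n < 0L) return(list(at = integer(0), score = numeric(0)))
  at <- 0:n
  sc <- vapply(at, function(a) motif_score_at(aa_chars, motif, a), 0)
  keep <- sc >= motif$min_score
  list(at = at[keep], score = sc[keep])
}

#' Detect the RdRp palmprint (motifs A, B, C) in a protein sequence
#'
#' Exhaustively enumerates placements of motifs A, B and C subject to
#' their order and the configured inter-motif gap bounds (gap = next
#' motif start minus previous motif end, in amino acids). Every motif
#' must individually reach its `min_score`; among valid placements the
#' one with the highest total score is reported (ties: leftmost A, then
#' B, then C). The palmprint is the substring from the start of motif A
#' to the end of motif C.
#'
#' @param orf_aa protein sequence (single string, one-letter amino
#'   acids).
#' @param models motif models from [read_palm_models()]; defaults to the
#'   shipped toy models.
#' @return one-row tibble with motif spans (`a_start`, `a_end`,
#'   `b_start`, `b_end`, `c_start`, `c_end`; 0-based half-open aa
#'   coordinates), per-motif scores, `total_score`, and `palmprint`; or a
#'   zero-row tibble when no valid placement exists.
#' @export
detect_palmprint <- function(orf_aa, models = load_palm_models()) {
  empty <- tibble(
    a_start = integer(0), a_end = integer(0), b_start = integer(0),
    b_end = integer(0), c_start = integer(0), c_end = integer(0),
    score_a = numeric(0), score_b = numeric(0), score_c = numeric(0),
    total_score = numeric(0), palmprint = character(0)
  )
  aa <- seq_chars(orf_aa)
  pa <- motif_placements(aa, models$motifs$A)
  if (!length(pa$at)) return(empty)
  pb <- motif_placements(aa, models$motifs$B)
  if (!length(pb$at)) return(empty)
  pc <- motif_placements(aa, models$motifs$C)
  if (!length(pc$at)) return(empty)
  wa <- models$motifs$A$width; wb <- models$motifs$B$width; wc <- models$motifs$C$width
  gab <- models$gaps[["A->B"]]; gbc <- models$gaps[["B->C"]]
  best <- NULL
  for (ia in seq_along(pa$at)) {
    a0 <- pa$at[ia]
    for (ib in seq_along(pb$at)) {
      gap1 <- pb$at[ib] - (a0 + wa)
      if (gap1 < gab$min || gap1 > gab$max) next
      for (ic in seq_along(pc$at)) {
        gap2 <- pc$at[ic] - (pb$at[ib] + wb)
        if (gap2 < gbc$min || gap2 > gbc$max) next
        tot <- pa$score[ia] + pb$score[ib] + pc$score[ic]
        if (is.null(best) || tot > best$tot + 1e-12) {
          best <- list(a = ia, b = ib, c = ic, tot = tot)
        }
      }
    }
  }
  if (is.null(best)) return(empty)
  a0 <- pa$at[best$a]; b0 <- pb$at[best$b]; c0 <- pc$at[best$c]
  tibble(
    a_start = a0, a_end = a0 + wa,
    b_start = b0, b_end = b0 + wb,
    c_start = c0, c_end = c0 + wc,
    score_a = pa$score[best$a], score_b = pb$score[best$b],
    score_c = pc$score[best$c], total_score = best$tot,
    palmprint = substr(orf_aa, a0 + 1L, c0 + wc)
  )
}

# one codon per amino acid (standard code), used when synthesizing coding
# sequence for planted ORFs
CODON_FOR_AA <- c(
  A = "GCT", C = "TGC", D = "GAT", E = "GAA", F = "TTC", G = "GGT",
  H = "CAC", I = "ATC", K = "AAA", L = "CTG", M = "ATG", N = "AAC",
  P = "CCG", Q = "CAG", R = "CGT", S = "TCT", T = "ACC", V = "GTT",
  W = "TGG", Y = "TAC", `*` = "TAA"
)

#' Find open reading frames on a circular monomer
#'
#' Translates all six frames of the doubled monomer so that ORFs spanning
#' the circular origin are found, then deduplicates modulo the monomer
#' length. Default mode is stop-to-stop: a reported ORF is a maximal
#' stop-free stretch bounded by in-frame stop codons on both sides (the
#' stops are not part of the reported span). `mode = "atg-to-stop"`
#' reports from the first ATG of each such stretch instead.
#'
#' @param circ one-row tibble with `id` and `monomer`, or a bare monomer
#'   string.
#' @param min_aa minimum ORF length in amino acids (default 100).
#' @param genetic_code NCBI genetic code id as a string (default `"1"`,
#'   standard; `"4"` for mold mitochondrial).
#' @param mode `"stop-to-stop"` (default) or `"atg-to-stop"`.
#' @return tibble with `contig_id`, `orf_id`, `strand`, `start`, `end`
#'   (0-based half-open on the plus strand of the monomer; `end` may
#'   exceed the monomer length for origin-wrapping ORFs),
#'   `wraps_origin`, `aa_length`, `aa`.
#' @export
find_orfs_circular <- function(circ, min_aa = 100L, genetic_code = "1",
                               mode = c("stop-to-stop", "atg-to-stop")) {
  mode <- match.arg(mode)
  m <- if (is.character(circ)) circ else circ$monomer
  id <- if (is.character(circ)) "seq" else circ$id
  L <- nchar(m)
  code <- Biostrings::getGeneticCode(genetic_code)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") m else revcomp(m)
    dd <- paste0(s, s)
    seen <- character(0)
    for (f in 0:2) {
      n_codon <- (2L * L - f) %/% 3L
      if (n_codon < 1L) next
      frame_seq <- substr(dd, f + 1L, f + 3L * n_codon)
      aa <- as.character(suppressWarnings(Biostrings::translate(
        Biostrings::DNAString(frame_seq), genetic.code = code,
        if.fuzzy.codon = "solve")))
      ch <- seq_chars(aa)
      stops <- which(ch == "*")
      if (!length(stops)) {
        # stop-free circular frame: one ORF covering the whole circle
        if (L %% 3L == 0L && L %/% 3L >= min_aa) {
          key <- paste(strand, f, L %/% 3L)
          if (!key %in% seen) {
            seen <- c(seen, key)
            out[[length(out) + 1L]] <- orf_row(id, strand, f, L %/% 3L, L,
                                               substr(aa, 1L, L %/% 3L))
          }
        }
        next
      }
      # maximal stop-free runs bounded by stops on both sides
      bounds <- cbind(head(stops, -1L), stops[-1L])
      for (b in seq_len(nrow(bounds))) {
        a_from <- bounds[b, 1L] + 1L   # 1-based aa index after left stop
        a_to <- bounds[b, 2L] - 1L     # 1-based aa index before right stop
        if (a_to < a_from) next
        if (mode == "atg-to-stop") {
          rel <- which(ch[a_from:a_to] == "M")
          if (!length(rel)) next
          a_from <- a_from + rel[1L] - 1L
        }
        len_aa <- a_to - a_from + 1L
        if (len_aa < min_aa || 3L * len_aa > L) next
        nt_start <- f + 3L * (a_from - 1L)       # 0-based on doubled strand
        start_mod <- nt_start %% L
        key <- paste(strand, start_mod, len_aa)
        if (key %in% seen) next
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- orf_row(id, strand, start_mod, len_aa, L,
                                           substr(aa, a_from, a_to))
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else orf_row(NULL)
  res[order(res$start, res$strand), ]
}

# build one ORF row, mapping minus-strand coordinates back to the plus
# strand of the monomer; with no arguments returns the empty schema
orf_row <- function(id, strand, start_native, len_aa, L, aa) {
  if (is.null(id)) {
    return(tibble(
      contig_id = character(0), orf_id = character(0), strand = character(0),
      start = integer(0), end = integer(0), wraps_origin = logical(0),
      aa_length = integer(0), aa = character(0)
    ))
  }
  len_nt <- 3L * len_aa
  if (strand == "+") {
    start <- start_native
  } else {
    start <- (L - (start_native + len_nt)) %% L
  }
  tibble(
    contig_id = id, strand = strand,
    start = start, end = start + len_nt,
    wraps_origin = start + len_nt > L,
    aa_length = len_aa, aa = aa,
    orf_id = paste0(id, ":", strand, start)
  )[, c("contig_id", "orf_id", "strand", "start", "end", "wraps_origin",
        "aa_length", "aa")]
}

#' Detect palmprints across a table of ORFs
#'
#' Applies [detect_palmprint()] to each ORF and keeps hits.
#'
#' @param orfs tibble from [find_orfs_circular()] (columns `orf_id`,
#'   `aa`; other columns are carried through).
#' @param models motif models (see [read_palm_models()]).
#' @return tibble with one row per ORF carrying a palmprint: the ORF
#'   columns plus the [detect_palmprint()] columns.
#' @export
detect_palmprints <- function(orfs, models = load_palm_models()) {
  rows <- lapply(seq_len(nrow(orfs)), function(i) {
    hit <- detect_palmprint(orfs$aa[i], models)
    if (nrow(hit) == 0L) return(NULL)
    cbind(orfs[i, ], hit)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(cbind(orf_row(NULL), detect_palmprint("", models)))
  }
  tibble::as_tibble(do.call(rbind, rows))
}

#' Cluster palmprint amino-acid sequences into species-like OTUs
#'
#' Greedy centroid clustering of palmprints at an amino-acid identity
#' threshold (linear global alignment, no doubling, no reverse
#' complement).
#'
#' @param hits tibble with `orf_id` and `palmprint` columns (e.g. from
#'   [detect_palmprints()]).
#' @param threshold identity threshold, inclusive (default 0.90).
#' @return see [greedy_cluster()].
#' @export
cluster_palmprints <- function(hits, threshold = 0.90) {
  items <- tibble(id = hits$orf_id, sequence = hits$palmprint)
  greedy_cluster(items, threshold = threshold, mode = "linear-aa")
}
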