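#' Scan one strand of a circular monomer for a ribozyme motif
#'
#' The monomer is doubled so that motifs spanning the circle origin are
#' found; coordinates are reported modulo the monomer length (`end` may
#' exceed it for origin-wrapping hits). Conserved-segment weights are
#' scored (achieved / attainable); every segment — and the total — must
#' reach the descriptor's `min_score`, and all helix complementarity
#' constraints are hard requirements. Overlapping matches of the same
#' motif are merged to the best-scoring placement.
#'
#' @param circ one-row tibble with `id` and `monomer` (a bare character
#'   monomer is also accepted, id `"seq"`).
#' @param descriptor descriptor from [read_descriptor()].
#' @param strand `"+"` or `"-"`; minus-strand hits are reported in
#'   plus-strand coordinates.
#' @return tibble of hits: `contig_id`, `class`, `strand`, `start`, `end`,
#'   `score`, `cleavage_site`, `source`.
#' @export
scan_strand <- function(circ, descriptor, strand = "+") {
  if (is.character(circ)) circ <- tibble(id = "seq", monomer = circ)
  m <- circ$monomer
  L <- nchar(m)
  empty <- empty_hits()
  if (L < descriptor$min_span) return(empty)
  s <- if (strand == "+") m else revcomp(m)
  matches <- scan_doubled(s, descriptor)
  if (!nrow(matches)) return(empty)
  # map minus-strand coordinates back onto the plus strand
  if (strand == "-") {
    len <- matches$end - matches$start
    e <- matches$end
    matches$start <- ((L - e) %% L)
    matches$end <- matches$start + len
    matches$cleavage_site <- (L - 1L - matches$cleavage_site) %% L
  }
  tibble(
    contig_id = circ$id,
    class = descriptor$class,
    strand = strand,
    start = as.integer(matches$start),
    end = as.integer(matches$end),
    score = matches$score,
    cleavage_site = as.integer(matches$cleavage_site),
    source = "descriptor"
  )
}

empty_hits <- function() {
  tibble(contig_id = character(0), class = character(0), strand = character(0),
         start = integer(0), end = integer(0), score = numeric(0),
         cleavage_site = integer(0), source = character(0))
}

# core matcher on the doubled sequence; returns start/end/score/cleavage in
# 0-based coordinates with start in [0, L)
scan_doubled <- function(s, desc) {
  L <- nchar(s)
  d <- paste0(s, s)
  ch <- seq_chars(d)
  n <- length(ch)
  # per-segment position scores, vectorised over the doubled sequence
  seg_idx <- which(vapply(desc$elements, function(e) e$kind == "segment", TRUE))
  seg_scores <- list()
  for (i in seg_idx) {
    el <- desc$elements[[i]]
    w <- el$weights
    len <- length(w)
    npos <- n - len + 1L
    if (npos < 1L) return(data.frame())
    sc <- numeric(npos)
    for (j in seq_len(len)) {
      if (w[j] == 0) next
      sc <- sc + w[j] * (ch[j:(npos + j - 1L)] %in% IUPAC_SETS[[el$pattern[j]]])
    }
    seg_scores[[as.character(i)]] <- sc
  }
  first_seg <- seg_idx[1]
  el1 <- desc$elements[[first_seg]]
  sc1 <- seg_scores[[as.character(first_seg)]]
  anchors <- which(sc1 >= desc$min_score * sum(el1$weights)) - 1L  # 0-based
  if (!length(anchors)) return(data.frame())
  # candidate motif starts: anchor minus every feasible prefix length
  pre <- desc$elements[seq_len(first_seg - 1L)]
  offs <- 0L
  if (length(pre)) {
    offs <- Reduce(function(acc, el) {
      unique(as.vector(outer(acc, seq(el$min_len, el$max_len), `+`)))
    }, pre, init = 0L)
  }
  starts <- unique(as.vector(outer(anchors, offs, `-`)))
  starts <- starts[starts >= 0L & starts < L]
  if (!length(starts)) return(data.frame())

  match_from <- function(pos, eidx, helix_open, seg_sum) {
    # returns best completed match as list(score_w, end, elem_starts) or NULL
    if (eidx > length(desc$elements)) {
      return(list(score_w = seg_sum, end = pos, elem_starts = integer(0)))
    }
    el <- desc$elements[[eidx]]
    if (el$kind == "segment") {
      len <- el$min_len
      if (pos + len > n) return(NULL)
      sc <- seg_scores[[as.character(eidx)]][pos + 1L]
      if (is.na(sc) || sc < desc$min_score * sum(el$weights)) return(NULL)
      res <- match_from(pos + len, eidx + 1L, helix_open, seg_sum + sc)
      if (is.null(res)) return(NULL)
      res$elem_starts <- c(setNames(pos, el$name), res$elem_starts)
      return(res)
    }
    if (el$kind == "spacer") {
      best <- NULL
      for (l in seq(el$min_len, el$max_len)) {
        if (pos + l > n) break
        res <- match_from(pos + l, eidx + 1L, helix_open, seg_sum)
        if (!is.null(res) && (is.null(best) || res$score_w > best$score_w)) best <- res
      }
      if (!is.null(best)) best$elem_starts <- c(setNames(pos, el$name), best$elem_starts)
      return(best)
    }
    # helix: first occurrence opens the stem, second closes it
    hname <- el$helix
    if (is.null(helix_open[[hname]])) {
      best <- NULL
      for (l in seq(el$min_len, el$max_len)) {
        if (pos + l > n) break
        ho <- helix_open
        ho[[hname]] <- c(pos, l)
        res <- match_from(pos + l, eidx + 1L, ho, seg_sum)
        if (!is.null(res) && (is.null(best) || res$score_w > best$score_w)) best <- res
      }
      if (!is.null(best)) best$elem_starts <- c(setNames(pos, el$name), best$elem_starts)
      return(best)
    }
    op <- helix_open[[hname]]
    l <- op[2]
    if (pos + l > n) return(NULL)
    open_arm <- ch[(op[1] + 1L):(op[1] + l)]
    close_arm <- ch[(pos + 1L):(pos + l)]
    # antiparallel pairing: open[i] pairs close[l + 1 - i]; WC plus G.U
    pairs_ok <- all(open_arm %in% c("A", "C", "G", "T")) &&
      all(close_arm %in% c("A", "C", "G", "T")) &&
      all(DNA_PAIRS[cbind(open_arm, rev(close_arm))])
    if (!pairs_ok) return(NULL)
    res <- match_from(pos + l, eidx + 1L, helix_open, seg_sum)
    if (is.null(res)) return(NULL)
    res$elem_starts <- c(setNames(pos, el$name), res$elem_starts)
    res
  }

  hits <- list()
  for (st in sort(starts)) {
    res <- match_from(st, 1L, list(), 0)
    if (is.null(res)) next
    score <- res$score_w / desc$total_weight
    # summation order can leave the ratio a few ulp off 1 for exact matches
    if (abs(score - 1) < 1e-9) score <- 1
    if (score < desc$min_score) next
    cleav <- NA_integer_
    if (!is.null(desc$cleavage)) {
      cleav <- (res$elem_starts[[desc$cleavage$element]] + desc$cleavage$offset) %% L
    }
    hits[[length(hits) + 1L]] <- data.frame(start = st, end = res$end,
                                            score = score, cleavage_site = cleav)
  }
  if (!length(hits)) return(data.frame())
  hits <- do.call(rbind, hits)
  # merge overlapping placements of one motif: keep best score, then leftmost
  hits <- hits[order(-hits$score, hits$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(hits))) {
      if (j == i || !keep[j]) next
      if (spans_overlap_mod(hits$start[i], hits$end[i], hits$start[j], hits$end[j], L)) {
        keep[j] <- FALSE
      }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits[order(hits$start), , drop = FALSE]
}

# do two [start, end) spans overlap on a circle of length L?
spans_overlap_mod <- function(s1, e1, s2, e2, L) {
  iv1 <- if (e1 <= L) list(c(s1, e1)) else list(c(s1, L), c(0L, e1 - L))
  iv2 <- if (e2 <= L) list(c(s2, e2)) else list(c(s2, L), c(0L, e2 - L))
  for (a in iv1) for (b in iv2) {
    if (a[1] < b[2] && b[1] < a[2]) return(TRUE)
  }
  FALSE
}

#' Scan both polarities of circular monomers for all ribozyme classes
#'
#' @param circles tibble of circular contigs from [detect_circles()].
#' @param descriptors named list from [load_descriptors()].
#' @return tibble of hits (see [scan_strand()]).
#' @export
scan_ribozymes <- function(circles, descriptors = load_descriptors()) {
  out <- list(empty_hits())
  for (i in seq_len(nrow(circles))) {
    circ <- circles[i, ]
    for (desc in descriptors) {
      out[[length(out) + 1L]] <- scan_strand(circ, desc, "+")
      out[[length(out) + 1L]] <- scan_strand(circ, desc, "-")
    }
  }
  do.call(rbind, out)
}

#' Ingest ribozyme hits from an INFERNAL cmsearch tabular file
#'
#' Reads the `--tblout` dialect, filters by E-value, maps covariance-model
#' names to the five ribozyme classes, and converts coordinates to 0-based
#' half-open plus-strand spans. Strand is inferred from the coordinate
#' order (`seq from` > `seq to` means minus).
#'
#' @param path tblout file.
#' @param model_map named character vector mapping model names to classes
#'   (e.g. `c("RF00008" = "HHRz")`), or a two-column data frame
#'   (`model`, `class`).
#' @param evalue_max inclusion threshold; hits with E-value at or above it
#'   are dropped (default `1e-3`).
#' @return tibble of hits; `score` is `-log10(E) / 20` clamped into
#'   `[0, 1]`, `source` is `"cm_tabular"`.
#' @export
load_cm_hits <- function(path, model_map, evalue_max = 1e-3) {
  if (is.data.frame(model_map)) {
    model_map <- setNames(as.character(model_map$class), model_map$model)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & trimws(lines) != ""]
  out <- list(empty_hits())
  for (k in seq_along(lines)) {
    tok <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(tok) < 16L) stop("malformed tblout line ", k, " in ", path)
    target <- tok[1]
    model <- tok[3]
    from <- suppressWarnings(as.integer(tok[8]))
    to <- suppressWarnings(as.integer(tok[9]))
    evalue <- suppressWarnings(as.numeric(tok[16]))
    if (is.na(from) || is.na(to) || is.na(evalue)) {
      stop("malformed tblout line ", k, " in ", path)
    }
    if (evalue >= evalue_max) next
    if (!model %in% names(model_map)) {
      warning("tblout line ", k, ": model '", model, "' not in model map; skipped")
      next
    }
    strand <- if (from > to) "-" else "+"
    out[[length(out) + 1L]] <- tibble(
      contig_id = target,
      class = unname(model_map[model]),
      strand = strand,
      start = min(from, to) - 1L,
      end = max(from, to),
      score = min(1, -log10(max(evalue, 1e-300)) / 20),
      cleavage_site = NA_integer_,
      source = "cm_tabular"
    )
  }
  do.call(rbind, out)
}

#' Call ambisense ribozyme pairs from per-contig hits
#'
#' A candidate viroid-like circle must carry one self-cleaving motif on
#' each polarity strand. When several hits share a polarity the
#' highest-scoring one is used (ties broken by leftmost start). Mixed-class
#' pairs are allowed by default and labelled with the alphabetically
#' ordered combination (e.g. `"HHRz/HPRz"`); `same_class_only = TRUE`
#' restricts pairing to hits of one class on both polarities.
#'
#' @param hits tibble of hits for ONE contig.
#' @param same_class_only require both hits to come from the same class.
#' @return tibble with zero or one row: `contig_id`, `combo`,
#'   `plus_class`, `minus_class`, `plus_start`, `minus_start`,
#'   `plus_score`, `minus_score`, `orientation_note`.
#' @export
find_ambisense_pairs <- function(hits, same_class_only = FALSE) {
  empty <- tibble(contig_id = character(0), combo = character(0),
                  plus_class = character(0), minus_class = character(0),
                  plus_start = integer(0), minus_start = integer(0),
                  plus_score = numeric(0), minus_score = numeric(0),
                  orientation_note = character(0))
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  if (length(unique(hits$contig_id)) > 1L) {
    stop("find_ambisense_pairs expects hits from a single contig")
  }
  pick <- function(h) h[order(-h$score, h$start), ][1, ]
  plus <- hits[hits$strand == "+", ]
  minus <- hits[hits$strand == "-", ]
  if (nrow(plus) == 0L || nrow(minus) == 0L) return(empty)
  if (same_class_only) {
    shared <- intersect(plus$class, minus$class)
    if (!length(shared)) return(empty)
    cand <- lapply(sort(shared), function(cl) {
      p <- pick(plus[plus$class == cl, ])
      m <- pick(minus[minus$class == cl, ])
      list(p = p, m = m, s = p$score + m$score)
    })
    best <- cand[[which.max(vapply(cand, function(x) x$s, 0))]]
    p <- best$p
    m <- best$m
  } else {
    p <- pick(plus)
    m <- pick(minus)
  }
  combo <- paste(sort(c(p$class, m$class)), collapse = "/")
  note <- if (!is.na(p$cleavage_site) && !is.na(m$cleavage_site)) {
    sprintf("cleavage_plus=%d;cleavage_minus=%d", p$cleavage_site, m$cleavage_site)
  } else {
    "cleavage_sites_unavailable"
  }
  tibble(contig_id = p$contig_id, combo = combo,
         plus_class = p$class, minus_class = m$class,
         plus_start = p$start, minus_start = m$start,
         plus_score = p$score, minus_score = m$score,
         orientation_note = note)
}
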