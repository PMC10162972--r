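#' @name ribozyme-descriptors
#' @title Ribozyme descriptor format
#'
#' @description
#' Ribozyme motifs are described in a small plain-text block format, one
#' element per line, and matched by [scan_strand()]. The shipped descriptors
#' (in `inst/extdata/ribozymes/`) are simplified approximations of the five
#' self-cleaving ribozyme classes found in viroid-like circular RNAs —
#' hammerhead (HHRz), hairpin (HPRz), delta (DVRz), twister (TWRz) and
#' Varkud satellite (VSRz). They combine the conserved catalytic nucleotides
#' of each class with its helical architecture, but are not covariance
#' models: users with INFERNAL results should ingest them via
#' [load_cm_hits()] instead.
#'
#' File syntax (`#` starts a comment):
#' \preformatted{
#' class HHRz
#' min_score 0.7
#' element core1 segment CUGAUGA 1,1,1,1,0.2,1,1
#' element H2o   helix  H2 6 7
#' element L2    spacer 3 6
#' element H2c   helix  H2 6 7
#' cleavage core1 4
#' }
#' `segment` elements carry an IUPAC pattern with per-position weights and
#' are scored; `helix` elements come in named pairs whose two arms must be
#' complementary (Watson-Crick plus G-U wobble) at equal chosen length
#' within the stated range; `spacer` elements match any sequence within a
#' length range. A hit requires every segment to reach `min_score` of its
#' attainable weight (and the total likewise) while all helix constraints
#' hold; helix complementarity is a hard requirement, never scored.
NULL

DNA_PAIRS <- matrix(FALSE, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
DNA_PAIRS["A","T"] <- DNA_PAIRS["T","A"] <- TRUE
DNA_PAIRS["G","C"] <- DNA_PAIRS["C","G"] <- TRUE
DNA_PAIRS["G","T"] <- DNA_PAIRS["T","G"] <- TRUE  # wobble

#' Parse a ribozyme descriptor file
#'
#' See \link{ribozyme-descriptors} for the format.
#'
#' @param path descriptor file path.
#' @return a validated descriptor object (list with `class`, `min_score`,
#'   `elements`, `cleavage`, `min_span`, `max_span`).
#' @export
read_descriptor <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[lines != ""]
  desc <- list(class = NULL, min_score = NULL, elements = list(), cleavage = NULL)
  for (ln in lines) {
    tok <- strsplit(ln, "\\s+")[[1]]
    key <- tok[1]
    if (key == "class") {
      desc$class <- tok[2]
    } else if (key == "min_score") {
      desc$min_score <- as.numeric(tok[2])
    } else if (key == "element") {
      name <- tok[2]; kind <- tok[3]
      el <- switch(kind,
        segment = {
          pat <- toupper(gsub("U", "T", tok[4]))
          w <- as.numeric(strsplit(tok[5], ",")[[1]])
          if (length(w) != nchar(pat)) {
            stop("descriptor ", path, ": segment '", name, "' weight count != pattern length")
          }
          list(kind = "segment", name = name, pattern = seq_chars(pat), weights = w,
               min_len = nchar(pat), max_len = nchar(pat))
        },
        helix = list(kind = "helix", name = name, helix = tok[4],
                     min_len = as.integer(tok[5]), max_len = as.integer(tok[6])),
        spacer = list(kind = "spacer", name = name,
                      min_len = as.integer(tok[4]), max_len = as.integer(tok[5])),
        stop("descriptor ", path, ": unknown element kind '", kind, "'")
      )
      desc$elements[[length(desc$elements) + 1L]] <- el
    } else if (key == "cleavage") {
      desc$cleavage <- list(element = tok[2], offset = as.integer(tok[3]))
    } else {
      stop("descriptor ", path, ": unknown directive '", key, "'")
    }
  }
  validate_descriptor(desc, path)
}

validate_descriptor <- function(desc, path = "<descriptor>") {
  if (is.null(desc$class)) stop(path, ": missing class")
  if (is.null(desc$min_score) || desc$min_score <= 0 || desc$min_score > 1) {
    stop(path, ": min_score must be in (0, 1]")
  }
  if (!length(desc$elements)) stop(path, ": no elements")
  helix_counts <- table(vapply(Filter(function(e) e$kind == "helix", desc$elements),
                               function(e) e$helix, ""))
  if (length(helix_counts) && any(helix_counts != 2L)) {
    stop(path, ": every helix name must occur exactly twice")
  }
  segs <- Filter(function(e) e$kind == "segment", desc$elements)
  if (!length(segs)) stop(path, ": at least one segment element required")
  if (any(vapply(segs, function(e) any(e$weights < 0), TRUE))) {
    stop(path, ": negative segment weights")
  }
  if (!is.null(desc$cleavage)) {
    nm <- vapply(desc$elements, function(e) e$name, "")
    if (!desc$cleavage$element %in% nm) stop(path, ": cleavage references unknown element")
  }
  desc$min_span <- sum(vapply(desc$elements, function(e) e$min_len, 0L))
  desc$max_span <- sum(vapply(desc$elements, function(e) e$max_len, 0L))
  desc$total_weight <- sum(vapply(segs, function(e) sum(e$weights), 0))
  desc
}

#' Load a directory of ribozyme descriptors
#'
#' @param dir directory containing `*.txt` descriptor files; defaults to the
#'   descriptors shipped with the package.
#' @return named list of descriptors (by class).
#' @export
load_descriptors <- function(dir = system.file("extdata", "ribozymes", package = "viroidscan")) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  ds <- lapply(files, read_descriptor)
  setNames(ds, vapply(ds, function(d) d$class, ""))
}

#' Instantiate a concrete motif sequence from a descriptor
#'
#' Samples one realisation of the motif: consensus (highest-weight matching)
#' bases for segments, random complementary arms for helices, random spacer
#' fill. Used by the synthetic-data generator to plant motifs with known
#' truth. Optionally substitutes `n_subst` of the lowest-weight segment
#' positions so that scored recovery below 1.0 can be exercised.
#'
#' @param desc descriptor from [read_descriptor()].
#' @param n_subst number of low-weight segment positions to substitute
#'   (default 0).
#' @return list with `seq` (the concrete motif, DNA alphabet) and
#'   `cleavage_offset` (0-based offset of the cleavage site within `seq`,
#'   or `NA`).
#' @export
instantiate_motif <- function(desc, n_subst = 0L) {
  helix_seqs <- list()
  parts <- character(length(desc$elements))
  starts <- integer(length(desc$elements))
  pos <- 0L
  seg_positions <- list()  # element idx -> offsets+weights for substitution
  for (i in seq_along(desc$elements)) {
    el <- desc$elements[[i]]
    starts[i] <- pos
    if (el$kind == "segment") {
      bases <- vapply(el$pattern, function(p) {
        s <- IUPAC_SETS[[p]]
        s[sample.int(length(s), 1L)]
      }, "")
      parts[i] <- paste(bases, collapse = "")
      seg_positions[[length(seg_positions) + 1L]] <- list(idx = i, weights = el$weights)
    } else if (el$kind == "helix") {
      l <- sample(seq(el$min_len, el$max_len), 1L)
      if (is.null(helix_seqs[[el$helix]])) {
        arm <- random_seq(l)
        helix_seqs[[el$helix]] <- arm
        parts[i] <- arm
      } else {
        parts[i] <- revcomp(helix_seqs[[el$helix]])
      }
    } else {
      parts[i] <- random_seq(sample(seq(el$min_len, el$max_len), 1L))
    }
    pos <- pos + nchar(parts[i])
  }
  # recompute starts now that variable lengths are fixed
  lens <- nchar(parts)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  if (n_subst > 0L) {
    # substitute the globally lowest-weight segment positions
    cand <- do.call(rbind, lapply(seg_positions, function(sp) {
      cbind(elem = sp$idx, off = seq_along(sp$weights) - 1L, w = sp$weights)
    }))
    cand <- cand[order(cand[, "w"]), , drop = FALSE]
    for (j in seq_len(min(n_subst, nrow(cand)))) {
      ei <- cand[j, "elem"]; off <- cand[j, "off"]
      old <- substr(parts[ei], off + 1L, off + 1L)
      allowed <- IUPAC_SETS[[desc$elements[[ei]]$pattern[off + 1L]]]
      repl <- setdiff(c("A", "C", "G", "T"), allowed)
      if (!length(repl)) repl <- setdiff(c("A", "C", "G", "T"), old)
      parts[ei] <- paste0(substr(parts[ei], 1L, off),
                          repl[sample.int(length(repl), 1L)],
                          substr(parts[ei], off + 2L, nchar(parts[ei])))
    }
  }
  cleav <- NA_integer_
  if (!is.null(desc$cleavage)) {
    nm <- vapply(desc$elements, function(e) e$name, "")
    ei <- which(nm == desc$cleavage$element)[1]
    cleav <- starts[ei] + desc$cleavage$offset
  }
  list(seq = paste(parts, collapse = ""), cleavage_offset = cleav)
}
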