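#' Parse a dot-bracket secondary structure
#'
#' @param structure string over `(`, `)`, `.`.
#' @return integer vector `partner` of the structure's length: 0-based
#'   partner position for paired bases, `NA` for unpaired.
#' @export
parse_dotbracket <- function(structure) {
  ch <- seq_chars(structure)
  bad <- which(!ch %in% c("(", ")", "."))
  if (length(bad)) {
    stop("invalid structure character '", ch[bad[1]], "' at position ", bad[1])
  }
  n <- length(ch)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j - 1L
      partner[j] <- i - 1L
    }
  }
  if (length(stack)) stop("unbalanced '(' at position ", stack[length(stack)])
  partner
}

# helix-level tree of a structure: each node is an outermost pair (i, j)
# (0-based) whose children are the outermost pairs directly inside it.
# Returns list(children = list by node id, span = 2-col matrix, roots).
structure_tree <- function(partner) {
  n <- length(partner)
  nodes <- list()
  spans <- NULL
  roots <- integer(0)
  # collect_children over [from, to] 0-based inclusive; returns node ids
  collect <- function(from, to) {
    ids <- integer(0)
    i <- from
    while (i <= to) {
      p <- partner[i + 1L]
      if (!is.na(p) && p > i) {
        # new node: descend through the stacked helix to its loop
        a <- i; b <- p
        while (a + 1L < b && !is.na(partner[a + 2L]) && partner[a + 2L] == b - 1L) {
          a <- a + 1L; b <- b - 1L
        }
        id <- length(nodes) + 1L
        nodes[[id]] <<- integer(0)           # placeholder
        spans <<- rbind(spans, c(i, p))
        kids <- if (a + 1L <= b - 1L) collect(a + 1L, b - 1L) else integer(0)
        nodes[[id]] <<- kids
        ids <- c(ids, id)
        i <- p + 1L
      } else {
        i <- i + 1L
      }
    }
    ids
  }
  if (n > 0L) roots <- collect(0L, n - 1L)
  list(children = nodes, span = spans, roots = roots)
}

#' Classify a secondary structure as rod, quasi-rod, or branched
#'
#' Terminal loops are hairpin loops plus, for circular molecules, the
#' exterior loop (a perfect circular rod has exactly two terminal
#' loops). The classes are:
#' \describe{
#'   \item{rod}{exactly two terminal loops and no loop with two or more
#'     branching helices.}
#'   \item{quasi-rod}{a rod backbone once every side helix subtree of
#'     span at most `side_hairpin_max` nt is pruned: at each internal
#'     branching loop the largest subtree continues the backbone and all
#'     other subtrees must be prunable. Extra helices on the exterior
#'     loop are never prunable: a rod passes through the exterior as a
#'     single backbone.}
#'   \item{branched}{anything else (including structures with no pairs).}
#' }
#'
#' @param structure dot-bracket string.
#' @param circular treat the molecule as circular (default TRUE): the
#'   exterior loop counts as a terminal loop and as a branching loop.
#' @param side_hairpin_max largest side-subtree span (nt) tolerated in a
#'   quasi-rod (default 30).
#' @return list with `class`, `terminal_loop_count`,
#'   `max_multiloop_degree` (largest number of branching helices in any
#'   loop, exterior included when circular), `paired_fraction`.
#' @export
classify_fold <- function(structure, circular = TRUE, side_hairpin_max = 30L) {
  partner <- parse_dotbracket(structure)
  n <- length(partner)
  tree <- structure_tree(partner)
  n_nodes <- length(tree$children)
  hairpins <- if (n_nodes) sum(lengths(tree$children) == 0L) else 0L
  terminal <- hairpins + as.integer(circular)
  degrees <- lengths(tree$children)                  # branching helices per internal loop
  if (circular) degrees <- c(degrees, length(tree$roots))
  max_degree <- if (length(degrees)) max(degrees) else 0L
  paired_fraction <- if (n) sum(!is.na(partner)) / n else 0
  res <- list(
    terminal_loop_count = terminal,
    max_multiloop_degree = max_degree,
    paired_fraction = paired_fraction
  )
  if (n_nodes == 0L) {
    res$class <- "branched"
    return(res)
  }
  span_len <- tree$span[, 2L] - tree$span[, 1L] + 1L
  # walk the backbone from the exterior: at each internal loop the
  # largest-span subtree continues and the rest must be prunable side
  # subtrees; extra helices on the exterior loop are never prunable (a
  # rod has a single backbone through the exterior)
  prunable_only <- length(tree$roots) == 1L
  any_pruned <- FALSE
  kids <- if (prunable_only) tree$children[[tree$roots]] else integer(0)
  while (length(kids)) {
    main <- kids[which.max(span_len[kids])]
    side <- setdiff(kids, main)
    if (length(side)) {
      any_pruned <- TRUE
      if (any(span_len[side] > side_hairpin_max)) {
        prunable_only <- FALSE
        break
      }
    }
    kids <- tree$children[[main]]
  }
  res$class <- if (!prunable_only) {
    "branched"
  } else if (!any_pruned && terminal <= 2L) {
    "rod"
  } else {
    "quasi-rod"
  }
  res
}

#' Fold a sequence by base-pair maximization (test-scale fallback)
#'
#' A deterministic Nussinov-style folder: maximizes the number of
#' base pairs (Watson-Crick plus G-U wobble) with a minimum hairpin loop
#' size, with a leftmost-partner traceback tie-break. This is a
#' test-scale fallback so the fold classifier is exercisable without an
#' external thermodynamic folder; it is not a minimum-free-energy
#' predictor.
#'
#' @param seq nucleotide string (DNA alphabet; U accepted).
#' @param min_loop minimum unpaired bases in a hairpin loop (default 3).
#' @param max_length refuse sequences longer than this (default 1500).
#' @return dot-bracket string of the same length.
#' @export
nussinov_fold <- function(seq, min_loop = 3L, max_length = 1500L) {
  s <- toupper(gsub("U", "T", seq, fixed = TRUE))
  if (nchar(s) > max_length) {
    stop("sequence of length ", nchar(s), " exceeds the fallback folder cap (",
         max_length, " nt); supply an external structure instead")
  }
  nussinov_cpp(s, as.integer(min_loop))
}
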