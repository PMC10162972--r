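#' Generate a circular genome with planted features
#'
#' Builds a monomer of exactly `length` nt containing, as requested: a
#' ribozyme motif on the plus strand, a ribozyme motif on the minus
#' strand (embedded as its reverse complement), and an open reading
#' frame whose protein carries the RdRp palmprint motifs A, B and C.
#' Remaining space is filled with i.i.d. uniform background, or with a
#' pair of complementary arms when `rod_bias` is on (first arm from
#' {A,G}, second arm its reverse complement, separated by short loop
#' linkers) so that base-pair maximization folds the molecule into a
#' rod. Note that rod-biased backgrounds are, by construction, one long
#' inverted self-repeat and will trip the dispersed-repeat mask.
#'
#' @param length monomer length in nt.
#' @param ribozyme_plus,ribozyme_minus ribozyme class name (e.g.
#'   `"HHRz"`) or NULL to plant none.
#' @param with_orf plant a palmprint-bearing ORF on the plus strand.
#' @param rod_bias complementary-arm background (default FALSE).
#' @param n_subst low-weight substitutions applied to each planted
#'   ribozyme motif (default 0).
#' @param seed optional seed; when given, generation runs under
#'   [withr::with_seed()].
#' @param descriptors,palm_models motif sources (default: shipped).
#' @return list with `monomer` and `truth` (planted element classes,
#'   0-based spans on the monomer, cleavage sites, ORF span and protein,
#'   palmprint string).
#' @export
make_circular_genome <- function(length, ribozyme_plus = NULL, ribozyme_minus = NULL,
                                 with_orf = FALSE, rod_bias = FALSE, n_subst = 0L,
                                 seed = NULL, descriptors = load_descriptors(),
                                 palm_models = load_palm_models()) {
  build <- function() {
    elements <- list()
    truth <- list(rod_bias = rod_bias)
    if (!is.null(ribozyme_plus)) {
      d <- descriptors[[ribozyme_plus]]
      if (is.null(d)) stop("unknown ribozyme class: ", ribozyme_plus)
      m <- instantiate_motif(d, n_subst)
      elements$rz_plus <- list(seq = m$seq, meta = list(
        class = ribozyme_plus, cleavage_offset = m$cleavage_offset))
    }
    if (!is.null(ribozyme_minus)) {
      d <- descriptors[[ribozyme_minus]]
      if (is.null(d)) stop("unknown ribozyme class: ", ribozyme_minus)
      m <- instantiate_motif(d, n_subst)
      elements$rz_minus <- list(seq = revcomp(m$seq), meta = list(
        class = ribozyme_minus, cleavage_offset = m$cleavage_offset))
    }
    if (with_orf) {
      orf <- plant_palm_orf(palm_models)
      elements$orf <- list(seq = orf$nt, meta = orf)
    }
    fixed <- sum(vapply(elements, function(e) nchar(e$seq), 0))
    n_gaps <- max(1L, base::length(elements))
    min_gap <- 12L
    free <- length - fixed
    if (free < n_gaps * min_gap) {
      stop("infeasible packing: planted elements need ", fixed + n_gaps * min_gap,
           " nt but genome length is ", length)
    }
    # split the free space into one gap after each element (plus a
    # leading gap when there are no elements)
    extra <- free - n_gaps * min_gap
    cuts <- if (n_gaps > 1L) sort(sample.int(extra + 1L, n_gaps - 1L, replace = TRUE) - 1L) else integer(0)
    gap_len <- diff(c(0L, cuts, extra)) + min_gap
    if (rod_bias) {
      # the largest gap hosts the paired arms: arm + loop + revcomp(arm)
      gi <- which.max(gap_len)
      glen <- gap_len[gi]
      arm_len <- (glen - 5L) %/% 2L
      arm <- random_seq(arm_len, alphabet = c("A", "G"))
      arm_fill <- paste0(arm, random_seq(glen - 2L * arm_len, alphabet = c("T", "C")),
                         revcomp(arm))
    }
    parts <- character(0)
    pos <- 0L
    spans <- list()
    for (i in seq_len(n_gaps)) {
      if (base::length(elements)) {
        el <- elements[[i]]
        nm <- names(elements)[i]
        spans[[nm]] <- c(pos, pos + nchar(el$seq))
        parts <- c(parts, el$seq)
        pos <- pos + nchar(el$seq)
      }
      g <- if (rod_bias && i == gi) arm_fill else random_seq(gap_len[i])
      parts <- c(parts, g)
      pos <- pos + nchar(g)
    }
    monomer <- paste(parts, collapse = "")
    stopifnot(nchar(monomer) == length)
    L <- length
    if (!is.null(elements$rz_plus)) {
      sp <- spans$rz_plus
      truth$rz_plus <- list(
        class = elements$rz_plus$meta$class, start = sp[1], end = sp[2],
        cleavage = if (is.na(elements$rz_plus$meta$cleavage_offset)) NA_integer_
                   else sp[1] + elements$rz_plus$meta$cleavage_offset)
    }
    if (!is.null(elements$rz_minus)) {
      sp <- spans$rz_minus
      truth$rz_minus <- list(
        class = elements$rz_minus$meta$class, start = sp[1], end = sp[2],
        cleavage = if (is.na(elements$rz_minus$meta$cleavage_offset)) NA_integer_
                   else sp[2] - 1L - elements$rz_minus$meta$cleavage_offset)
    }
    if (with_orf) {
      sp <- spans$orf
      truth$orf <- list(
        start = sp[1] + 3L, end = sp[2] - 3L,   # inner span, stops excluded
        aa = elements$orf$meta$aa, palmprint = elements$orf$meta$palmprint)
    }
    list(monomer = monomer, truth = truth)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# synthesize a stop-to-stop ORF whose protein carries the palmprint
# motifs A, B, C of the given models (consensus residues), with random
# non-catalytic filler; returns nt (including flanking stop codons), aa,
# and the palmprint substring
plant_palm_orf <- function(models, pad = c(30L, 30L)) {
  consensus <- function(m) {
    vapply(m$weights, function(w) names(w)[which.max(w)], "")
  }
  filler_alphabet <- setdiff(names(CODON_FOR_AA), c("*", "D", "G", "M"))
  filler <- function(n) sample(filler_alphabet, n, replace = TRUE)
  gab <- models$gaps[["A->B"]]; gbc <- models$gaps[["B->C"]]
  g1 <- sample(seq(gab$min, gab$max), 1L)
  g2 <- sample(seq(gbc$min, gbc$max), 1L)
  aa_chars <- c("M", filler(pad[1]), consensus(models$motifs$A), filler(g1),
                consensus(models$motifs$B), filler(g2), consensus(models$motifs$C),
                filler(pad[2]))
  aa <- paste(aa_chars, collapse = "")
  nt <- paste0(CODON_FOR_AA[["*"]],
               paste(CODON_FOR_AA[aa_chars], collapse = ""),
               CODON_FOR_AA[["*"]])
  a0 <- 1L + pad[1]
  c_end <- a0 + models$motifs$A$width + g1 + models$motifs$B$width + g2 +
    models$motifs$C$width
  list(nt = nt, aa = aa, palmprint = substr(aa, a0 + 1L, c_end))
}

#' Linearize a circular monomer into an assembler-style contig
#'
#' The contig is the monomer rotated by `rotation`, repeated `copies`
#' times (rolling-circle concatemer), with its first `r` nt appended as
#' the terminal repeat. Optional substitutions are applied afterwards.
#'
#' @param monomer monomer string.
#' @param rotation left rotation offset in nt.
#' @param r terminal repeat length (>= 1).
#' @param copies monomer copies (>= 1).
#' @param substitution_rate per-base substitution probability applied to
#'   the finished contig (default 0).
#' @param id contig id (default `"contig"`).
#' @param seed optional seed (see [make_circular_genome()]).
#' @return one-row tibble with `id`, `sequence`, `length`.
#' @export
make_contig <- function(monomer, rotation = 0L, r = 50L, copies = 1L,
                        substitution_rate = 0, id = "contig", seed = NULL) {
  build <- function() {
    if (r < 1L || r > nchar(monomer)) {
      stop("terminal repeat length ", r, " outside [1, monomer length]")
    }
    if (copies < 1L) stop("copies must be >= 1")
    rot <- rotate(monomer, rotation %% nchar(monomer))
    s <- paste0(strrep(rot, copies), substr(rot, 1L, r))
    if (substitution_rate > 0) {
      ch <- seq_chars(s)
      hit <- which(stats::runif(base::length(ch)) < substitution_rate)
      for (i in hit) {
        ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
      }
      s <- paste(ch, collapse = "")
    }
    tibble(id = id, sequence = s, length = nchar(s))
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Generate a seeded synthetic contig set with planted truth
#'
#' Default composition: 50 circles with paired ambisense ribozymes (the
#' intended candidates; lengths drawn across the size classes, larger
#' genomes carrying palmprint ORFs), 20 linear decoys, 15 circles with a
#' ribozyme on one polarity only, and 15 circles more than 30%
#' repetitive. Regeneration with the same seed is byte-identical.
#'
#' @param spec named list of counts: `n_true`, `n_linear`,
#'   `n_single_rz`, `n_repetitive`.
#' @param seed integer seed (default 42).
#' @param descriptors,palm_models motif sources (default: shipped).
#' @return list with `contigs` (tibble: `id`, `sequence`, `length`) and
#'   `truth` (one row per contig: planted monomer, rotation, repeat
#'   length, copies, ribozyme classes and starts, combo label, ORF span,
#'   palmprint, repeat design and the intended pipeline outcome).
#' @export
make_dataset <- function(spec = list(), seed = 42L,
                         descriptors = load_descriptors(),
                         palm_models = load_palm_models()) {
  spec <- utils::modifyList(
    list(n_true = 50L, n_linear = 20L, n_single_rz = 15L, n_repetitive = 15L),
    spec)
  withr::with_seed(as.integer(seed), {
    classes <- names(descriptors)
    contigs <- list()
    truth <- list()
    add <- function(contig, tr) {
      contigs[[base::length(contigs) + 1L]] <<- contig
      truth[[base::length(truth) + 1L]] <<- tr
    }
    truth_row <- function(id, kind, expected, monomer = NA_character_,
                          rotation = NA_integer_, r = NA_integer_,
                          copies = NA_integer_, rz_plus = NA_character_,
                          rz_plus_start = NA_integer_, rz_minus = NA_character_,
                          rz_minus_start = NA_integer_, has_orf = FALSE,
                          orf_start = NA_integer_, orf_end = NA_integer_,
                          palmprint = NA_character_, repeat_design = NA_character_) {
      combo <- if (!is.na(rz_plus) && !is.na(rz_minus)) {
        paste(sort(c(rz_plus, rz_minus)), collapse = "/")
      } else NA_character_
      tibble(
        id = id, kind = kind, expected = expected, monomer = monomer,
        monomer_length = ifelse(is.na(monomer), NA_integer_, nchar(monomer)),
        rotation = rotation, r = r, copies = copies,
        rz_plus = rz_plus, rz_plus_start = rz_plus_start,
        rz_minus = rz_minus, rz_minus_start = rz_minus_start, combo = combo,
        has_orf = has_orf, orf_start = orf_start, orf_end = orf_end,
        palmprint = palmprint, repeat_design = repeat_design
      )
    }
    size_ranges <- list(c(260L, 799L), c(800L, 1199L), c(1200L, 2199L),
                        c(2200L, 3999L), c(4000L, 5000L))
    size_probs <- c(0.71, 0.16, 0.10, 0.007, 0.033)
    sample_length <- function() {
      k <- sample.int(5L, 1L, prob = size_probs)
      rg <- size_ranges[[k]]
      sample(seq(rg[1], rg[2]), 1L)
    }
    plant_circle <- function(id, kind, expected, single = FALSE,
                             repetitive = FALSE) {
      len <- sample_length()
      rp <- sample(classes, 1L)
      rm <- if (single) NULL else sample(classes, 1L)
      with_orf <- !repetitive && len >= 2200L
      if (repetitive) {
        # fixed layout so the ~35% tandem array always fits, interior to
        # the monomer and clear of the motifs: rz+ | rc(rz-) | array |
        # uniform background (rotation kept at 0)
        len <- max(len, 450L)
        m1 <- instantiate_motif(descriptors[[rp]])
        m2 <- instantiate_motif(descriptors[[rm]])
        arr_len <- ceiling(0.35 * len)
        unit <- random_seq(8L)
        arr <- substr(strrep(unit, ceiling(arr_len / 8L) + 1L), 1L, arr_len)
        head_len <- nchar(m1$seq) + 12L + nchar(m2$seq) + 12L
        rest <- len - head_len - arr_len
        stopifnot(rest >= 10L)
        g <- list(
          monomer = paste0(m1$seq, random_seq(12L), revcomp(m2$seq),
                           random_seq(12L), arr, random_seq(rest)),
          truth = list(
            rz_plus = list(class = rp, start = 0L, end = nchar(m1$seq)),
            rz_minus = list(class = rm, start = nchar(m1$seq) + 12L,
                            end = nchar(m1$seq) + 12L + nchar(m2$seq))
          )
        )
        rotation <- 0L
      } else {
        g <- make_circular_genome(len, rp, rm, with_orf = with_orf,
                                  descriptors = descriptors,
                                  palm_models = palm_models)
        rotation <- sample.int(len, 1L) - 1L
      }
      r <- sample(25:120, 1L)
      copies <- if (!repetitive && stats::runif(1) < 0.1) 2L else 1L
      contig <- make_contig(g$monomer, rotation = rotation, r = r,
                            copies = copies, id = id)
      add(contig, truth_row(
        id, kind, expected, monomer = g$monomer, rotation = rotation, r = r,
        copies = copies,
        rz_plus = g$truth$rz_plus$class, rz_plus_start = g$truth$rz_plus$start,
        rz_minus = if (single) NA_character_ else g$truth$rz_minus$class,
        rz_minus_start = if (single) NA_integer_ else g$truth$rz_minus$start,
        has_orf = with_orf,
        orf_start = if (with_orf) g$truth$orf$start else NA_integer_,
        orf_end = if (with_orf) g$truth$orf$end else NA_integer_,
        palmprint = if (with_orf) g$truth$orf$palmprint else NA_character_,
        repeat_design = if (repetitive) "tandem array, 35% of monomer" else "none"
      ))
    }
    for (i in seq_len(spec$n_true)) {
      plant_circle(sprintf("true_circle_%02d", i), "true_circle", "candidate")
    }
    for (i in seq_len(spec$n_linear)) {
      id <- sprintf("linear_decoy_%02d", i)
      len <- sample_length()
      add(tibble(id = id, sequence = random_seq(len), length = len),
          truth_row(id, "linear_decoy", "rejected:not_circular"))
    }
    for (i in seq_len(spec$n_single_rz)) {
      plant_circle(sprintf("single_rz_%02d", i), "single_ribozyme",
                   "rejected:no_ribozyme_pair", single = TRUE)
    }
    for (i in seq_len(spec$n_repetitive)) {
      plant_circle(sprintf("repetitive_%02d", i), "repetitive",
                   "rejected:repetitive", repetitive = TRUE)
    }
    list(contigs = do.call(rbind, contigs), truth = do.call(rbind, truth))
  })
}
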