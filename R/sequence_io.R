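#' Read assembled contigs from a FASTA file
#'
#' Sequences are uppercased and RNA `U` is normalised to the internal DNA
#' alphabet (`T`); IUPAC ambiguity codes are retained as-is. Record order is
#' preserved.
#'
#' @param path path to a FASTA file (wrapped or unwrapped records).
#' @return a tibble with columns `id`, `sequence`, `length` — one row per
#'   contig.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(tibble(id = character(0), sequence = character(0), length = integer(0)))
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("malformed FASTA: record ", which(ids == "")[1], " has an empty header")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in FASTA: ", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (any(nchar(seqs) == 0L)) {
    stop("malformed FASTA: record '", ids[nchar(seqs) == 0L][1], "' has an empty sequence")
  }
  bad <- regexpr(paste0("[^", paste(IUPAC_LETTERS, collapse = ""), "]"), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop("non-IUPAC character in record '", ids[i], "' at position ", bad[i])
  }
  tibble(id = ids, sequence = unname(seqs), length = unname(nchar(seqs)))
}

#' Write contigs to a FASTA file
#'
#' @param contigs tibble with `id` and either `sequence` or `monomer` column.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(contigs, path, width = 70L) {
  seq_col <- if ("sequence" %in% names(contigs)) "sequence" else "monomer"
  set <- Biostrings::BStringSet(setNames(contigs[[seq_col]], contigs$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write annotation records as GFF3
#'
#' Internal coordinates are 0-based half-open; GFF3 columns 4/5 are written
#' 1-based inclusive. Features wrapping the monomer origin carry their raw
#' (possibly beyond-length) end in the attributes and are flagged
#' `wraps_origin=true`.
#'
#' @param records tibble with columns `contig_id`, `type`, `start`, `end`,
#'   `strand`, `score` and optionally `attributes` (character, already
#'   `key=value;...` formatted) and `source`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (is.null(records) || nrow(records) == 0L) return(invisible(path))
  src <- if ("source" %in% names(records)) records$source else rep("viroidscan", nrow(records))
  attrs <- if ("attributes" %in% names(records)) records$attributes else rep(".", nrow(records))
  attrs[is.na(attrs) | attrs == ""] <- "."
  score <- ifelse(is.na(records$score), ".", formatC(records$score, format = "g"))
  lines <- paste(records$contig_id, src, records$type,
                 records$start + 1L, records$end,
                 score, records$strand, ".", attrs, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write a table as TSV with a header row
#'
#' @param table data frame or tibble.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reverse complement of an IUPAC nucleotide sequence
#'
#' Ambiguity codes are complemented correctly (e.g. `R` -> `Y`).
#'
#' @param seq character scalar over the IUPAC alphabet.
#' @return the reverse complement, same length.
#' @export
revcomp <- function(seq) {
  if (nchar(seq) == 0L) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
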