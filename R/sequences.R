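#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Internal convention: all coordinates are 0-based, half-open [start, end).
# 1-based inclusive coordinates appear only in human-readable reports and are
# flagged as such there.

VALID_DNA <- "ACGTNRYSWKMBDHV"

assert_dna <- function(seq, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", VALID_DNA), toupper(seq))
  if (any(bad)) {
    abort(sprintf(
      "%s contains non-nucleotide characters (first offender: %s)",
      what, seq[which(bad)[1]]
    ))
  }
  invisible(TRUE)
}

#' Build a labeled-sequence tibble
#'
#' The unit consumed by every scanner and aligner in the package: a DNA
#' string with an identifier and the 0-based offset of the slice on its
#' parent sequence.
#'
#' @param id Character vector of sequence identifiers.
#' @param seq Character vector of DNA strings over `A,C,G,T,N` (IUPAC
#'   ambiguity codes tolerated); case-insensitive on input, stored uppercase.
#' @param offset Integer vector, 0-based start of each slice on its parent.
#' @return A tibble with columns `id`, `seq`, `offset`.
#' @export
#' @examples
#' labeled_seq("chr", "acgtACGT")
labeled_seq <- function(id, seq, offset = 0L) {
  seq <- toupper(seq)
  if (any(nchar(seq) < 1L)) abort("sequences must have length >= 1")
  if (any(offset < 0L)) abort("offset must be >= 0")
  assert_dna(seq)
  tibble(id = as.character(id), seq = seq, offset = as.integer(offset))
}

#' Read a FASTA file into a labeled-sequence tibble
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A tibble with columns `id`, `seq`, `offset` (always 0), one row
#'   per record, in file order, sequences uppercased.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id: %s", ids[anyDuplicated(ids)]))
  }
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    if (grepl(sprintf("[^%s]", VALID_DNA), seqs[[i]])) {
      abort(sprintf("record '%s' contains non-nucleotide characters", ids[[i]]))
    }
  }
  labeled_seq(ids, unname(seqs))
}

#' Write a labeled-sequence tibble to FASTA
#'
#' @param seqs Tibble as returned by [labeled_seq()].
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(seqs$seq)
  names(set) <- seqs$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of DNA strings
#'
#' Vectorized; `N` maps to `N`, IUPAC ambiguity codes to their complements.
#'
#' @param s Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ATGAACTAGTTCAT") # a perfect palindrome returns itself
revcomp <- function(s) {
  assert_dna(s)
  rc1 <- function(x) intToUtf8(rev(utf8ToInt(chartr(
    "ACGTNRYSWKMBDHVacgtnryswkmbdhv",
    "TGCANYRSWMKVHDBTGCANYRSWMKVHDB", x
  ))))
  vapply(toupper(s), rc1, character(1), USE.NAMES = FALSE)
}

#' GC content of DNA strings
#'
#' @param s Character vector of DNA strings.
#' @return Fraction of G+C among unambiguous (non-N) bases.
#' @export
gc_content <- function(s) {
  s <- toupper(s)
  gc <- nchar(gsub("[^GC]", "", s))
  acgt <- nchar(gsub("[^ACGT]", "", s))
  gc / acgt
}

#' Construct an interval tibble
#'
#' 0-based half-open intervals; `length = end - start`.
#'
#' @param seq_id Sequence identifier.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @param strand `"+"` or `"-"`.
#' @param name Optional feature name (used in BED output).
#' @return Tibble with columns `seq_id`, `start`, `end`, `strand`, `name`.
#' @export
interval <- function(seq_id, start, end, strand = "+", name = ".") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L)) abort("interval start must be >= 0")
  if (any(end <= start)) abort("interval must satisfy start < end")
  if (!all(strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  tibble(
    seq_id = as.character(seq_id), start = start, end = end,
    strand = as.character(strand), name = as.character(name)
  )
}

#' Extract the subsequence covered by an interval
#'
#' @param seqs Labeled-sequence tibble.
#' @param iv Single-row interval tibble.
#' @return The covered DNA string; reverse-complemented when `strand == "-"`.
#' @export
interval_seq <- function(seqs, iv) {
  stopifnot(nrow(iv) == 1L)
  row <- seqs[seqs$id == iv$seq_id, ]
  if (nrow(row) != 1L) abort(sprintf("no sequence with id '%s'", iv$seq_id))
  s <- substr(row$seq, iv$start + 1L, iv$end)
  if (iv$strand == "-") s <- revcomp(s)
  s
}

#' Write intervals as BED6
#'
#' 0-based half-open, six columns, no header; byte-stable for identical
#' input (an empty interval set yields an empty file).
#'
#' @param intervals Interval tibble ([interval()]); an optional `score`
#'   column is used for column 5 (default 0).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(intervals)) intervals$name else "."
  score <- if ("score" %in% names(intervals)) intervals$score else 0L
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%s\t%s",
    intervals$seq_id, intervals$start, intervals$end,
    name, format(score, trim = TRUE), intervals$strand
  )
  writeLines(lines, path)
  invisible(path)
}

# Deterministic key=value serialization of (possibly nested) lists and
# tibbles; the single structured-report format used for truth files and
# architecture reports.
serialize_report <- function(x, prefix = character(0)) {
  out <- character(0)
  if (is.data.frame(x)) {
    for (i in seq_len(nrow(x))) {
      fields <- vapply(
        names(x),
        function(nm) sprintf("%s=%s", nm, format(x[[nm]][i], trim = TRUE, digits = 12)),
        character(1)
      )
      out <- c(out, sprintf("%s[%d]\t%s", paste(prefix, collapse = "."), i,
                            paste(fields, collapse = ";")))
    }
  } else if (is.list(x)) {
    for (nm in names(x)) {
      out <- c(out, serialize_report(x[[nm]], c(prefix, nm)))
    }
  } else if (is.null(x) || length(x) == 0L) {
    out <- sprintf("%s\tNA", paste(prefix, collapse = "."))
  } else {
    out <- sprintf("%s\t%s", paste(prefix, collapse = "."),
                   paste(format(x, trim = TRUE, digits = 12), collapse = ","))
  }
  out
}

#' Write a structured text report
#'
#' Serializes a nested list/tibble object (a junction architecture, a
#' simulation truth, a mechanism call) as deterministic key--value lines,
#' one record per feature. Byte-stable for identical input.
#'
#' @param x A (possibly nested) list or tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  writeLines(serialize_report(unclass(x)), path)
  invisible(path)
}
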