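# Shared I/O: FASTA via Biostrings, strict TSV round-trips, and coordinate
# convention conversion. All internal intervals are 0-based half-open;
# GFF3-like (1-based closed) coordinates are converted at the boundary.

#' Read a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of sequences (empty for an empty file).
#'   Duplicate record ids are rejected with the offending id named.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  stats::setNames(as.character(set), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences (unique names required).
#' @param path output path.
#' @param wrap line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, wrap = 60L) {
  if (is.null(names(seqs)) || any(names(seqs) == "") || anyNA(names(seqs)))
    stop("all sequences must be named", call. = FALSE)
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup) > 0L)
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = wrap)
  invisible(path)
}

#' Convert interval coordinates between conventions
#'
#' Supported conventions: `"1-based-closed"` (GFF3-like) and
#' `"0-based-half-open"` (BED-like, the internal convention). Converting a
#' record to its own convention is the identity.
#'
#' @param start,end interval coordinates (vectorised).
#' @param from,to source and target conventions.
#' @return data frame with converted `start`, `end`.
#' @export
convert_coordinates <- function(start, end,
                                from = c("1-based-closed", "0-based-half-open"),
                                to = c("0-based-half-open", "1-based-closed")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == "1-based-closed") {
    if (any(start < 1) || any(start > end))
      stop("invalid 1-based closed interval(s)", call. = FALSE)
  } else {
    if (any(start < 0) || any(start >= end))
      stop("invalid 0-based half-open interval(s)", call. = FALSE)
  }
  if (from == to) return(data.frame(start = start, end = end))
  if (from == "1-based-closed") data.frame(start = start - 1, end = end)
  else data.frame(start = start + 1, end = end)
}

#' Write a data frame as TSV
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
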