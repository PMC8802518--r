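#' Reverse-complement DNA sequences
#'
#' @param x character vector of DNA sequences over `A,C,G,T,N`.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Effective length of a reference sequence
#'
#' Approximates the number of valid fragment start positions:
#' `max(1, length - mean_fragment + 1)`.
#'
#' @param length integer vector of reference lengths (bases).
#' @param mean_fragment mean fragment length in bases (default 300).
#' @return numeric vector of effective lengths.
#' @export
effective_length <- function(length, mean_fragment = 300) {
  pmax(1, length - mean_fragment + 1)
}

#' Build a reference set
#'
#' Bundles genome sequences with per-reference metadata (length,
#' effective length, taxid) used throughout mapping and quantification.
#'
#' @param seqs named character vector of genome sequences (names are
#'   reference ids), or a `Biostrings::DNAStringSet`.
#' @param taxid optional vector of NCBI taxids, one per reference.
#' @param mean_fragment mean fragment length (bases) used to compute
#'   effective lengths.
#' @return an object of class `reference_set` with elements `seq`
#'   (named character) and `info` (data.frame with columns `id`,
#'   `length`, `effective_length`, `taxid`).
#' @export
reference_set <- function(seqs, taxid = NULL, mean_fragment = 300) {
  if (inherits(seqs, "DNAStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  if (length(seqs) == 0L) stop("empty reference set")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("reference sequences must be named")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate reference ids")
  seqs <- toupper(seqs)
  len <- nchar(seqs)
  if (is.null(taxid)) taxid <- rep(NA_character_, length(seqs))
  info <- data.frame(
    id = names(seqs),
    length = as.integer(len),
    effective_length = effective_length(len, mean_fragment),
    taxid = as.character(taxid),
    stringsAsFactors = FALSE
  )
  structure(list(seq = seqs, info = info), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d sequences, %s bases total\n",
              nrow(x$info), format(sum(as.numeric(x$info$length)), big.mark = ",")))
  print(head(x$info, 6))
  if (nrow(x$info) > 6) cat(sprintf("... and %d more\n", nrow(x$info) - 6L))
  invisible(x)
}

#' Read genome sequences from a FASTA file
#'
#' @param path FASTA file (optionally gzip-compressed).
#' @param taxid optional taxid vector, one per sequence.
#' @param mean_fragment mean fragment length for effective lengths.
#' @return a [reference_set()].
#' @export
read_fasta <- function(path, taxid = NULL, mean_fragment = 300) {
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  # keep only the first whitespace-delimited token of each FASTA header
  names(ss) <- sub("\\s.*$", "", names(ss))
  reference_set(ss, taxid = taxid, mean_fragment = mean_fragment)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector or a `reference_set`.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "reference_set")) seqs <- seqs$seq
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, format = "fasta", width = width)
  invisible(path)
}

#' Read reads from a FASTQ file
#'
#' @param path FASTQ file (optionally gzip-compressed).
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write reads to a FASTQ file
#'
#' Emits constant base quality (`I`, Phred 40): the engine is not
#' base-quality aware.
#'
#' @param reads named character vector of read sequences.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads), function(n) strrep("I", n), "")
  lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads), "+", qual))
  writeLines(lines, path)
  invisible(path)
}
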