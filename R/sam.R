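# SAM emission and ingestion. Only the fields the quantification engine
# needs are modeled; the alignment score travels in the standard AS:i:
# tag, multi-mappings are emitted as secondary records.

#' Write alignment records as SAM
#'
#' Emits a header with `@SQ` lines and one record per mapped mate, with
#' the per-mate alignment score in the `AS:i:` tag. For each fragment
#' the best-scoring record is primary; the others carry the secondary
#' flag (0x100).
#'
#' @param aln a `cedar_alignments` data.frame from [map_reads()].
#' @param refs the [reference_set()] mapped against.
#' @param path output SAM file.
#' @export
write_sam <- function(aln, refs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", refs$info$id, refs$info$length),
    sprintf("@PG\tID:cedarquant\tPN:cedarquant\tVN:%s",
            as.character(utils::packageVersion("cedarquant")))
  ), con)
  if (!nrow(aln)) return(invisible(path))
  o <- order(aln$fragment_id, -aln$score)
  aln <- aln[o, , drop = FALSE]
  secondary <- duplicated(aln$fragment_id)
  lines <- character(0)
  for (i in seq_len(nrow(aln))) {
    r <- aln[i, ]
    sec <- if (secondary[i]) 256L else 0L
    if (isTRUE(r$paired)) {
      f1 <- 1L + 2L + 64L + sec + if (r$strand == "-") 16L else 0L
      f1 <- f1 + if (r$strand2 == "-") 32L else 0L
      f2 <- 1L + 2L + 128L + sec + if (r$strand2 == "-") 16L else 0L
      f2 <- f2 + if (r$strand == "-") 32L else 0L
      lines <- c(lines,
        paste(r$fragment_id, f1, r$ref_id, r$pos + 1L, 255L, r$cigar, "=",
              r$pos2 + 1L, 0L, "*", "*", sprintf("AS:i:%d", as.integer(round(r$score1))),
              sep = "\t"),
        paste(r$fragment_id, f2, r$ref_id, r$pos2 + 1L, 255L, r$cigar2, "=",
              r$pos + 1L, 0L, "*", "*", sprintf("AS:i:%d", as.integer(round(r$score2))),
              sep = "\t"))
    } else {
      f1 <- sec + if (r$strand == "-") 16L else 0L
      lines <- c(lines,
        paste(r$fragment_id, f1, r$ref_id, r$pos + 1L, 255L, r$cigar, "*",
              0L, 0L, "*", "*", sprintf("AS:i:%d", as.integer(round(r$score))),
              sep = "\t"))
    }
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read alignments from a SAM file
#'
#' Accepts SAM from this package or from external aligners; the only
#' requirement beyond mandatory fields is an `AS:i:` score tag per
#' record. Multiple records for the same (fragment, reference, mate)
#' are reduced to the best-scoring one; paired mates are summed into a
#' single fragment-level score.
#'
#' @param path SAM file.
#' @return a `cedar_alignments`-style data.frame (one row per fragment
#'   x reference) with `fragment_id`, `ref_id`, `score`, `pos`,
#'   `strand`, `cigar`, `paired`, `frag_len` (NA when SEQ is absent).
#'   The header's `@SQ` reference table (columns `id`, `length`) is
#'   attached as attribute `sq_refs`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sq_refs <- if (length(sq)) {
    data.frame(
      id = sub("^.*\tSN:([^\t]+).*$", "\\1", sq),
      length = as.integer(sub("^.*\tLN:([0-9]+).*$", "\\1", sq)),
      stringsAsFactors = FALSE
    )
  } else NULL
  lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    res <- empty_alignments()
    attr(res, "sq_refs") <- sq_refs
    return(res)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) stop("malformed SAM record at line ", which(nf < 11L)[1])
  getf <- function(i) vapply(fields, `[[`, "", i)
  qname <- getf(1L)
  flag <- as.integer(getf(2L))
  rname <- getf(3L)
  pos <- as.integer(getf(4L)) - 1L
  cigar <- getf(6L)
  seq <- getf(10L)
  as_tag <- vapply(fields, function(f) {
    hit <- f[startsWith(f, "AS:i:")]
    if (length(hit)) as.numeric(substring(hit[1], 6L)) else NA_real_
  }, 0)
  keep <- !bitwAnd(flag, 4L) & rname != "*"
  if (anyNA(as_tag[keep])) {
    stop("SAM record without AS:i: tag at line ", which(keep & is.na(as_tag))[1])
  }
  qname <- qname[keep]; flag <- flag[keep]; rname <- rname[keep]
  pos <- pos[keep]; cigar <- cigar[keep]; seq <- seq[keep]; as_tag <- as_tag[keep]
  if (!length(qname)) return(empty_alignments())
  mate2 <- bitwAnd(flag, 128L) > 0L
  minus <- bitwAnd(flag, 16L) > 0L
  paired <- bitwAnd(flag, 1L) > 0L
  rlen <- ifelse(seq == "*", NA_integer_, nchar(seq))

  # best record per (fragment, reference, mate)
  key <- paste(qname, rname, mate2, sep = "\r")
  o <- order(key, -as_tag)
  first <- !duplicated(key[o])
  sel <- o[first]
  qname <- qname[sel]; rname <- rname[sel]; mate2 <- mate2[sel]
  pos <- pos[sel]; cigar <- cigar[sel]; minus <- minus[sel]
  paired <- paired[sel]; as_tag <- as_tag[sel]; rlen <- rlen[sel]

  # fold mates into fragment-level records
  fkey <- paste(qname, rname, sep = "\r")
  score <- as.vector(tapply(as_tag, fkey, sum))
  flen <- as.vector(tapply(rlen, fkey, function(x) if (anyNA(x)) NA_integer_ else sum(x)))
  ispair <- as.vector(tapply(paired & TRUE, fkey, any))
  ord <- order(fkey, mate2)
  lead <- ord[!duplicated(fkey[ord])]
  ukey <- sort(unique(fkey))
  stopifnot(identical(fkey[lead], ukey))
  res <- data.frame(
    fragment_id = qname[lead], ref_id = rname[lead], score = score,
    pos = pos[lead], strand = ifelse(minus[lead], "-", "+"), cigar = cigar[lead],
    paired = ispair, frag_len = flen, stringsAsFactors = FALSE
  )
  res <- res[order(res$fragment_id, res$ref_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("cedar_alignments", "data.frame")
  attr(res, "sq_refs") <- sq_refs
  res
}
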