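# Range-factorized equivalence classes. Fragments aligning to the same
# reference set AND falling in the same per-reference conditional
# probability bins share a class; class weights are the mean of member
# fragments' conditional probabilities. bins = 1 recovers the classical
# (non-factorized) equivalence-class reduction.

#' Conditional probability of a fragment given a reference
#'
#' Maps an alignment score to the conditional probability of the
#' fragment arising from the reference: `exp(alpha * (score - best))`,
#' which equals 1 when the score is the fragment's best.
#'
#' @param score alignment score(s) of the fragment on the reference.
#' @param best_score_for_fragment the fragment's best score over all
#'   its alignments.
#' @param alpha decay rate per score unit (default 1).
#' @return probabilities in `(0, 1]`.
#' @export
score_to_conditional_prob <- function(score, best_score_for_fragment, alpha = 1) {
  if (any(score > best_score_for_fragment + 1e-9)) {
    stop("score exceeds the fragment's best score")
  }
  exp(alpha * (score - best_score_for_fragment))
}

#' Construct a single equivalence class
#'
#' @param label strictly sorted character vector of reference ids.
#' @param count number of member fragments (>= 1).
#' @param weights per-reference mean conditional probabilities, one per
#'   label entry, all in `(0, 1]`.
#' @param bins per-reference range-bin indices (the bin signature).
#' @return an object of class `eq_class`.
#' @export
eq_class <- function(label, count, weights = rep(1, length(label)),
                     bins = rep(1L, length(label))) {
  label <- as.character(label)
  if (length(label) == 0L) stop("empty class label")
  if (is.unsorted(label, strictly = TRUE)) {
    o <- order(label)
    if (anyDuplicated(label)) stop("duplicate reference in class label")
    label <- label[o]; weights <- weights[o]; bins <- bins[o]
  }
  if (length(weights) != length(label) || length(bins) != length(label)) {
    stop("weights/bins must match the label length")
  }
  if (any(weights <= 0) || any(weights > 1 + 1e-12)) stop("weights must be in (0, 1]")
  if (count < 1) stop("class count must be >= 1")
  structure(list(label = label, count = as.numeric(count),
                 weights = as.numeric(weights), bins = as.integer(bins)),
            class = "eq_class")
}

#' Bundle equivalence classes with their reference view
#'
#' @param classes list of [eq_class()] objects.
#' @param refs a [reference_set()] or its `info` data.frame (columns
#'   `id`, `length`, `effective_length`, `taxid`).
#' @param unmapped number of fragments that failed to map (bookkeeping
#'   only).
#' @return an object of class `class_collection` with elements
#'   `classes`, `refs` (info data.frame), `total_fragments`, `unmapped`.
#' @export
class_collection <- function(classes, refs, unmapped = 0) {
  if (inherits(refs, "reference_set")) refs <- refs$info
  stopifnot(is.data.frame(refs),
            all(c("id", "length", "effective_length") %in% names(refs)))
  if (!"taxid" %in% names(refs)) refs$taxid <- NA_character_
  if (!length(classes)) stop("empty class collection")
  classes <- lapply(classes, function(cl) {
    if (!inherits(cl, "eq_class")) cl <- do.call(eq_class, cl)
    if (!all(cl$label %in% refs$id)) {
      stop("class label references unknown reference id: ",
           setdiff(cl$label, refs$id)[1])
    }
    cl
  })
  keys <- vapply(classes, function(cl) {
    paste(paste(cl$label, cl$bins, sep = "@"), collapse = ",")
  }, "")
  if (anyDuplicated(keys)) {
    stop("two classes share both label and bin signature")
  }
  structure(list(classes = classes, refs = refs,
                 total_fragments = sum(vapply(classes, `[[`, 0, "count")),
                 unmapped = unmapped),
            class = "class_collection")
}

#' @export
print.class_collection <- function(x, ...) {
  cat(sprintf("class_collection: %d classes, %s fragments, %d references (%d unmapped fragments)\n",
              length(x$classes), format(x$total_fragments, big.mark = ","),
              nrow(x$refs), x$unmapped))
  invisible(x)
}

#' Collapse alignments into range-factorized equivalence classes
#'
#' Converts per-fragment alignment scores to conditional probabilities
#' ([score_to_conditional_prob()]), assigns each probability to one of
#' `bins` equal-width bins over `(0, 1]`, and groups fragments sharing
#' both the reference set and the per-reference bin signature. Class
#' weights are arithmetic means of member probabilities.
#'
#' @param alignments a `cedar_alignments` data.frame (already
#'   score-filtered) with columns `fragment_id`, `ref_id`, `score`.
#' @param refs a [reference_set()] (or its info data.frame).
#' @param bins number of probability bins (>= 1; 1 disables
#'   factorization).
#' @param alpha score-to-probability decay rate.
#' @param all_fragment_ids optional vector of every fragment attempted;
#'   fragments with no alignment records are tallied as unmapped.
#' @return a [class_collection()].
#' @export
build_classes <- function(alignments, refs, bins = 4L, alpha = 1,
                          all_fragment_ids = NULL) {
  if (inherits(refs, "reference_set")) refs <- refs$info
  bins <- as.integer(bins)
  if (bins < 1L) stop("bins must be >= 1")
  if (!nrow(alignments)) stop("no alignments to build classes from")
  ridx <- match(alignments$ref_id, refs$id)
  if (anyNA(ridx)) {
    stop("alignment references unknown reference id: ",
         alignments$ref_id[is.na(ridx)][1])
  }
  frag <- as.character(alignments$fragment_id)
  score <- alignments$score
  o <- order(frag, ridx)
  frag <- frag[o]; ridx <- ridx[o]; score <- score[o]
  n <- length(frag)
  if (anyDuplicated(paste(frag, ridx, sep = "\r"))) {
    stop("duplicate (fragment, reference) alignment record")
  }
  gi <- cumsum(c(TRUE, frag[-1L] != frag[-n]))
  nfrag <- gi[n]
  # best score per fragment, broadcast to rows
  o2 <- order(gi, -score)
  best <- rep(score[o2][!duplicated(gi[o2])], tabulate(gi, nfrag))
  prob <- score_to_conditional_prob(score, best, alpha)
  bin <- pmin(bins, as.integer(ceiling(prob * bins)))

  ckey <- vapply(split(paste(ridx, bin, sep = "@"), gi), paste, "", collapse = ",")
  uc <- unique(ckey)
  cid_frag <- match(ckey, uc)
  counts <- tabulate(cid_frag, length(uc))
  cid_row <- cid_frag[gi]

  enc <- cid_row * (nrow(refs) + 1) + ridx
  wsum <- rowsum(prob, enc)  # ordered by numeric group value
  gnum <- as.numeric(rownames(wsum))
  w_cid <- floor(gnum / (nrow(refs) + 1))
  w_rid <- as.integer(round(gnum - w_cid * (nrow(refs) + 1)))
  o3 <- order(enc)
  firstg <- !duplicated(enc[o3])
  w_bin <- bin[o3][firstg]

  lab_split <- split(seq_along(gnum), w_cid)
  classes <- lapply(seq_along(uc), function(ci) {
    rows <- lab_split[[as.character(ci)]]
    eq_class(label = refs$id[w_rid[rows]], count = counts[ci],
             weights = as.numeric(wsum[rows]) / counts[ci], bins = w_bin[rows])
  })
  unmapped <- if (is.null(all_fragment_ids)) 0L else {
    length(setdiff(as.character(all_fragment_ids), frag))
  }
  class_collection(classes, refs, unmapped = unmapped)
}

#' Write a class collection to the plain-text class table format
#'
#' Format: a `#refs N` header; N reference lines (`id`, `length`,
#' `effective_length`, `taxid`, tab-separated); then one line per class
#' with `count`, label size, the 1-based reference indices, the
#' weights, and the bin signature.
#'
#' @param cc a [class_collection()].
#' @param path output file.
#' @export
write_eqclasses <- function(cc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#refs\t%d", nrow(cc$refs)), con)
  writeLines(sprintf("%s\t%d\t%s\t%s", cc$refs$id, cc$refs$length,
                     format(cc$refs$effective_length, trim = TRUE, scientific = FALSE),
                     ifelse(is.na(cc$refs$taxid), "NA", cc$refs$taxid)), con)
  lines <- vapply(cc$classes, function(cl) {
    idx <- match(cl$label, cc$refs$id)
    paste(c(format(cl$count, trim = TRUE, scientific = FALSE), length(idx), idx,
            format(cl$weights, digits = 17, trim = TRUE, scientific = FALSE),
            cl$bins), collapse = "\t")
  }, "")
  writeLines(lines, con)
  invisible(path)
}

#' Read a class collection from the plain-text class table format
#'
#' @param path file written by [write_eqclasses()].
#' @return a [class_collection()].
#' @export
read_eqclasses <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#refs")) {
    stop("not a class table: missing #refs header")
  }
  nref <- as.integer(strsplit(lines[1], "\t")[[1]][2])
  rf <- strsplit(lines[1 + seq_len(nref)], "\t", fixed = TRUE)
  refs <- data.frame(
    id = vapply(rf, `[[`, "", 1L),
    length = as.integer(vapply(rf, `[[`, "", 2L)),
    effective_length = as.numeric(vapply(rf, `[[`, "", 3L)),
    taxid = vapply(rf, `[[`, "", 4L),
    stringsAsFactors = FALSE
  )
  refs$taxid[refs$taxid == "NA"] <- NA_character_
  cl_lines <- lines[-(1:(nref + 1L))]
  cl_lines <- cl_lines[nzchar(cl_lines)]
  classes <- lapply(seq_along(cl_lines), function(i) {
    f <- strsplit(cl_lines[i], "\t", fixed = TRUE)[[1]]
    count <- as.numeric(f[1]); m <- as.integer(f[2])
    if (length(f) < 2L + 2L * m) {
      stop(sprintf("malformed class line %d: expected >= %d fields, got %d",
                   i + nref + 1L, 2L + 2L * m, length(f)))
    }
    idx <- as.integer(f[2L + seq_len(m)])
    w <- as.numeric(f[2L + m + seq_len(m)])
    b <- if (length(f) >= 2L + 3L * m) as.integer(f[2L + 2L * m + seq_len(m)]) else rep(1L, m)
    eq_class(label = refs$id[idx], count = count, weights = w, bins = b)
  })
  class_collection(classes, refs)
}
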