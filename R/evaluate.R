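# Accuracy protocol: mean squared log error with its filtering
# variants, false-positive counts across read thresholds, and
# concordance between rank tables.

#' Mean squared log error
#'
#' `L(y, yhat) = mean((log(y + 1) - log(yhat + 1))^2)` with natural
#' logarithms by default; only relative comparisons depend on the base.
#'
#' @param y true count vector.
#' @param yhat estimated count vector (same length).
#' @param base logarithm base.
#' @return non-negative scalar; 0 iff the vectors are identical.
#' @export
msle <- function(y, yhat, base = exp(1)) {
  if (length(y) != length(yhat)) stop("length mismatch between y and yhat")
  if (!length(y)) stop("MSLE of empty vectors is undefined")
  if (any(y < 0) || any(yhat < 0)) stop("counts must be non-negative")
  mean((log(y + 1, base = base) - log(yhat + 1, base = base))^2)
}

#' MSLE under the benchmark filtering variants
#'
#' `both_zero_removed` drops taxa where both the true and estimated
#' counts are zero. `read_threshold` drops low-count taxa before
#' recomputation: under the default `"max"` rule a taxon is dropped
#' when `max(y_i, yhat_i) < threshold` (small in both vectors);
#' `"estimated"` gates on the estimated count only, `"either"` drops
#' when either count is below the threshold. `N` updates to the
#' surviving length.
#'
#' @inheritParams msle
#' @param mode `"both_zero_removed"` or `"read_threshold"`.
#' @param threshold read threshold (required for `"read_threshold"`).
#' @param rule which vector governs threshold filtering.
#' @return the MSLE over surviving taxa.
#' @export
msle_filtered <- function(y, yhat, mode = c("both_zero_removed", "read_threshold"),
                          threshold = NULL, rule = c("max", "estimated", "either"),
                          base = exp(1)) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  if (length(y) != length(yhat)) stop("length mismatch between y and yhat")
  keep <- if (mode == "both_zero_removed") {
    !(y == 0 & yhat == 0)
  } else {
    if (is.null(threshold)) stop("read_threshold mode needs a threshold")
    switch(rule,
      max = pmax(y, yhat) >= threshold,
      estimated = yhat >= threshold,
      either = pmin(y, yhat) >= threshold
    )
  }
  if (!any(keep)) stop("MSLE undefined: no taxa survive the filter")
  msle(y[keep], yhat[keep], base = base)
}

#' False-positive taxa across read thresholds
#'
#' A false positive at threshold `t` is a taxon with zero true count
#' and an estimated count strictly greater than `t`; at `t = 0` every
#' falsely reported taxon counts, even with a single assigned read.
#'
#' @param y true counts.
#' @param yhat estimated counts (same length).
#' @param thresholds read thresholds.
#' @return named integer vector, FP count per threshold
#'   (non-increasing in the threshold).
#' @export
false_positives <- function(y, yhat, thresholds = 0:10) {
  if (length(y) != length(yhat)) stop("length mismatch between y and yhat")
  fp <- vapply(thresholds, function(t) sum(y == 0 & yhat > t), 0L)
  setNames(fp, thresholds)
}

#' Spearman concordance between two rank tables
#'
#' Outer-joins the two tables on taxid (missing taxa count as zero),
#' drops taxa that are zero in both, and returns the Spearman rank
#' correlation of the surviving paired counts (average ranks for ties).
#'
#' @param tableA,tableB data.frames with columns `taxid` and a count
#'   column (`estimated_reads` or the second column), or named numeric
#'   vectors.
#' @return Spearman's rho.
#' @export
concordance <- function(tableA, tableB) {
  va <- as_count_vector(tableA)
  vb <- as_count_vector(tableB)
  taxa <- union(names(va), names(vb))
  a <- ifelse(taxa %in% names(va), va[taxa], 0)
  b <- ifelse(taxa %in% names(vb), vb[taxa], 0)
  keep <- !(a == 0 & b == 0)
  if (sum(keep) < 3L) stop("concordance undefined: fewer than 3 surviving taxa")
  cor(a[keep], b[keep], method = "spearman")
}

as_count_vector <- function(x) {
  if (is.numeric(x)) {
    if (is.null(names(x))) stop("count vectors must be named by taxid")
    return(x)
  }
  stopifnot(is.data.frame(x), "taxid" %in% names(x))
  cntcol <- if ("estimated_reads" %in% names(x)) "estimated_reads" else names(x)[2]
  v <- setNames(x[[cntcol]], as.character(x$taxid))
  v[!is.na(names(v))]
}

#' Full evaluation report against a truth table
#'
#' @param y named true counts (or data.frame with `genome_id`/`taxid`
#'   and counts).
#' @param yhat named estimated counts.
#' @param thresholds read thresholds for the sweep.
#' @return an `eval_report` list: `msle_unfiltered`,
#'   `msle_both_zero_removed`, `msle_by_threshold`, `fp_by_threshold`,
#'   `n_taxa_used`.
#' @export
evaluate_report <- function(y, yhat, thresholds = 0:10) {
  if (is.data.frame(y)) y <- setNames(y[[ncol(y)]], y[[1]])
  if (is.data.frame(yhat)) yhat <- setNames(yhat[[ncol(yhat)]], yhat[[1]])
  taxa <- union(names(y), names(yhat))
  yy <- ifelse(taxa %in% names(y), y[taxa], 0)
  ee <- ifelse(taxa %in% names(yhat), yhat[taxa], 0)
  msle_t <- vapply(thresholds, function(t) {
    tryCatch(msle_filtered(yy, ee, "read_threshold", threshold = t), error = function(e) NA_real_)
  }, 0)
  n_used <- vapply(thresholds, function(t) sum(pmax(yy, ee) >= t), 0L)
  structure(list(
    msle_unfiltered = msle(yy, ee),
    msle_both_zero_removed = tryCatch(msle_filtered(yy, ee, "both_zero_removed"),
                                      error = function(e) NA_real_),
    msle_by_threshold = setNames(msle_t, thresholds),
    fp_by_threshold = false_positives(yy, ee, thresholds),
    n_taxa_used = setNames(n_used, thresholds)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: MSLE %.4f (unfiltered), %.4f (both-zero removed)\n",
              x$msle_unfiltered, x$msle_both_zero_removed))
  cat("FP by threshold:\n")
  print(x$fp_by_threshold)
  invisible(x)
}
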