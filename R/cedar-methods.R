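#' @export
print.cedar_fit <- function(x, ...) {
  cat("Strain abundance fit (EM + mass-preserving set-cover thresholding)\n")
  cat(sprintf("  fragments: %s   references reported: %d   removed: %d\n",
              format(x$total_fragments, big.mark = ","), length(x$est_reads),
              nrow(x$removed)))
  cat(sprintf("  EM iterations: %d over %d thresholding round(s); %s\n",
              x$iterations, x$rounds,
              if (x$converged) "converged" else "iteration budget reached"))
  if (x$discarded_mass > 0) {
    cat(sprintf("  final cutoff (%s %g reads) discarded %.3f fragments\n",
                if (x$options$cutoff_inclusive) "<=" else "<",
                x$options$cutoff, x$discarded_mass))
  }
  invisible(x)
}

#' @method summary cedar_fit
#' @export
summary.cedar_fit <- function(object, ...) {
  tab <- quant_table(object)
  structure(list(fit = object, table = tab), class = "summary.cedar_fit")
}

#' @export
print.summary.cedar_fit <- function(x, ...) {
  print(x$fit)
  cat("\nTop references by expected reads:\n")
  print(head(x$table[order(-x$table$estimated_reads), ], 10), row.names = FALSE)
  if (nrow(x$fit$removed)) {
    cat("\nRemovals by reason:\n")
    print(table(x$fit$removed$reason))
  }
  invisible(x)
}

#' Extract mixture coefficients from a fit
#'
#' @param object a [cedar()] fit.
#' @param type `"theta"` (effective-length-normalized nucleotide
#'   fraction), `"read_fraction"`, or `"est_reads"`.
#' @param ... unused.
#' @return named numeric vector over reported references.
#' @method coef cedar_fit
#' @export
coef.cedar_fit <- function(object, type = c("theta", "read_fraction", "est_reads"), ...) {
  type <- match.arg(type)
  object[[type]]
}

#' @export
fitted.cedar_fit <- function(object, ...) object$est_reads

#' @method logLik cedar_fit
#' @export
logLik.cedar_fit <- function(object, ...) {
  lls <- unlist(object$loglik)
  if (!length(lls)) return(structure(NA_real_, class = "logLik"))
  structure(lls[length(lls)], df = length(object$est_reads) - 1L,
            nobs = object$total_fragments, class = "logLik")
}

#' @method plot cedar_fit
#' @export
plot.cedar_fit <- function(x, n = 20L, ...) {
  e <- sort(x$est_reads, decreasing = TRUE)
  e <- head(e, n)
  barplot(e, las = 2, ylab = "expected reads",
          main = "cedar abundance estimates", ...)
  invisible(x)
}

#' Raw quantification table
#'
#' @param fit a [cedar()] fit.
#' @return data.frame with columns `reference_id`, `taxid`, `length`,
#'   `effective_length`, `estimated_reads`, `read_fraction`,
#'   `nucleotide_fraction`.
#' @export
quant_table <- function(fit) {
  idx <- match(names(fit$est_reads), fit$refs$id)
  data.frame(
    reference_id = names(fit$est_reads),
    taxid = fit$refs$taxid[idx],
    length = fit$refs$length[idx],
    effective_length = fit$refs$effective_length[idx],
    estimated_reads = unname(fit$est_reads),
    read_fraction = unname(fit$read_fraction),
    nucleotide_fraction = unname(fit$theta),
    stringsAsFactors = FALSE
  )
}

#' Write the raw quantification and removal-log tables
#'
#' @param fit a [cedar()] fit.
#' @param path output TSV for the quantification table.
#' @param removal_path optional output TSV for the removal log.
#' @param header optional comment lines (without leading `#`).
#' @export
write_quant_table <- function(fit, path, removal_path = NULL, header = character(0)) {
  con <- file(path, "w")
  if (length(header)) writeLines(paste0("# ", header), con)
  write.table(quant_table(fit), con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(removal_path)) {
    con <- file(removal_path, "w")
    if (length(header)) writeLines(paste0("# ", header), con)
    write.table(fit$removed, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(path)
}
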