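# The quantification engine: EM over (range-factorized) equivalence
# classes, interleaved every k iterations with a four-step, mass-
# preserving thresholding round (PR marking, safe removal, greedy set
# cover over critical classes, class update), then a final abundance
# cutoff.
#
# Internally the mixture is parameterized by read fractions pi_i =
# est_reads_i / total. The E-step responsibility of reference i for
# class q is proportional to pi_i * coverage_i * w_qi /
# effective_length_i, which equals the theta-based prior of the model
# (theta_i proportional to est_i / effective_length_i, multiplied by
# the coverage ratio) up to a per-class constant. With the coverage
# ratios held fixed within a thresholding round, one iteration is an
# exact EM step for the class-level log-likelihood
#   sum_q N^q log( sum_{i in label(q)} pi_i * cov_i * w_qi / el_i ),
# hence the likelihood is non-decreasing between thresholding rounds.

flatten_classes <- function(cc) {
  labs <- lapply(cc$classes, `[[`, "label")
  m <- lengths(labs)
  list(
    cls = rep.int(seq_along(labs), m),
    ref = match(unlist(labs, use.names = FALSE), cc$refs$id),
    w = unlist(lapply(cc$classes, `[[`, "weights"), use.names = FALSE),
    count = vapply(cc$classes, `[[`, 0, "count"),
    el = cc$refs$effective_length,
    ncls = length(labs),
    nref = nrow(cc$refs)
  )
}

# one E+M step on the flat representation; returns list(pi, est, ll)
# where ll is the log-likelihood at the *incoming* parameters
em_step_flat <- function(fl, pi, cov) {
  b <- pi[fl$ref] * cov[fl$ref] * fl$w / fl$el[fl$ref]
  denom <- as.vector(rowsum(b, fl$cls))  # cls ids are 1..ncls, all present
  ll <- sum(fl$count * log(denom))
  resp <- b / denom[fl$cls]
  rs <- rowsum(resp * fl$count[fl$cls], fl$ref)
  est <- numeric(fl$nref)
  est[as.integer(rownames(rs))] <- rs
  total <- sum(fl$count)
  list(pi = est / total, est = est, ll = ll)
}

#' Initialize an abundance state
#'
#' Uniform mixture over every reference appearing in at least one class
#' label; coverage ratios start at 1.
#'
#' @param classes a [class_collection()].
#' @return an object of class `abundance_state` with named vectors
#'   `est_reads`, `theta` (effective-length-normalized mixture weight),
#'   `read_fraction`, `coverage_ratio` over the active references, and
#'   an `iteration` counter.
#' @export
abundance_state <- function(classes) {
  active <- sort(unique(unlist(lapply(classes$classes, `[[`, "label"))))
  n <- length(active)
  est <- setNames(rep(classes$total_fragments / n, n), active)
  el <- classes$refs$effective_length[match(active, classes$refs$id)]
  th <- (est / el) / sum(est / el)
  structure(list(
    est_reads = est,
    theta = setNames(th, active),
    read_fraction = est / classes$total_fragments,
    coverage_ratio = setNames(rep(1, n), active),
    active = active,
    total_fragments = classes$total_fragments,
    iteration = 0L
  ), class = "abundance_state")
}

#' One EM iteration over a class collection
#'
#' E-step: within each class, responsibilities are proportional to the
#' reference's prior (its mixture weight times its coverage ratio)
#' times the class weight, normalized over the class label. M-step:
#' expected fragment counts are summed over classes and converted back
#' to mixture weights via effective-length normalization. Total
#' expected reads are preserved.
#'
#' @param state an [abundance_state()].
#' @param classes the [class_collection()] (labels must be subsets of
#'   `state$active`).
#' @return the updated `abundance_state`.
#' @export
em_iteration <- function(state, classes) {
  fl <- flatten_classes(classes)
  bad <- setdiff(classes$refs$id[unique(fl$ref)], state$active)
  if (length(bad)) stop("class label contains inactive reference: ", bad[1])
  pi <- numeric(fl$nref)
  cov <- numeric(fl$nref)
  aidx <- match(state$active, classes$refs$id)
  pi[aidx] <- state$read_fraction
  cov[aidx] <- state$coverage_ratio
  stp <- em_step_flat(fl, pi, cov)
  est <- setNames(stp$est[aidx], state$active)
  el <- classes$refs$effective_length[aidx]
  state$est_reads <- est
  state$read_fraction <- est / state$total_fragments
  state$theta <- (est / el) / sum(est / el)
  state$iteration <- state$iteration + 1L
  state
}

#' Mark potentially removable (PR) references
#'
#' A reference is PR when its current expected count is smaller than or
#' equal to the cutoff.
#'
#' @param state an [abundance_state()].
#' @param cutoff abundance cutoff in fragments.
#' @return character vector of PR reference ids.
#' @export
mark_potentially_removable <- function(state, cutoff = 2) {
  names(state$est_reads)[state$est_reads <= cutoff]
}

#' Remove safe PR references
#'
#' A PR reference is safe to remove when every equivalence class whose
#' label contains it also contains at least one non-PR reference; no
#' class can be orphaned by removing all safe references.
#'
#' @param pr character vector of PR reference ids.
#' @param classes a [class_collection()].
#' @return character vector of removed (safe) reference ids.
#' @export
remove_safe_pr <- function(pr, classes) {
  if (!length(pr)) return(character(0))
  unsafe <- character(0)
  for (cl in classes$classes) {
    if (all(cl$label %in% pr)) unsafe <- c(unsafe, cl$label)
  }
  setdiff(intersect(pr, unique(unlist(lapply(classes$classes, `[[`, "label")))),
          unique(unsafe))
}

#' Greedy set cover over critical equivalence classes
#'
#' Critical classes are those whose every member reference is PR.
#' Repeatedly retains the candidate covering the most uncovered
#' critical classes until all are covered. Ties prefer the candidate
#' with higher current expected count, then the lexicographically
#' smaller reference id.
#'
#' @param critical_classes list of [eq_class()] objects, each with
#'   label fully contained in `candidates`.
#' @param candidates character vector of PR reference ids.
#' @param state optional [abundance_state()] supplying expected counts
#'   for tie-breaking.
#' @return character vector of retained reference ids (empty when there
#'   are no critical classes).
#' @export
greedy_set_cover <- function(critical_classes, candidates, state = NULL) {
  if (!length(critical_classes)) return(character(0))
  labs <- lapply(critical_classes, function(cl) {
    if (inherits(cl, "eq_class")) cl$label else as.character(cl)
  })
  if (!all(unlist(labs) %in% candidates)) {
    stop("critical class label not contained in the candidate set")
  }
  est <- if (is.null(state)) setNames(numeric(length(candidates)), candidates) else state$est_reads
  uncovered <- rep(TRUE, length(labs))
  retained <- character(0)
  cands <- sort(candidates)
  while (any(uncovered)) {
    cover <- vapply(cands, function(r) {
      sum(vapply(labs[uncovered], function(l) r %in% l, NA))
    }, 0L)
    if (all(cover == 0L)) stop("uncoverable critical class")  # cannot happen given pre
    e <- est[cands]; e[is.na(e)] <- 0
    best <- order(-cover, -e, cands)[1L]
    pick <- cands[best]
    retained <- c(retained, pick)
    uncovered <- uncovered & !vapply(labs, function(l) pick %in% l, NA)
    cands <- setdiff(cands, pick)
  }
  retained
}

#' Remove references from a class collection
#'
#' Deletes the removed references from every label (and the matching
#' weights and bin entries, rescaling surviving weights so the largest
#' is 1), then merges classes whose surviving label and bin signature
#' coincide, summing counts and count-averaging weights. Total
#' fragments are unchanged.
#'
#' @param classes a [class_collection()].
#' @param removed character vector of reference ids to remove.
#' @return the updated [class_collection()].
#' @export
update_classes <- function(classes, removed) {
  if (!length(removed)) return(classes)
  pruned <- lapply(classes$classes, function(cl) {
    keep <- !(cl$label %in% removed)
    if (!any(keep)) {
      stop("removal would orphan an equivalence class (label: ",
           paste(cl$label, collapse = ","), ")")
    }
    if (all(keep)) return(cl)
    w <- cl$weights[keep]
    eq_class(label = cl$label[keep], count = cl$count,
             weights = w / max(w), bins = cl$bins[keep])
  })
  keys <- vapply(pruned, function(cl) {
    paste(paste(cl$label, cl$bins, sep = "@"), collapse = ",")
  }, "")
  if (anyDuplicated(keys)) {
    grp <- split(seq_along(pruned), keys)
    pruned <- lapply(grp, function(ii) {
      if (length(ii) == 1L) return(pruned[[ii]])
      cnt <- vapply(pruned[ii], `[[`, 0, "count")
      wmat <- vapply(pruned[ii], `[[`, numeric(length(pruned[[ii[1]]]$label)), "weights")
      wmat <- matrix(wmat, ncol = length(ii))
      eq_class(label = pruned[[ii[1]]]$label, count = sum(cnt),
               weights = as.vector(wmat %*% cnt) / sum(cnt),
               bins = pruned[[ii[1]]]$bins)
    })
    names(pruned) <- NULL
  }
  class_collection(pruned, classes$refs, unmapped = classes$unmapped)
}

#' Fit strain abundances by EM with mass-preserving thresholding
#'
#' Initializes the mixture uniformly over the references appearing in
#' class labels, then loops: `k_between_setcover` EM iterations followed
#' by a thresholding round — PR marking
#' ([mark_potentially_removable()]), safe removal ([remove_safe_pr()]),
#' greedy set cover over critical classes ([greedy_set_cover()]) and
#' class update ([update_classes()]). When a round removes nothing, EM
#' runs to convergence (or `max_iterations`), and references whose
#' final expected count does not exceed `cutoff` are dropped and
#' logged. Mass (total expected reads) is preserved through every EM
#' iteration and every thresholding round; only the final cutoff
#' discards mass, and the discarded mass is logged.
#'
#' @param classes a [class_collection()] (see [build_classes()],
#'   [read_eqclasses()]).
#' @param cutoff abundance cutoff in fragments, used both for PR
#'   marking and the final filter (default 2).
#' @param k_between_setcover EM iterations per thresholding round
#'   (default 10).
#' @param max_iterations total EM iteration budget (default 1000).
#' @param convergence_tol convergence is declared when no expected
#'   count changes by more than this many fragments (default 0.01).
#' @param use_coverage_prior multiply the selection prior by a
#'   per-reference coverage ratio, `1 - exp(-est_reads / effective
#'   length)` (a uniform-occupancy approximation of the fraction of the
#'   effective length covered), recomputed once per thresholding round
#'   (default TRUE).
#' @param cutoff_inclusive drop references with final expected count
#'   `<= cutoff` (TRUE, default) or strictly `< cutoff` (FALSE).
#' @param trace record per-iteration mass and per-round log-likelihood
#'   trajectories (default TRUE).
#' @return an object of class `cedar_fit`. Components: `est_reads`,
#'   `read_fraction`, `theta` (nucleotide fraction) over reported
#'   references; `removed` (data.frame: `ref_id`, `reason` in
#'   `safe-PR`, `set-cover`, `final-cutoff`; `round`, `est_at_removal`);
#'   `total_fragments`, `discarded_mass`, `iterations`, `rounds`,
#'   `converged`, `mass_trace`, `loglik` (list of per-round
#'   trajectories), `options`, `refs`.
#' @export
cedar <- function(classes, cutoff = 2, k_between_setcover = 10L,
                  max_iterations = 1000L, convergence_tol = 0.01,
                  use_coverage_prior = TRUE, cutoff_inclusive = TRUE,
                  trace = TRUE) {
  stopifnot(inherits(classes, "class_collection"))
  if (!length(classes$classes)) stop("empty class collection")
  k_between_setcover <- max(1L, as.integer(k_between_setcover))
  cc <- classes
  total <- cc$total_fragments
  n_initial <- length(unique(unlist(lapply(cc$classes, `[[`, "label"))))

  fl <- flatten_classes(cc)
  active_idx <- sort(unique(fl$ref))
  pi <- numeric(fl$nref)
  pi[active_idx] <- 1 / length(active_idx)
  est <- pi * total

  removed_log <- list()
  mass_trace <- numeric(0)
  ll_blocks <- list()
  iter <- 0L
  round_i <- 0L

  coverage <- function(est_vec) {
    if (!use_coverage_prior) return(rep(1, fl$nref))
    1 - exp(-est_vec / fl$el)
  }

  run_block <- function(n_iter, cov, until_converged = FALSE) {
    lls <- numeric(0)
    it <- 0L
    repeat {
      if (iter >= max_iterations) break
      if (!until_converged && it >= n_iter) break
      stp <- em_step_flat(fl, pi, cov)
      lls <- c(lls, stp$ll)
      delta <- max(abs(stp$est - est))
      pi <<- stp$pi; est <<- stp$est
      iter <<- iter + 1L; it <- it + 1L
      if (trace) mass_trace <<- c(mass_trace, sum(est))
      if (until_converged && delta <= convergence_tol) {
        return(list(ll = lls, converged = TRUE))
      }
    }
    list(ll = lls, converged = FALSE)
  }

  state_from <- function() {
    act <- sort(unique(fl$ref))
    ids <- cc$refs$id[act]
    el <- cc$refs$effective_length[act]
    e <- est[act]
    structure(list(
      est_reads = setNames(e, ids),
      theta = setNames((e / el) / sum(e / el), ids),
      read_fraction = setNames(e / total, ids),
      coverage_ratio = setNames(coverage(est)[act], ids),
      active = ids, total_fragments = total, iteration = iter
    ), class = "abundance_state")
  }

  repeat {
    round_i <- round_i + 1L
    if (round_i > n_initial + 1L) {
      stop("thresholding failed to terminate within the reference bound")
    }
    cov <- coverage(est)
    blk <- run_block(k_between_setcover, cov)
    if (trace) ll_blocks[[length(ll_blocks) + 1L]] <- blk$ll
    if (iter >= max_iterations) break

    st <- state_from()
    pr <- mark_potentially_removable(st, cutoff)
    safe <- remove_safe_pr(pr, cc)
    remaining_pr <- setdiff(pr, safe)
    critical <- Filter(function(cl) all(cl$label %in% pr), cc$classes)
    retained <- greedy_set_cover(critical, remaining_pr, st)
    removed_sc <- setdiff(remaining_pr, retained)
    removed_round <- c(safe, removed_sc)
    if (!length(removed_round)) break

    removed_log[[length(removed_log) + 1L]] <- data.frame(
      ref_id = removed_round,
      reason = c(rep("safe-PR", length(safe)), rep("set-cover", length(removed_sc))),
      round = round_i,
      est_at_removal = unname(st$est_reads[removed_round]),
      stringsAsFactors = FALSE
    )
    cc <- update_classes(cc, removed_round)
    fl <- flatten_classes(cc)
    drop_idx <- match(removed_round, cc$refs$id)
    pi[drop_idx] <- 0
    pi <- pi / sum(pi)
    est <- pi * total
    if (trace) mass_trace <- c(mass_trace, sum(est))
  }

  # EM to convergence with the active set frozen
  converged <- FALSE
  if (iter < max_iterations) {
    blk <- run_block(NA, coverage(est), until_converged = TRUE)
    if (trace) ll_blocks[[length(ll_blocks) + 1L]] <- blk$ll
    converged <- blk$converged
  }

  act <- sort(unique(fl$ref))
  ids <- cc$refs$id[act]
  e <- setNames(est[act], ids)
  low <- if (cutoff_inclusive) e <= cutoff else e < cutoff
  if (any(low)) {
    removed_log[[length(removed_log) + 1L]] <- data.frame(
      ref_id = ids[low], reason = "final-cutoff", round = round_i,
      est_at_removal = unname(e[low]), stringsAsFactors = FALSE
    )
  }
  rep_e <- e[!low]
  el <- cc$refs$effective_length[act][!low]
  removed <- if (length(removed_log)) do.call(rbind, removed_log) else
    data.frame(ref_id = character(0), reason = character(0),
               round = integer(0), est_at_removal = numeric(0))
  rownames(removed) <- NULL

  structure(list(
    est_reads = rep_e,
    read_fraction = rep_e / total,
    theta = if (length(rep_e)) (rep_e / el) / sum(rep_e / el) else rep_e,
    removed = removed,
    total_fragments = total,
    discarded_mass = sum(e[low]),
    iterations = iter,
    rounds = round_i,
    converged = converged,
    mass_trace = mass_trace,
    loglik = ll_blocks,
    options = list(cutoff = cutoff, k_between_setcover = k_between_setcover,
                   max_iterations = max_iterations, convergence_tol = convergence_tol,
                   use_coverage_prior = use_coverage_prior,
                   cutoff_inclusive = cutoff_inclusive),
    refs = cc$refs
  ), class = "cedar_fit")
}
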