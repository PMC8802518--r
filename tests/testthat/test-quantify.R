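test_that("a symmetric class is a fixed point with equal splits", {
  refs <- make_refs(c("A", "B"))
  cc <- class_collection(list(eq_class(c("A", "B"), 10)), refs)
  st <- abundance_state(cc)
  st <- em_iteration(st, cc)
  expect_equal(unname(st$est_reads), c(5, 5))
  st2 <- em_iteration(st, cc)
  expect_equal(st2$est_reads, st$est_reads)
  expect_equal(sum(st2$theta), 1)
})

test_that("EM drains ambiguous mass toward the evidence-backed reference", {
  refs <- make_refs(c("A", "B"))
  cc <- class_collection(list(eq_class("A", 6), eq_class(c("A", "B"), 4)), refs)
  # reference oracle: plain dense EM, many iterations
  oracle <- oracle_plain_em(cc, 1000)
  expect_equal(unname(oracle), c(10, 0), tolerance = 1e-3)
  fit <- cedar(cc, use_coverage_prior = FALSE)
  expect_equal(unname(fit$est_reads["A"]), 10, tolerance = 1e-6)
  expect_false("B" %in% names(fit$est_reads))
})

test_that("PR marking is inclusive at the cutoff", {
  refs <- make_refs(c("A", "B", "C"))
  cc <- class_collection(list(eq_class("A", 1)), refs)
  st <- abundance_state(cc)
  st$est_reads <- c(A = 100, B = 2, C = 2.5)
  expect_equal(mark_potentially_removable(st, 2), "B")
  st$est_reads <- c(A = 0, B = 0.01, C = 5)
  expect_equal(mark_potentially_removable(st, 0), "A")
})

test_that("safe removal requires a non-PR backup in every class", {
  refs <- make_refs(c("X", "Y", "Z"))
  cc1 <- class_collection(list(eq_class(c("X", "Y"), 5)), refs)
  expect_equal(remove_safe_pr("X", cc1), "X")
  expect_equal(remove_safe_pr(c("X", "Y"), cc1), character(0))  # class would orphan
  cc2 <- class_collection(list(eq_class(c("X", "Z"), 3), eq_class(c("Y", "Z"), 2)), refs)
  expect_equal(sort(remove_safe_pr(c("X", "Y"), cc2)), c("X", "Y"))
})

test_that("greedy set cover retains the island member covering all critical classes", {
  cls <- list(eq_class(c("G4", "G5"), 2), eq_class(c("G4", "G6"), 2),
              eq_class(c("G4", "G5", "G6"), 2))
  retained <- greedy_set_cover(cls, c("G4", "G5", "G6"))
  expect_equal(retained, "G4")
  expect_equal(greedy_set_cover(list(eq_class("X", 1)), "X"), "X")
  expect_equal(greedy_set_cover(list(), c("A", "B")), character(0))
  expect_error(greedy_set_cover(list(eq_class(c("A", "Q"), 1)), c("A", "B")),
               "not contained")
})

test_that("greedy set cover matches an independent greedy trace on random instances", {
  set.seed(17)
  for (i in 1:60) {
    ncand <- sample(2:12, 1)
    cand <- sprintf("C%02d", seq_len(ncand))
    ncls <- sample(1:20, 1)
    labs <- lapply(seq_len(ncls), function(j) sort(sample(cand, sample(1:min(4, ncand), 1))))
    est <- setNames(runif(ncand, 0, 3), cand)
    st <- structure(list(est_reads = est), class = "abundance_state")
    cls <- lapply(labs, function(l) eq_class(l, 1))
    got <- greedy_set_cover(cls, cand, st)
    want <- oracle_greedy_cover(labs, cand, est)
    expect_equal(got, want)
    # the cover is valid
    expect_true(all(vapply(labs, function(l) any(l %in% got), NA)))
  }
})

test_that("class update deletes, merges, conserves, and refuses to orphan", {
  refs <- make_refs(c("A", "B", "C"))
  cc <- class_collection(list(eq_class(c("A", "B"), 5)), refs)
  up <- update_classes(cc, "B")
  expect_equal(length(up$classes), 1L)
  expect_equal(up$classes[[1]]$label, "A")
  expect_equal(up$classes[[1]]$count, 5)

  cc2 <- class_collection(list(eq_class(c("A", "B"), 3), eq_class(c("A", "C"), 2)), refs)
  up2 <- update_classes(cc2, c("B", "C"))
  expect_equal(length(up2$classes), 1L)
  expect_equal(up2$classes[[1]]$count, 5)
  expect_equal(up2$total_fragments, cc2$total_fragments)

  expect_error(update_classes(cc, c("A", "B")), "orphan")

  # surviving weights are rescaled so the best is 1
  cc3 <- class_collection(list(eq_class(c("A", "B"), 4, weights = c(1, 0.5))), refs)
  up3 <- update_classes(cc3, "A")
  expect_equal(up3$classes[[1]]$weights, 1)
})

test_that("the six-genome worked example resolves exactly as described", {
  fit <- cedar(fig2_classes())
  expect_setequal(names(fit$est_reads), c("G2", "G3", "G4"))
  sc <- fit$removed[fit$removed$reason == "set-cover", "ref_id"]
  expect_setequal(sc, c("G5", "G6"))
  fc <- fit$removed[fit$removed$reason == "final-cutoff", "ref_id"]
  expect_equal(fc, "G1")
  # the island's reads all flow to the retained member
  expect_equal(unname(fit$est_reads["G4"]), 5, tolerance = 1e-6)
  expect_equal(sum(fit$est_reads) + fit$discarded_mass, fit$total_fragments,
               tolerance = 1e-6)
})

test_that("pure unique mapping reproduces raw counts exactly", {
  refs <- make_refs(c("A", "B", "C"))
  cc <- class_collection(list(eq_class("A", 120), eq_class("B", 37), eq_class("C", 11)),
                         refs)
  fit <- cedar(cc)
  expect_equal(fit$est_reads, c(A = 120, B = 37, C = 11))
  expect_equal(nrow(fit$removed), 0L)
})

test_that("a low-abundance indistinguishable pair collapses to one reference", {
  refs <- make_refs(c("A", "B"))
  cc <- class_collection(list(eq_class(c("A", "B"), 4)), refs)
  fit <- cedar(cc)
  expect_equal(length(fit$est_reads), 1L)
  expect_equal(unname(fit$est_reads), 4, tolerance = 1e-6)
  expect_equal(fit$removed$reason, "set-cover")
  # above the cutoff the thresholding never engages: a well-covered
  # identical pair stays unresolved at an even split, by design
  cc2 <- class_collection(list(eq_class(c("A", "B"), 1000)), refs)
  fit2 <- cedar(cc2)
  expect_equal(fit2$est_reads, c(A = 500, B = 500), tolerance = 1e-6)
})

test_that("mass is preserved through EM and thresholding; only the cutoff discards", {
  for (seed in 1:25) {
    cc <- simulate_classes(n_refs = sample(3:10, 1), n_classes = sample(4:25, 1),
                           seed = seed)
    fit <- cedar(cc)
    expect_true(all(abs(fit$mass_trace - cc$total_fragments) <= 1e-6))
    expect_equal(sum(fit$est_reads) + fit$discarded_mass, cc$total_fragments,
                 tolerance = 1e-6)
    # sparsification: nothing reported at or below the cutoff
    expect_true(all(fit$est_reads > fit$options$cutoff))
    # termination: removal rounds never exceed the reference count
    removal_rounds <- unique(fit$removed$round[fit$removed$reason != "final-cutoff"])
    expect_lte(length(removal_rounds), nrow(cc$refs))
  }
})

test_that("the class-level log-likelihood is monotone within each EM block", {
  for (seed in 26:45) {
    cc <- simulate_classes(n_refs = 8, n_classes = 18, seed = seed)
    fit <- cedar(cc)
    for (blk in fit$loglik) {
      if (length(blk) > 1) expect_true(all(diff(blk) >= -1e-8))
    }
  }
})

test_that("the fit object behaves like a model fit", {
  fit <- cedar(fig2_classes())
  expect_s3_class(fit, "cedar_fit")
  expect_output(print(fit), "references reported")
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-9)
  expect_equal(coef(fit, "est_reads"), fitted(fit))
  expect_true(is.finite(as.numeric(logLik(fit))))
  tab <- quant_table(fit)
  expect_equal(tab$estimated_reads, unname(fit$est_reads))
  s <- summary(fit)
  expect_output(print(s), "Removals by reason")
})

test_that("degenerate inputs are rejected", {
  refs <- make_refs("A")
  cc <- class_collection(list(eq_class("A", 1)), refs)
  st <- abundance_state(cc)
  expect_error(em_iteration(st, class_collection(list(eq_class("B", 1)), make_refs("B"))),
               "inactive")
})
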