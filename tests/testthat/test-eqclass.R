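test_that("score-to-probability mapping follows the exponential decay form", {
  expect_equal(score_to_conditional_prob(200, 200), 1.0)
  expect_equal(score_to_conditional_prob(194, 200), exp(-6))
  expect_equal(score_to_conditional_prob(200, 200) / score_to_conditional_prob(194, 200),
               exp(6))
  expect_equal(score_to_conditional_prob(190, 200, alpha = 0.5), exp(-5))
  expect_error(score_to_conditional_prob(201, 200), "exceeds")
})

aln_df <- function(frag, ref, score) {
  data.frame(fragment_id = frag, ref_id = ref, score = score, stringsAsFactors = FALSE)
}

test_that("uniquely mapping fragments collapse to one unit-weight class", {
  refs <- make_refs(c("A", "B"))
  cc <- build_classes(aln_df(c("f1", "f2", "f3"), "A", c(200, 180, 150)), refs)
  expect_equal(length(cc$classes), 1L)
  cl <- cc$classes[[1]]
  expect_equal(cl$label, "A")
  expect_equal(cl$count, 3)
  expect_equal(cl$weights, 1.0)  # every unique mapping is its own best
  expect_equal(cc$total_fragments, 3)
})

test_that("range factorization splits classes by probability bin only when bins > 1", {
  refs <- make_refs(c("A", "B"))
  # f1: B at probability 0.8; f2: B at probability 0.002
  aln <- aln_df(c("f1", "f1", "f2", "f2"), c("A", "B", "A", "B"),
                c(200, 200 + log(0.8), 200, 200 + log(0.002)))
  cc1 <- build_classes(aln, refs, bins = 1)
  expect_equal(length(cc1$classes), 1L)
  expect_equal(cc1$classes[[1]]$label, c("A", "B"))
  expect_equal(cc1$classes[[1]]$count, 2)
  expect_equal(cc1$classes[[1]]$weights, c(1, mean(c(0.8, 0.002))))

  cc4 <- build_classes(aln, refs, bins = 4)
  expect_equal(length(cc4$classes), 2L)
  expect_true(all(vapply(cc4$classes, function(cl) identical(cl$label, c("A", "B")), NA)))
  sigs <- lapply(cc4$classes, `[[`, "bins")
  expect_false(identical(sigs[[1]], sigs[[2]]))  # 0.8 -> bin 4, 0.002 -> bin 1
})

test_that("fragment counts are conserved for every bins setting", {
  set.seed(41)
  refs <- make_refs(sprintf("R%02d", 1:6))
  for (rep in 1:10) {
    nfrag <- sample(5:40, 1)
    rows <- do.call(rbind, lapply(seq_len(nfrag), function(i) {
      m <- sample(1:4, 1)
      aln_df(sprintf("f%03d", i), sample(refs$id, m),
             200 - c(0, cumsum(runif(m - 1, 0, 4))))
    }))
    for (b in c(1, 2, 4, 8)) {
      cc <- build_classes(rows, refs, bins = b)
      expect_equal(cc$total_fragments, nfrag)
      expect_true(all(vapply(cc$classes, function(cl) {
        all(cl$weights > 0 & cl$weights <= 1)
      }, NA)))
    }
  }
})

test_that("unmapped fragments are tallied, not silently dropped", {
  refs <- make_refs("A")
  cc <- build_classes(aln_df("f1", "A", 200), refs,
                      all_fragment_ids = c("f1", "f2", "f3"))
  expect_equal(cc$unmapped, 2L)
  expect_equal(cc$total_fragments, 1)
})

test_that("the class table text format round-trips", {
  cc <- simulate_classes(n_refs = 7, n_classes = 12, seed = 3)
  f <- tempfile(fileext = ".eq")
  write_eqclasses(cc, f)
  back <- read_eqclasses(f)
  expect_equal(back$total_fragments, cc$total_fragments)
  expect_equal(back$refs$id, cc$refs$id)
  expect_equal(back$refs$effective_length, cc$refs$effective_length)
  key <- function(x) {
    k <- vapply(x$classes, function(cl) paste(cl$label, cl$bins, collapse = ";"), "")
    order(k)
  }
  a <- cc$classes[key(cc)]; b <- back$classes[key(back)]
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) {
    expect_equal(b[[i]]$label, a[[i]]$label)
    expect_equal(b[[i]]$count, a[[i]]$count)
    expect_equal(b[[i]]$weights, a[[i]]$weights, tolerance = 1e-12)
    expect_equal(b[[i]]$bins, a[[i]]$bins)
  }
})

test_that("quantification is invariant to class order", {
  cc <- simulate_classes(n_refs = 9, n_classes = 20, seed = 8)
  fit1 <- cedar(cc)
  set.seed(1)
  perm <- sample(seq_along(cc$classes))
  cc2 <- class_collection(cc$classes[perm], cc$refs)
  fit2 <- cedar(cc2)
  expect_equal(fit1$est_reads, fit2$est_reads, tolerance = 1e-9)
  expect_equal(sort(fit1$removed$ref_id), sort(fit2$removed$ref_id))
})

test_that("class invariants are enforced at construction", {
  expect_error(eq_class(character(0), 1), "empty")
  expect_error(eq_class(c("A", "A"), 1), "duplicate")
  expect_error(eq_class("A", 1, weights = 0), "weights")
  expect_error(eq_class("A", 0), "count")
  refs <- make_refs(c("A", "B"))
  expect_error(class_collection(list(eq_class("C", 1)), refs), "unknown reference")
  expect_error(class_collection(list(eq_class("A", 1), eq_class("A", 2)), refs),
               "share both label")
})
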