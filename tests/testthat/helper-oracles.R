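# Independent oracles and shared fixtures. Oracles deliberately avoid
# the code paths they check.

# full-read global affine alignment score via Biostrings (independent
# of the package's own Gotoh aligner); gap of length g costs
# gap_open + g * gap_extend, matching the package convention
oracle_nw_score <- function(q, r, scheme = scoring_scheme()) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(scheme$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- scheme$match
  m["N", ] <- scheme$mismatch; m[, "N"] <- scheme$mismatch
  Biostrings::pairwiseAlignment(q, r, type = "global", substitutionMatrix = m,
                                gapOpening = scheme$gap_open,
                                gapExtension = scheme$gap_extend) |>
    Biostrings::score()
}

# greedy set-cover trace: straightforward re-statement of the rule
# (most uncovered classes, then larger count, then smaller id)
oracle_greedy_cover <- function(labels, candidates, est) {
  retained <- character(0)
  left <- labels
  cand <- candidates
  while (length(left)) {
    ncov <- vapply(cand, function(r) sum(vapply(left, function(l) r %in% l, NA)), 0L)
    e <- est[cand]
    e[is.na(e)] <- 0
    ord <- order(-ncov, -e, cand)
    pick <- cand[ord[1]]
    retained <- c(retained, pick)
    left <- Filter(function(l) !(pick %in% l), left)
    cand <- setdiff(cand, pick)
  }
  retained
}

# plain dense EM over a class collection (uniform prior, no coverage
# term, no thresholding): reference fixed-point solver
oracle_plain_em <- function(cc, iters = 1000) {
  ids <- cc$refs$id
  el <- setNames(cc$refs$effective_length, ids)
  act <- sort(unique(unlist(lapply(cc$classes, `[[`, "label"))))
  est <- setNames(rep(0, length(act)), act)
  total <- cc$total_fragments
  pi <- setNames(rep(1 / length(act), length(act)), act)
  for (t in seq_len(iters)) {
    est[] <- 0
    for (cl in cc$classes) {
      b <- pi[cl$label] * cl$weights / el[cl$label]
      est[cl$label] <- est[cl$label] + cl$count * b / sum(b)
    }
    pi <- est / total
  }
  est
}

# Spearman rho from first principles: average ranks + Pearson formula
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# toy NCBI-style taxonomy dump:
#   1 root; 10 genus; 101,102 species under 10; 20 genus; 201 species
#   under 20 with no family anywhere; 7 points at missing parent 99
write_toy_taxonomy <- function(dir = tempfile("tax")) {
  dir.create(dir, showWarnings = FALSE)
  nodes <- c(
    "1\t|\t1\t|\troot\t|",
    "10\t|\t1\t|\tgenus\t|",
    "101\t|\t10\t|\tspecies\t|",
    "102\t|\t10\t|\tspecies\t|",
    "20\t|\t1\t|\tgenus\t|",
    "201\t|\t20\t|\tspecies\t|",
    "7\t|\t99\t|\tspecies\t|"
  )
  names_l <- c(
    "1\t|\troot\t|\t\t|\tscientific name\t|",
    "10\t|\tExamplea\t|\t\t|\tscientific name\t|",
    "101\t|\tExamplea alpha\t|\t\t|\tscientific name\t|",
    "101\t|\tE. alpha junior\t|\t\t|\tsynonym\t|",
    "102\t|\tExamplea beta\t|\t\t|\tscientific name\t|",
    "20\t|\tSamplea\t|\t\t|\tscientific name\t|",
    "201\t|\tSamplea gamma\t|\t\t|\tscientific name\t|",
    "7\t|\tOrphanus\t|\t\t|\tscientific name\t|"
  )
  writeLines(nodes, file.path(dir, "nodes.dmp"))
  writeLines(names_l, file.path(dir, "names.dmp"))
  dir
}

make_refs <- function(ids, length = 1000L, taxid = NA_character_) {
  data.frame(id = ids, length = length,
             effective_length = effective_length(length),
             taxid = taxid, stringsAsFactors = FALSE)
}

# reconstruction of the worked six-genome scenario: G1 barely covered
# by unique reads, G2/G3 well covered, and a fully symmetric
# multi-mapping island {G4, G5, G6} that EM alone cannot break
fig2_classes <- function() {
  refs <- make_refs(paste0("G", 1:6), length = 10000L)
  class_collection(list(
    eq_class("G1", 2),
    eq_class("G2", 300),
    eq_class("G3", 300),
    eq_class(c("G2", "G3"), 6),
    eq_class(c("G4", "G5", "G6"), 5)
  ), refs)
}
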