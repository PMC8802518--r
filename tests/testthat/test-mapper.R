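set.seed(202)
g3 <- vapply(1:3, function(i) paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = ""), "")
refs3 <- reference_set(setNames(g3, c("r1", "r2", "r3")))
idx3 <- build_kmer_index(refs3, k = 19)

test_that("k-mer index enumerates canonical occurrences", {
  r <- reference_set(c(x = "ACGTACGT"))
  i <- build_kmer_index(r, k = 5)
  expect_equal(length(i$pos), 4L)  # L - k + 1
  r2 <- reference_set(c(x = "AAAAAA"))
  i2 <- build_kmer_index(r2, k = 5)
  expect_equal(ls(i2$env), "AAAAA")
  expect_equal(length(i2$env[["AAAAA"]]), 2L)
  # k-mers overlapping N are skipped
  r3 <- reference_set(c(x = "ACGTANCGTAC"))
  i3 <- build_kmer_index(r3, k = 5)
  expect_false(any(grepl("N", ls(i3$env))))
  expect_true(all(i3$pos >= 0 & i3$pos <= nchar("ACGTANCGTAC") - 5))
})

test_that("index construction validates its inputs", {
  expect_error(build_kmer_index(reference_set(c(a = "ACGTACGTAC")), k = 3), "k must be")
  expect_error(build_kmer_index(reference_set(c(a = "ACGTA")), k = 19), "longer than every")
})

test_that("a perfect-match read scores match * length with a full-M CIGAR", {
  rd <- substr(g3[2], 501, 600)
  rec <- map_fragment(idx3, refs3, rd)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$ref_id, "r2")
  expect_equal(rec$score, 200)
  expect_equal(rec$cigar, "100M")
  expect_equal(rec$pos, 500L)
  expect_equal(rec$strand, "+")
  # its reverse complement maps to the same locus on the minus strand
  rc <- map_fragment(idx3, refs3, revcomp(rd))
  expect_equal(rc$pos, 500L)
  expect_equal(rc$score, 200)
  expect_equal(rc$strand, "-")
})

test_that("a read shared by three references yields three equal-score records", {
  shared <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  gs <- vapply(1:3, function(i) {
    paste0(paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = ""), shared,
           paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = ""))
  }, "")
  rs <- reference_set(setNames(gs, c("a", "b", "c")))
  ix <- build_kmer_index(rs, 19)
  rec <- map_fragment(ix, rs, substr(shared, 11, 110))
  expect_equal(sort(rec$ref_id), c("a", "b", "c"))
  expect_equal(length(unique(rec$score)), 1L)
})

test_that("substituted reads score as the independent global aligner does", {
  set.seed(31)
  for (i in 1:10) {
    start <- sample(200:2800, 1)
    rd <- substr(g3[1], start, start + 99)
    npos <- sample(1:3, 1)
    pos <- sample(10:90, npos)
    for (p in pos) {
      substr(rd, p, p) <- sample(setdiff(c("A", "C", "G", "T"), substr(rd, p, p)), 1)
    }
    rec <- map_fragment(idx3, refs3, rd)
    rec <- rec[rec$ref_id == "r1", ]
    expect_equal(nrow(rec), 1L)
    window <- substr(g3[1], rec$pos + 1, rec$pos + 100)
    expect_equal(rec$score, oracle_nw_score(rd, window))
  }
  # the canonical example: one substitution at position 50
  rd <- substr(g3[1], 1001, 1100)
  substr(rd, 50, 50) <- setdiff(c("A", "C", "G", "T"), substr(rd, 50, 50))[1]
  rec <- map_fragment(idx3, refs3, rd)
  expect_equal(rec$score, 2 * 99 - 4)
})

test_that("stored scores are reproducible from CIGAR and sequences", {
  set.seed(77)
  for (i in 1:15) {
    start <- sample(200:2800, 1)
    rd <- substr(g3[3], start, start + 99)
    for (p in sample(5:95, sample(0:4, 1))) {
      substr(rd, p, p) <- sample(setdiff(c("A", "C", "G", "T"), substr(rd, p, p)), 1)
    }
    rec <- map_fragment(idx3, refs3, rd)
    for (j in seq_len(nrow(rec))) {
      oriented <- if (rec$strand[j] == "-") revcomp(rd) else rd
      ref <- refs3$seq[[rec$ref_id[j]]]
      expect_equal(alignment_score_from_cigar(rec$cigar[j], oriented, ref, rec$pos[j]),
                   rec$score[j])
    }
  }
})

test_that("indels are recovered by the between-MEM aligner", {
  rd <- substr(g3[2], 1201, 1300)
  rd_del <- paste0(substr(rd, 1, 49), substr(rd, 51, 100))  # 1 bp deletion
  rec <- map_fragment(idx3, refs3, rd_del)
  rec <- rec[rec$ref_id == "r2", ]
  expect_match(rec$cigar, "D")
  expect_equal(rec$score, 2 * 99 - (5 + 3))
  oriented_ref <- refs3$seq[["r2"]]
  expect_equal(alignment_score_from_cigar(rec$cigar, rd_del, oriented_ref, rec$pos),
               rec$score)
})

test_that("the fraction-of-best filter is inclusive at the boundary", {
  rec <- data.frame(fragment_id = "f", ref_id = c("a", "b", "c"),
                    score = c(130, 129, 200), stringsAsFactors = FALSE)
  kept <- filter_by_score(rec, fragment_length = 100, scoring_scheme())
  expect_equal(kept$score, c(130, 200))  # threshold 0.65 * 200 = 130, inclusive
  strict <- filter_by_score(rec, 100, scoring_scheme(min_score_fraction = 1))
  expect_equal(strict$score, 200)
})

test_that("paired-end mates must agree on reference and orientation", {
  frag <- substr(g3[3], 1001, 1300)
  m1 <- substr(frag, 1, 100)
  m2 <- revcomp(substr(frag, 201, 300))
  rec <- map_reads(idx3, refs3, c(f = m1), c(f = m2))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$ref_id, "r3")
  expect_equal(rec$score, 400)
  expect_true(rec$strand != rec$strand2)
  # same-orientation mate pair is rejected (orphans dropped by default)
  bad <- map_reads(idx3, refs3, c(f = m1), c(f = substr(frag, 201, 300)))
  expect_equal(nrow(bad), 0L)
  orph <- map_reads(idx3, refs3, c(f = m1), c(f = substr(frag, 201, 300)),
                    keep_orphans = TRUE)
  expect_true(nrow(orph) >= 1)
  expect_false(any(orph$paired))
})

test_that("error-free reads always map best to their source genome", {
  set.seed(99)
  genomes <- simulate_genomes(6, 2000, seed = 5)
  truth <- community_truth(genomes, setNames(rep(50, 6), genomes$info$id))
  rd <- simulate_reads(truth, read_len = 80, frag_mean = 200, frag_sd = 20,
                       sub_rate = 0, seed = 6)
  ix <- build_kmer_index(genomes, 19)
  aln <- map_reads(ix, genomes, rd$reads1, rd$reads2)
  src <- sub("\\|.*$", "", aln$fragment_id)
  best <- tapply(aln$score, aln$fragment_id, max)
  on_src <- aln$ref_id == src
  expect_true(all(tapply(on_src & aln$score == best[aln$fragment_id],
                         aln$fragment_id, any)))
  # unrelated random genomes share no 19-mers: reads map uniquely
  expect_true(all(table(aln$fragment_id) == 1))
  expect_equal(length(unique(aln$fragment_id)), 300L)
})
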