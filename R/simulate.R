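# Synthetic communities: genomes with controlled-identity islands,
# ground-truth counts, and error-bearing paired-end reads. Everything
# is deterministic for a fixed seed; the global RNG state is restored.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

#' Simulate community genomes with multi-mapping islands
#'
#' Non-island genomes are i.i.d. uniform sequences. Each island is
#' built from a shared ancestral sequence, with every member mutated
#' independently at per-base substitution rate `1 - identity`, so
#' members stay nearly identical and their reads multi-map within the
#' island.
#'
#' @param n number of genomes (ids `G1` ... `Gn`).
#' @param length genome length in bases (>= 1000).
#' @param islands list of island specifications, each a list with
#'   `members` (integer indices into `1:n`) and `identity` (fraction in
#'   `[0.9, 1)`, identity of each member to the island ancestor).
#' @param seed integer seed (deterministic output).
#' @param mean_fragment mean fragment length used for effective lengths.
#' @return a [reference_set()].
#' @export
simulate_genomes <- function(n, length = 10000L, islands = list(), seed = NULL,
                             mean_fragment = 300) {
  stopifnot(n >= 1, length >= 1000)
  members_all <- integer(0)
  for (isl in islands) {
    if (is.null(isl$members) || is.null(isl$identity)) {
      stop("each island needs 'members' and 'identity'")
    }
    if (isl$identity < 0.9 || isl$identity >= 1) {
      stop("island identity must be in [0.9, 1)")
    }
    if (length(isl$members) > n || any(isl$members < 1) || any(isl$members > n)) {
      stop("island references more members than available genomes")
    }
    members_all <- c(members_all, isl$members)
  }
  if (anyDuplicated(members_all)) stop("islands overlap")
  with_seed(seed, {
    seqs <- character(n)
    free <- setdiff(seq_len(n), members_all)
    for (i in free) seqs[i] <- rand_dna(length)
    for (isl in islands) {
      base <- rand_dna(length)
      rate <- 1 - isl$identity
      for (i in isl$members) seqs[i] <- mutate_chars(base, rate)
    }
    reference_set(setNames(seqs, paste0("G", seq_len(n))),
                  mean_fragment = mean_fragment)
  })
}

# substitute each base independently with probability rate, always to a
# different base
mutate_chars <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    pick <- sample.int(3L, length(hit), replace = TRUE)
    ch[hit] <- mapply(function(b, p) alt[[b]][p], ch[hit], pick, USE.NAMES = FALSE)
  }
  paste(ch, collapse = "")
}

#' Bundle simulated genomes with ground-truth counts
#'
#' Absent genomes keep a zero count but remain in the reference,
#' mimicking index/dataset mismatch.
#'
#' @param genomes a [reference_set()].
#' @param true_counts integer vector of true fragment counts, named by
#'   genome id (missing genomes default to 0).
#' @param island_spec the island specification used to build the
#'   genomes (bookkeeping).
#' @return an object of class `community_truth`.
#' @export
community_truth <- function(genomes, true_counts, island_spec = list()) {
  stopifnot(inherits(genomes, "reference_set"))
  cnt <- setNames(rep(0, nrow(genomes$info)), genomes$info$id)
  if (is.null(names(true_counts))) {
    stopifnot(length(true_counts) == length(cnt))
    cnt[] <- true_counts
  } else {
    unknown <- setdiff(names(true_counts), names(cnt))
    if (length(unknown)) stop("true_counts names not in genome set: ", unknown[1])
    cnt[names(true_counts)] <- true_counts
  }
  if (sum(cnt) <= 0) stop("total true count must be positive")
  if (any(cnt < 0)) stop("negative true count")
  structure(list(genomes = genomes, true_counts = cnt, island_spec = island_spec),
            class = "community_truth")
}

#' Simulate paired-end reads from a community
#'
#' For each genome, exactly its true count of fragments is drawn with
#' uniform start positions; fragment lengths are normal
#' (`frag_mean`, `frag_sd`) truncated to `[read_len, genome length]`.
#' Mates are the fragment's two ends, the second reverse-complemented.
#' Substitution errors are i.i.d. per base. Read names encode
#' provenance as `genome|index`, and the output order is globally
#' shuffled.
#'
#' @param truth a [community_truth()].
#' @param read_len read length in bases (<= `frag_mean`).
#' @param frag_mean mean fragment length (default 300).
#' @param frag_sd fragment length standard deviation (default 50).
#' @param sub_rate per-base substitution error probability (default
#'   0.002).
#' @param seed integer seed.
#' @param out_prefix if non-NULL, write `<prefix>_1.fastq`,
#'   `<prefix>_2.fastq` and `<prefix>_truth.tsv`.
#' @return invisibly, a list with `reads1`, `reads2` (named character
#'   vectors) and `truth` (data.frame `genome_id`, `taxid`,
#'   `true_reads`).
#' @export
simulate_reads <- function(truth, read_len = 100L, frag_mean = 300, frag_sd = 50,
                           sub_rate = 0.002, seed = NULL, out_prefix = NULL) {
  stopifnot(inherits(truth, "community_truth"))
  if (read_len > frag_mean) stop("read_len must not exceed frag_mean")
  info <- truth$genomes$info
  cnt <- truth$true_counts
  short <- info$id[cnt[info$id] > 0 & info$length < read_len]
  if (length(short)) stop("genome shorter than read_len: ", short[1])

  res <- with_seed(seed, {
    r1 <- vector("list", nrow(info)); r2 <- vector("list", nrow(info))
    for (gi in seq_len(nrow(info))) {
      c_g <- cnt[[info$id[gi]]]
      if (c_g == 0) next
      g <- truth$genomes$seq[[gi]]
      L <- info$length[gi]
      flen <- pmin(L, pmax(read_len, round(rnorm(c_g, frag_mean, frag_sd))))
      start <- floor(runif(c_g, min = 1, max = L - flen + 1 + 1))  # 1-based
      m1 <- substring(g, start, start + read_len - 1L)
      m2 <- revcomp(substring(g, start + flen - read_len, start + flen - 1L))
      nm <- paste0(info$id[gi], "|", seq_len(c_g))
      r1[[gi]] <- setNames(m1, nm); r2[[gi]] <- setNames(m2, nm)
    }
    reads1 <- unlist(r1); reads2 <- unlist(r2)
    if (sub_rate > 0) {
      reads1 <- apply_substitutions(reads1, sub_rate)
      reads2 <- apply_substitutions(reads2, sub_rate)
    }
    perm <- sample.int(length(reads1))
    list(reads1 = reads1[perm], reads2 = reads2[perm])
  })
  truth_tab <- data.frame(genome_id = info$id, taxid = info$taxid,
                          true_reads = unname(cnt[info$id]), stringsAsFactors = FALSE)
  out <- list(reads1 = res$reads1, reads2 = res$reads2, truth = truth_tab)
  if (!is.null(out_prefix)) {
    write_fastq(setNames(out$reads1, paste0(names(out$reads1), "/1")),
                paste0(out_prefix, "_1.fastq"))
    write_fastq(setNames(out$reads2, paste0(names(out$reads2), "/2")),
                paste0(out_prefix, "_2.fastq"))
    write.table(truth_tab, paste0(out_prefix, "_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}

apply_substitutions <- function(reads, rate) {
  n_mut <- stats::rbinom(length(reads), nchar(reads), rate)
  todo <- which(n_mut > 0)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"), N = c("A", "C", "G"))
  for (i in todo) {
    ch <- strsplit(reads[[i]], "")[[1]]
    pos <- sample.int(length(ch), n_mut[i])
    for (p in pos) ch[p] <- sample(alt[[ch[p]]], 1L)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulate a random class collection
#'
#' Generates random range-factorized equivalence-class instances for
#' stress-testing the engine: random reference lengths, random label
#' subsets, weights in `(0, 1]` with bin signatures derived from the
#' weights, and random counts. Duplicate (label, bin signature) classes
#' are merged.
#'
#' @param n_refs number of references.
#' @param n_classes number of classes drawn (before merging).
#' @param seed integer seed.
#' @param max_label maximum label size.
#' @param bins number of probability bins.
#' @param max_count maximum per-class fragment count.
#' @return a [class_collection()].
#' @export
simulate_classes <- function(n_refs = 8L, n_classes = 15L, seed = NULL,
                             max_label = 4L, bins = 4L, max_count = 50L) {
  stopifnot(n_refs >= 1, n_classes >= 1, max_label >= 1)
  with_seed(seed, {
    ids <- sprintf("R%03d", seq_len(n_refs))
    len <- sample(1000:10000, n_refs, replace = TRUE)
    refs <- data.frame(id = ids, length = len,
                       effective_length = effective_length(len),
                       taxid = NA_character_, stringsAsFactors = FALSE)
    raw <- lapply(seq_len(n_classes), function(i) {
      m <- sample.int(min(max_label, n_refs), 1L)
      lab <- sort(sample(ids, m))
      w <- runif(m, min = 0.02, max = 1)
      w[sample.int(m, 1L)] <- 1  # some member attains the best score
      eq_class(label = lab, count = sample.int(max_count, 1L),
               weights = w, bins = pmin(bins, as.integer(ceiling(w * bins))))
    })
    keys <- vapply(raw, function(cl) {
      paste(paste(cl$label, cl$bins, sep = "@"), collapse = ",")
    }, "")
    merged <- lapply(split(raw, keys), function(grp) {
      if (length(grp) == 1L) return(grp[[1L]])
      cnt <- vapply(grp, `[[`, 0, "count")
      wmat <- matrix(unlist(lapply(grp, `[[`, "weights")), ncol = length(grp))
      eq_class(label = grp[[1L]]$label, count = sum(cnt),
               weights = as.vector(wmat %*% cnt) / sum(cnt), bins = grp[[1L]]$bins)
    })
    names(merged) <- NULL
    class_collection(merged, refs)
  })
}
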