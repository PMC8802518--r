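# Simplified selective alignment: canonical k-mer hash seeding, maximal
# exact match (MEM) detection as diagonal runs of k-mer hits, monotone
# chaining, affine-gap alignment of between-MEM regions and read ends,
# and a fraction-of-best score filter. Coordinates are 0-based
# half-open internally and 1-based on SAM emission.

#' Alignment scoring scheme
#'
#' @param match match bonus (positive integer, default 2).
#' @param mismatch mismatch penalty (negative, default -4).
#' @param gap_open gap-open cost (positive, default 5); a gap of length
#'   `g` costs `gap_open + g * gap_extend`.
#' @param gap_extend per-base gap-extension cost (positive, default 3).
#' @param min_score_fraction minimum fraction of the best possible
#'   alignment score a mapping must reach to be retained (default 0.65,
#'   inclusive).
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -4L, gap_open = 5L,
                           gap_extend = 3L, min_score_fraction = 0.65) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            min_score_fraction > 0, min_score_fraction <= 1)
  structure(list(match = as.numeric(match), mismatch = as.numeric(mismatch),
                 gap_open = as.numeric(gap_open), gap_extend = as.numeric(gap_extend),
                 min_score_fraction = min_score_fraction),
            class = "scoring_scheme")
}

subst_matrix <- function(scheme) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(scheme$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- scheme$match
  m["N", ] <- scheme$mismatch  # N never matches anything, itself included
  m[, "N"] <- scheme$mismatch
  m
}

#' Build a canonical k-mer index over a reference set
#'
#' Indexes every N-free k-mer occurrence of every reference, keyed by
#' the lexicographic minimum of the k-mer and its reverse complement,
#' with the occurrence strand recorded.
#'
#' @param refs a [reference_set()].
#' @param k k-mer length, between 5 and 31 (default 19).
#' @return an object of class `kmer_index`.
#' @export
build_kmer_index <- function(refs, k = 19L) {
  stopifnot(inherits(refs, "reference_set"))
  k <- as.integer(k)
  if (k < 5L || k > 31L) stop("k must be in [5, 31]")
  if (nrow(refs$info) == 0L) stop("empty reference set")
  if (all(refs$info$length < k)) stop("k is longer than every reference sequence")

  keys <- vector("list", nrow(refs$info))
  refi <- vector("list", nrow(refs$info))
  posi <- vector("list", nrow(refs$info))
  fwdi <- vector("list", nrow(refs$info))
  for (i in seq_len(nrow(refs$info))) {
    s <- refs$seq[[i]]
    L <- nchar(s)
    if (L < k) next
    f <- substring(s, 1:(L - k + 1L), k:L)
    rc <- revcomp(s)
    r <- substring(rc, seq(L - k + 1L, 1L), seq(L, k))  # r[j] == revcomp(f[j])
    ok <- !grepl("N", f, fixed = TRUE)
    if (!any(ok)) next
    f <- f[ok]; r <- r[ok]
    fwd <- f <= r
    keys[[i]] <- ifelse(fwd, f, r)
    refi[[i]] <- rep.int(i, length(f))
    posi[[i]] <- (which(ok)) - 1L  # 0-based
    fwdi[[i]] <- fwd
  }
  key <- unlist(keys, use.names = FALSE)
  if (is.null(key) || length(key) == 0L) stop("no indexable k-mers in reference set")
  idx <- list(
    k = k,
    ref = unlist(refi, use.names = FALSE),
    pos = unlist(posi, use.names = FALSE),
    fwd = unlist(fwdi, use.names = FALSE),
    ref_ids = refs$info$id
  )
  ent <- split(seq_along(key), key)
  idx$env <- list2env(ent, hash = TRUE, size = max(16L, length(ent)))
  structure(idx, class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: k=%d, %d occurrences over %d references\n",
              x$k, length(x$pos), length(x$ref_ids)))
  invisible(x)
}

# MEMs for a batch of reads: diagonal runs of consecutive canonical
# k-mer hits. Returns one row per MEM with 0-based coordinates on the
# oriented read (the read itself for plus, its reverse complement for
# minus alignments).
find_mems <- function(index, reads) {
  k <- index$k
  L <- nchar(reads)
  use <- which(L >= k)
  if (!length(use)) {
    return(data.frame(read = integer(0), ref = integer(0), plus = logical(0),
                      qstart = integer(0), rstart = integer(0), len = integer(0)))
  }
  rc <- character(length(reads))
  rc[use] <- revcomp(reads[use])
  keyl <- vector("list", length(use))
  offl <- vector("list", length(use))
  qfl <- vector("list", length(use))
  rdl <- vector("list", length(use))
  for (jj in seq_along(use)) {
    i <- use[jj]
    Li <- L[i]
    f <- substring(reads[i], 1:(Li - k + 1L), k:Li)
    r <- substring(rc[i], seq(Li - k + 1L, 1L), seq(Li, k))
    ok <- !grepl("N", f, fixed = TRUE)
    if (!any(ok)) next
    f <- f[ok]; r <- r[ok]
    fwd <- f <= r
    keyl[[jj]] <- ifelse(fwd, f, r)
    offl[[jj]] <- which(ok) - 1L
    qfl[[jj]] <- fwd
    rdl[[jj]] <- rep.int(i, length(f))
  }
  key <- unlist(keyl, use.names = FALSE)
  if (is.null(key) || !length(key)) {
    return(data.frame(read = integer(0), ref = integer(0), plus = logical(0),
                      qstart = integer(0), rstart = integer(0), len = integer(0)))
  }
  off <- unlist(offl, use.names = FALSE)
  qf <- unlist(qfl, use.names = FALSE)
  rd <- unlist(rdl, use.names = FALSE)

  uk <- unique(key)
  vals <- mget(uk, envir = index$env, ifnotfound = list(NULL))
  hl <- vals[match(key, uk)]
  ln <- lengths(hl)
  if (sum(ln) == 0L) {
    return(data.frame(read = integer(0), ref = integer(0), plus = logical(0),
                      qstart = integer(0), rstart = integer(0), len = integer(0)))
  }
  eidx <- unlist(hl, use.names = FALSE)
  rd <- rep.int(rd, ln); off <- rep.int(off, ln); qf <- rep.int(qf, ln)
  ref <- index$ref[eidx]; rpos <- index$pos[eidx]; rfwd <- index$fwd[eidx]
  plus <- qf == rfwd
  oe <- ifelse(plus, off, L[rd] - k - off)  # offset on the oriented read
  dg <- rpos - oe
  o <- order(rd, ref, plus, dg, oe)
  n <- length(o)
  rd <- rd[o]; ref <- ref[o]; plus <- plus[o]; dg <- dg[o]; oe <- oe[o]
  newgrp <- c(TRUE, rd[-1L] != rd[-n] | ref[-1L] != ref[-n] |
                plus[-1L] != plus[-n] | dg[-1L] != dg[-n])
  newrun <- newgrp | c(TRUE, oe[-1L] != oe[-n] + 1L)
  first <- which(newrun)
  last <- c(first[-1L] - 1L, n)
  data.frame(
    read = rd[first], ref = ref[first], plus = plus[first],
    qstart = oe[first], rstart = dg[first] + oe[first],
    len = oe[last] - oe[first] + k
  )
}

# affine-gap (Gotoh) global alignment of a read segment against a
# reference window; returns score and CIGAR ops (lengths + characters).
# Hand-rolled because the segments are tiny (typically 1-5 bases
# between adjacent MEMs) and per-call overhead dominates runtime.
seg_align <- function(qseg, rseg, scheme) {
  nq <- nchar(qseg); nr <- nchar(rseg)
  if (nq == 0L && nr == 0L) return(list(score = 0, len = integer(0), op = character(0)))
  if (nq == 0L) {
    return(list(score = -(scheme$gap_open + scheme$gap_extend * nr), len = nr, op = "D"))
  }
  if (nr == 0L) {
    return(list(score = -(scheme$gap_open + scheme$gap_extend * nq), len = nq, op = "I"))
  }
  qc <- strsplit(qseg, "")[[1]]
  rc <- strsplit(rseg, "")[[1]]
  if (nq == 1L && nr == 1L) {
    sub <- if (qc == rc && qc != "N") scheme$match else scheme$mismatch
    dbl <- -2 * (scheme$gap_open + scheme$gap_extend)
    if (sub >= dbl) return(list(score = sub, len = 1L, op = "M"))
    return(list(score = dbl, len = c(1L, 1L), op = c("I", "D")))
  }
  go <- scheme$gap_open; ge <- scheme$gap_extend
  NEG <- -1e12
  # state matrices: M diagonal, X gap in reference (read insertion),
  # Y gap in read (deletion); gap of length g costs go + g * ge
  M <- matrix(NEG, nq + 1L, nr + 1L)
  X <- matrix(NEG, nq + 1L, nr + 1L)
  Y <- matrix(NEG, nq + 1L, nr + 1L)
  tM <- matrix(0L, nq + 1L, nr + 1L)  # 1 from M, 2 from X, 3 from Y
  tX <- matrix(0L, nq + 1L, nr + 1L)
  tY <- matrix(0L, nq + 1L, nr + 1L)
  M[1L, 1L] <- 0
  if (nq >= 1L) { X[-1L, 1L] <- -(go + ge * seq_len(nq)); tX[-1L, 1L] <- 2L }
  if (nr >= 1L) { Y[1L, -1L] <- -(go + ge * seq_len(nr)); tY[1L, -1L] <- 3L }
  for (i in 2L:(nq + 1L)) {
    qi <- qc[i - 1L]
    for (j in 2L:(nr + 1L)) {
      sub <- if (qi == rc[j - 1L] && qi != "N") scheme$match else scheme$mismatch
      mm <- M[i - 1L, j - 1L]; mx <- X[i - 1L, j - 1L]; my <- Y[i - 1L, j - 1L]
      best <- if (mm >= mx && mm >= my) 1L else if (mx >= my) 2L else 3L
      M[i, j] <- max(mm, mx, my) + sub
      tM[i, j] <- best
      xo <- M[i - 1L, j] - (go + ge); xe <- X[i - 1L, j] - ge
      if (xo >= xe) { X[i, j] <- xo; tX[i, j] <- 1L } else { X[i, j] <- xe; tX[i, j] <- 2L }
      yo <- M[i, j - 1L] - (go + ge); ye <- Y[i, j - 1L] - ge
      if (yo >= ye) { Y[i, j] <- yo; tY[i, j] <- 1L } else { Y[i, j] <- ye; tY[i, j] <- 3L }
    }
  }
  i <- nq + 1L; j <- nr + 1L
  sc <- c(M[i, j], X[i, j], Y[i, j])
  st <- which.max(sc)
  score <- sc[st]
  ops <- character(nq + nr)
  no <- 0L
  while (i > 1L || j > 1L) {
    no <- no + 1L
    if (st == 1L) {
      ops[no] <- "M"; st <- tM[i, j]; i <- i - 1L; j <- j - 1L
    } else if (st == 2L) {
      ops[no] <- "I"; st <- tX[i, j]; i <- i - 1L
    } else {
      ops[no] <- "D"; st <- tY[i, j]; j <- j - 1L
    }
  }
  r <- rle(rev(ops[seq_len(no)]))
  list(score = score, len = r$lengths, op = r$values)
}

merge_cigar_ops <- function(lens, ops) {
  if (!length(lens)) return("")
  keep <- lens > 0L
  lens <- lens[keep]; ops <- ops[keep]
  if (!length(lens)) return("")
  grp <- cumsum(c(TRUE, ops[-1L] != ops[-length(ops)]))
  lens <- as.integer(tapply(lens, grp, sum))
  ops <- ops[!duplicated(grp)]
  paste0(lens, ops, collapse = "")
}

# best chain of MEMs on one (read, reference, strand): monotone DP
# maximizing sum of MEM lengths minus 0.01 * (read gap + reference gap)
chain_mems <- function(qs, rs, ln) {
  n <- length(qs)
  if (n == 1L) return(1L)
  o <- order(qs, rs)
  qs <- qs[o]; rs <- rs[o]; ln <- ln[o]
  dp <- as.numeric(ln)
  bp <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (qs[i] >= qs[j] + ln[j] && rs[i] >= rs[j] + ln[j]) {
        gap <- 0.01 * ((qs[i] - qs[j] - ln[j]) + (rs[i] - rs[j] - ln[j]))
        cand <- dp[j] + ln[i] - gap
        if (cand > dp[i]) { dp[i] <- cand; bp[i] <- j }
      }
    }
  }
  end <- which.max(dp)
  chain <- end
  while (bp[chain[1L]] > 0L) chain <- c(bp[chain[1L]], chain)
  o[chain]
}

# score + CIGAR + leftmost position for one chained candidate
align_candidate <- function(Q, refseq, qs, rs, ln, scheme) {
  L <- nchar(Q)
  Lr <- nchar(refseq)
  sel <- chain_mems(qs, rs, ln)
  qs <- qs[sel]; rs <- rs[sel]; ln <- ln[sel]
  score <- scheme$match * sum(ln)
  lens <- integer(0); ops <- character(0)
  # left overhang
  if (qs[1L] > 0L) {
    rwin <- max(0L, rs[1L] - qs[1L])
    sa <- seg_align(substr(Q, 1L, qs[1L]), substr(refseq, rwin + 1L, rs[1L]), scheme)
    score <- score + sa$score
    lens <- c(lens, sa$len); ops <- c(ops, sa$op)
    pos <- rwin
  } else {
    pos <- rs[1L]
  }
  lens <- c(lens, ln[1L]); ops <- c(ops, "M")
  if (length(qs) > 1L) {
    for (j in 2:length(qs)) {
      qgap_from <- qs[j - 1L] + ln[j - 1L]
      rgap_from <- rs[j - 1L] + ln[j - 1L]
      sa <- seg_align(substr(Q, qgap_from + 1L, qs[j]),
                      substr(refseq, rgap_from + 1L, rs[j]), scheme)
      score <- score + sa$score
      lens <- c(lens, sa$len, ln[j]); ops <- c(ops, sa$op, "M")
    }
  }
  # right overhang
  qend <- qs[length(qs)] + ln[length(ln)]
  rend <- rs[length(rs)] + ln[length(ln)]
  if (qend < L) {
    rwin_end <- min(Lr, rend + (L - qend))
    sa <- seg_align(substr(Q, qend + 1L, L), substr(refseq, rend + 1L, rwin_end), scheme)
    score <- score + sa$score
    lens <- c(lens, sa$len); ops <- c(ops, sa$op)
  }
  list(score = score, pos = pos, cigar = merge_cigar_ops(lens, ops))
}

empty_alignments <- function() {
  structure(data.frame(
    fragment_id = character(0), ref_id = character(0), score = numeric(0),
    pos = integer(0), strand = character(0), cigar = character(0),
    paired = logical(0), pos2 = integer(0), strand2 = character(0),
    cigar2 = character(0), score1 = numeric(0), score2 = numeric(0),
    len1 = integer(0), len2 = integer(0),
    frag_len = integer(0), stringsAsFactors = FALSE
  ), class = c("cedar_alignments", "data.frame"))
}

# per-mate candidate table for a batch of oriented reads:
# one row per (read, ref) with the best-strand chained alignment
mate_candidates <- function(index, refs, reads, scheme) {
  mems <- find_mems(index, reads)
  if (!nrow(mems)) {
    return(data.frame(read = integer(0), ref = integer(0), plus = logical(0),
                      score = numeric(0), pos = integer(0), cigar = character(0)))
  }
  L <- nchar(reads)
  full <- mems$len == L[mems$read]  # MEM covers the whole read: perfect match
  res <- data.frame(
    read = mems$read, ref = mems$ref, plus = mems$plus,
    score = NA_real_, pos = NA_integer_, cigar = NA_character_,
    stringsAsFactors = FALSE
  )
  res$score[full] <- scheme$match * mems$len[full]
  res$pos[full] <- mems$rstart[full]
  res$cigar[full] <- paste0(mems$len[full], "M")

  # group (read, ref, plus); groups already contiguous from find_mems ordering
  n <- nrow(mems)
  newgrp <- c(TRUE, mems$read[-1L] != mems$read[-n] | mems$ref[-1L] != mems$ref[-n] |
                mems$plus[-1L] != mems$plus[-n])
  keeprow <- logical(n)
  first <- which(newgrp)
  last <- c(first[-1L] - 1L, n)
  rcs <- NULL
  if (!all(full)) rcs <- revcomp(reads)  # one vectorized call per batch
  for (g in seq_along(first)) {
    rows <- first[g]:last[g]
    if (any(full[rows])) {
      # keep the full-length perfect record, drop partial seeds
      keeprow[rows[full[rows]][1L]] <- TRUE
      next
    }
    rd <- mems$read[rows[1L]]
    Q <- if (mems$plus[rows[1L]]) reads[rd] else rcs[rd]
    ac <- align_candidate(Q, refs$seq[[mems$ref[rows[1L]]]],
                          mems$qstart[rows], mems$rstart[rows], mems$len[rows], scheme)
    r1 <- rows[1L]
    res$score[r1] <- ac$score; res$pos[r1] <- ac$pos; res$cigar[r1] <- ac$cigar
    keeprow[r1] <- TRUE
  }
  res <- res[keeprow, , drop = FALSE]
  # best strand per (read, ref); ties prefer plus
  o <- order(res$read, res$ref, -res$score, !res$plus)
  res <- res[o, , drop = FALSE]
  res[!duplicated(res[, c("read", "ref")]), , drop = FALSE]
}

#' Map reads or read pairs against an indexed reference set
#'
#' Seeds each read with canonical k-mer hits extended to maximal exact
#' matches, chains MEMs per reference and strand, aligns the regions
#' between chained MEMs and at read ends with an affine-gap global
#' aligner, and scores each candidate. For pairs, both mates must map
#' to the same reference in opposite orientations within `frag_span`
#' bases; the fragment score is the sum of mate scores. By default the
#' fraction-of-best score filter ([filter_by_score()]) is applied.
#'
#' @param index a [build_kmer_index()] index.
#' @param refs the [reference_set()] the index was built from.
#' @param reads named character vector of read sequences (names are
#'   fragment ids).
#' @param mates optional second-mate sequences (same names, same order).
#' @param scheme a [scoring_scheme()].
#' @param frag_span maximum paired-end fragment span in bases.
#' @param keep_orphans keep fragments where only one mate maps; the
#'   orphan record is scored and filtered against the mapped mate's
#'   length only (half weight). Default drops orphans.
#' @param filter apply [filter_by_score()] (default TRUE).
#' @param chunk_size reads per processing batch.
#' @return a `cedar_alignments` data.frame, one row per (fragment,
#'   reference) candidate: `fragment_id`, `ref_id`, `score`, `pos`
#'   (0-based leftmost of mate 1), `strand`, `cigar`, `paired`, `pos2`,
#'   `strand2`, `cigar2`, `len1`, `len2`, `frag_len`. Unmapped
#'   fragments are absent.
#' @export
map_reads <- function(index, refs, reads, mates = NULL, scheme = scoring_scheme(),
                      frag_span = 1000L, keep_orphans = FALSE, filter = TRUE,
                      chunk_size = 4000L) {
  stopifnot(inherits(index, "kmer_index"), inherits(refs, "reference_set"))
  if (length(reads) == 0L) return(empty_alignments())
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("frag", seq_along(reads))
  paired <- !is.null(mates)
  if (paired) stopifnot(length(mates) == length(reads))
  out <- vector("list", ceiling(length(reads) / chunk_size))
  ci <- 0L
  for (start in seq(1L, length(reads), by = chunk_size)) {
    ci <- ci + 1L
    sel <- start:min(length(reads), start + chunk_size - 1L)
    r1 <- toupper(unname(reads[sel]))
    c1 <- mate_candidates(index, refs, r1, scheme)
    if (paired) {
      r2 <- toupper(unname(mates[sel]))
      c2 <- mate_candidates(index, refs, r2, scheme)
      m <- merge(c1, c2, by = c("read", "ref"), suffixes = c("1", "2"))
      m <- m[m$plus1 != m$plus2, , drop = FALSE]
      if (nrow(m)) {
        span <- abs(m$pos1 - m$pos2) + pmax(nchar(r1[m$read]), nchar(r2[m$read]))
        m <- m[span <= frag_span, , drop = FALSE]
      }
      rec <- data.frame(
        fragment_id = ids[sel][m$read], ref_id = refs$info$id[m$ref],
        score = m$score1 + m$score2, pos = m$pos1,
        strand = ifelse(m$plus1, "+", "-"), cigar = m$cigar1,
        paired = rep(TRUE, nrow(m)), pos2 = m$pos2, strand2 = ifelse(m$plus2, "+", "-"),
        cigar2 = m$cigar2, score1 = m$score1, score2 = m$score2,
        len1 = nchar(r1[m$read]), len2 = nchar(r2[m$read]),
        stringsAsFactors = FALSE
      )
      rec$frag_len <- rec$len1 + rec$len2
      if (keep_orphans) {
        pairedreads <- unique(m$read)
        orph <- function(cc, ln, mate2) {
          cc <- cc[!(cc$read %in% pairedreads), , drop = FALSE]
          if (!nrow(cc)) return(NULL)
          data.frame(
            fragment_id = ids[sel][cc$read], ref_id = refs$info$id[cc$ref],
            score = cc$score, pos = cc$pos, strand = ifelse(cc$plus, "+", "-"),
            cigar = cc$cigar, paired = FALSE, pos2 = NA_integer_,
            strand2 = NA_character_, cigar2 = NA_character_,
            score1 = cc$score, score2 = NA_real_,
            len1 = ln[cc$read], len2 = 0L, frag_len = ln[cc$read],
            stringsAsFactors = FALSE
          )
        }
        rec <- rbind(rec, orph(c1, nchar(r1), FALSE), orph(c2, nchar(r2), TRUE))
      }
    } else {
      rec <- data.frame(
        fragment_id = ids[sel][c1$read], ref_id = refs$info$id[c1$ref],
        score = c1$score, pos = c1$pos, strand = ifelse(c1$plus, "+", "-"),
        cigar = c1$cigar, paired = FALSE, pos2 = NA_integer_,
        strand2 = NA_character_, cigar2 = NA_character_,
        score1 = c1$score, score2 = NA_real_,
        len1 = nchar(r1)[c1$read], len2 = 0L, stringsAsFactors = FALSE
      )
      rec$frag_len <- rec$len1
    }
    out[[ci]] <- rec
  }
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) return(empty_alignments())
  if (filter) {
    best <- scheme$match * res$frag_len
    res <- res[res$score >= scheme$min_score_fraction * best, , drop = FALSE]
  }
  res <- res[order(res$fragment_id, res$ref_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("cedar_alignments", "data.frame")
  attr(res, "scheme") <- scheme
  res
}

#' Map a single fragment
#'
#' Convenience wrapper around [map_reads()] for one read or read pair;
#' no score filtering is applied (see [filter_by_score()]).
#'
#' @inheritParams map_reads
#' @param read read sequence (single string).
#' @param mate optional mate sequence.
#' @param fragment_id id for the emitted records.
#' @return a `cedar_alignments` data.frame (possibly empty).
#' @export
map_fragment <- function(index, refs, read, mate = NULL, scheme = scoring_scheme(),
                         frag_span = 1000L, fragment_id = "fragment") {
  map_reads(index, refs, setNames(read, fragment_id),
            mates = if (is.null(mate)) NULL else setNames(mate, fragment_id),
            scheme = scheme, frag_span = frag_span, filter = FALSE)
}

#' Filter alignment records by fraction of the best possible score
#'
#' The best possible score for a fragment is `match * fragment_length`
#' (mate lengths summed for pairs); records scoring at least
#' `min_score_fraction` of it (inclusive) are retained.
#'
#' @param records `cedar_alignments` rows belonging to one fragment.
#' @param fragment_length total fragment length in bases.
#' @param scheme a [scoring_scheme()].
#' @return the retained records.
#' @export
filter_by_score <- function(records, fragment_length, scheme = scoring_scheme()) {
  if (!nrow(records)) return(records)
  best <- scheme$match * fragment_length
  records[records$score >= scheme$min_score_fraction * best, , drop = FALSE]
}

parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", toks)),
       op = sub("^\\d+", "", toks))
}

#' Recompute an alignment score from a CIGAR string
#'
#' Walks the CIGAR against the read and reference sequences, scoring
#' matches/mismatches in `M` runs and affine penalties for `I`/`D`
#' runs. Used to verify stored scores.
#'
#' @param cigar CIGAR string.
#' @param read read sequence as aligned (already reverse-complemented
#'   for minus-strand records).
#' @param refseq full reference sequence.
#' @param pos 0-based leftmost reference position of the alignment.
#' @param scheme a [scoring_scheme()].
#' @return numeric score.
#' @export
alignment_score_from_cigar <- function(cigar, read, refseq, pos, scheme = scoring_scheme()) {
  pc <- parse_cigar(cigar)
  qi <- 0L; ri <- pos
  score <- 0
  for (j in seq_along(pc$op)) {
    n <- pc$len[j]
    switch(pc$op[j],
      M = {
        q <- strsplit(substr(read, qi + 1L, qi + n), "")[[1]]
        r <- strsplit(substr(refseq, ri + 1L, ri + n), "")[[1]]
        eq <- q == r & q != "N"
        score <- score + scheme$match * sum(eq) + scheme$mismatch * sum(!eq)
        qi <- qi + n; ri <- ri + n
      },
      I = { score <- score - (scheme$gap_open + scheme$gap_extend * n); qi <- qi + n },
      D = { score <- score - (scheme$gap_open + scheme$gap_extend * n); ri <- ri + n },
      stop("unsupported CIGAR op: ", pc$op[j])
    )
  }
  score
}
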