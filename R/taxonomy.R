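# NCBI taxonomy: dump parsing, lineage walks, rank aggregation.
# Dump dialect: fields separated by "\t|\t", records terminated by "\t|".
# merged.dmp / delnodes.dmp are intentionally not consulted: the
# nodes/names pair is the single source of truth.

split_dmp <- function(lines, min_fields, what) {
  lines <- sub("\t\\|$", "", lines)
  fields <- strsplit(lines, "\t|\t", fixed = TRUE)
  bad <- which(lengths(fields) < min_fields)
  if (length(bad)) {
    stop(sprintf("malformed %s record at line %d: expected >= %d fields, got %d",
                 what, bad[1], min_fields, lengths(fields)[bad[1]]))
  }
  fields
}

#' Load an NCBI taxonomy from dump files
#'
#' Parses `nodes.dmp` (taxid, parent taxid, rank) and `names.dmp`,
#' keeping only `scientific name` rows. The root is detected as the
#' node that is its own parent.
#'
#' @param nodes_path path to `nodes.dmp`.
#' @param names_path path to `names.dmp`.
#' @return an object of class `taxonomy_db`: a list with named character
#'   vectors `parent`, `rank`, `name` (names are taxids) and the `root`
#'   taxid.
#' @export
load_taxonomy <- function(nodes_path, names_path) {
  nf <- split_dmp(readLines(nodes_path), 3L, "nodes.dmp")
  taxid <- vapply(nf, `[[`, "", 1L)
  parent <- vapply(nf, `[[`, "", 2L)
  rank <- vapply(nf, `[[`, "", 3L)
  if (anyDuplicated(taxid)) stop("duplicate taxid in nodes.dmp: ", taxid[duplicated(taxid)][1])

  mf <- split_dmp(readLines(names_path), 4L, "names.dmp")
  cls <- vapply(mf, `[[`, "", 4L)
  sci <- mf[cls == "scientific name"]
  ntax <- vapply(sci, `[[`, "", 1L)
  nm <- vapply(sci, `[[`, "", 2L)
  unknown <- !(ntax %in% taxid)
  if (any(unknown)) {
    warning(sprintf("%d name record(s) for taxids absent from nodes.dmp dropped (e.g. taxid %s)",
                    sum(unknown), ntax[unknown][1]))
    ntax <- ntax[!unknown]; nm <- nm[!unknown]
  }

  root <- taxid[taxid == parent]
  if (length(root) != 1L) {
    stop(sprintf("expected exactly one root (own-parent) node, found %d", length(root)))
  }
  structure(list(
    parent = setNames(parent, taxid),
    rank = setNames(rank, taxid),
    name = setNames(nm, ntax),
    root = root
  ), class = "taxonomy_db")
}

#' @export
print.taxonomy_db <- function(x, ...) {
  cat(sprintf("taxonomy_db: %d nodes, %d scientific names, root taxid %s\n",
              length(x$parent), length(x$name), x$root))
  invisible(x)
}

#' Taxonomic lineage of a node
#'
#' Walks the parent chain from a node to the root.
#'
#' @param db a [load_taxonomy()] database.
#' @param taxid query taxid (coerced to character).
#' @return data.frame with columns `taxid` and `rank`; the first row is
#'   the query node, the last the root.
#' @export
lineage <- function(db, taxid) {
  taxid <- as.character(taxid)
  if (!taxid %in% names(db$parent)) stop("unknown taxid: ", taxid)
  chain <- character(0)
  ranks <- character(0)
  cur <- taxid
  repeat {
    chain <- c(chain, cur)
    ranks <- c(ranks, db$rank[[cur]])
    if (cur == db$root) break
    nxt <- db$parent[[cur]]
    if (is.null(nxt) || !nxt %in% names(db$parent)) {
      stop(sprintf("broken lineage: taxid %s has parent %s absent from the taxonomy",
                   cur, if (is.null(nxt)) "<none>" else nxt))
    }
    if (length(chain) > length(db$parent)) {
      stop("cycle detected in taxonomy parent chain starting at taxid ", taxid)
    }
    cur <- nxt
  }
  data.frame(taxid = chain, rank = ranks, stringsAsFactors = FALSE)
}

#' Read a reference-to-taxid mapping table
#'
#' Two-column tab-separated file: reference id, taxid. Lines starting
#' with `#` are ignored.
#'
#' @param path TSV file.
#' @return named character vector mapping reference id to taxid.
#' @export
read_ref_tax_map <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    colClasses = "character", col.names = c("reference_id", "taxid"))
  if (anyDuplicated(tab$reference_id)) stop("duplicate reference id in taxid map")
  setNames(tab$taxid, tab$reference_id)
}

# first ancestor (including self) with the requested rank, or NA
rank_ancestor <- function(db, taxid, rank, cache) {
  key <- taxid
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  lin <- lineage(db, taxid)
  i <- match(rank, lin$rank)
  out <- if (is.na(i)) NA_character_ else lin$taxid[i]
  assign(key, out, envir = cache)
  out
}

#' Aggregate strain-level estimates to a taxonomic rank
#'
#' Each reference's count is assigned to the first ancestor (including
#' the reference's own taxid) whose rank equals `rank`. Mass is never
#' dropped: references whose lineage lacks the requested rank are
#' reported under a reserved `no-rank-at-level` row, and references
#' absent from the taxid map under `unmapped-taxonomy`.
#'
#' @param est named numeric vector of estimated counts (names are
#'   reference ids), or a [cedar()] fit.
#' @param map named character vector mapping reference id to taxid
#'   (see [read_ref_tax_map()]).
#' @param db a [load_taxonomy()] database.
#' @param rank requested rank name, or `"strain"` for no aggregation
#'   beyond each reference's own taxid.
#' @return data.frame with columns `taxid`, `name`, `rank`,
#'   `estimated_reads`, `relative_abundance`; reserved rows carry `NA`
#'   taxids and the reserved label as `name`. Total `estimated_reads`
#'   equals `sum(est)` exactly.
#' @export
aggregate_to_rank <- function(est, map, db, rank) {
  if (inherits(est, "cedar_fit")) est <- est$est_reads
  if (length(est) == 0L) stop("empty estimate vector")
  ids <- names(est)
  if (is.null(ids)) stop("estimates must be named by reference id")
  tax <- unname(map[ids])
  unmapped <- is.na(tax)

  group <- rep(NA_character_, length(est))
  if (identical(rank, "strain")) {
    group[!unmapped] <- tax[!unmapped]
  } else {
    cache <- new.env(parent = emptyenv())
    for (j in which(!unmapped)) {
      if (!tax[j] %in% names(db$parent)) {
        stop(sprintf("reference %s: unknown taxid %s", ids[j], tax[j]))
      }
      group[j] <- tryCatch(rank_ancestor(db, tax[j], rank, cache), error = function(e) {
        stop(sprintf("reference %s: %s", ids[j], conditionMessage(e)))
      })
    }
  }

  norank <- !unmapped & is.na(group)
  keep <- !unmapped & !norank
  agg <- if (any(keep)) {
    tapply(est[keep], group[keep], sum)
  } else {
    setNames(numeric(0), character(0))
  }
  out <- data.frame(
    taxid = names(agg),
    name = unname(ifelse(names(agg) %in% names(db$name), db$name[names(agg)], NA_character_)),
    rank = rep(if (identical(rank, "strain")) "strain" else rank, length(agg)),
    estimated_reads = as.numeric(agg),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$estimated_reads, out$taxid), , drop = FALSE]
  if (any(norank)) {
    out <- rbind(out, data.frame(taxid = NA_character_, name = "no-rank-at-level",
                                 rank = rank, estimated_reads = sum(est[norank])))
  }
  if (any(unmapped)) {
    out <- rbind(out, data.frame(taxid = NA_character_, name = "unmapped-taxonomy",
                                 rank = rank, estimated_reads = sum(est[unmapped])))
  }
  total <- sum(out$estimated_reads)
  out$relative_abundance <- if (total > 0) out$estimated_reads / total else 0
  rownames(out) <- NULL
  out
}

#' Write a rank table as TSV
#'
#' Columns: `taxid`, `scientific_name`, `rank`, `estimated_reads`,
#' `relative_abundance` (fraction of total in `[0, 1]`).
#'
#' @param tab a table from [aggregate_to_rank()].
#' @param path output file.
#' @param header optional comment lines (without leading `#`).
#' @export
write_rank_table <- function(tab, path, header = character(0)) {
  out <- data.frame(
    taxid = tab$taxid,
    scientific_name = tab$name,
    rank = tab$rank,
    estimated_reads = tab$estimated_reads,
    relative_abundance = tab$relative_abundance,
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
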