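# Pathway enrichment: GMT gene sets, one-sided hypergeometric tests,
# Benjamini-Hochberg FDR.

#' Load a GMT gene-set file
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' `id`, `description`, `member1`, `member2`, ... Duplicate members within
#' a pathway are deduplicated; duplicate pathway ids are an error.
#'
#' @param path GMT file path.
#' @return A pathway database: list with `pathways` (named list of member
#'   character vectors), `names` (named character: id -> description) and
#'   `hierarchy` (NULL until [load_hierarchy()] is applied).
#' @export
load_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3
  if (any(short)) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(which(short), collapse = ", "))
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  pathways <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(pathways) <- ids
  descs <- stats::setNames(vapply(fields, `[[`, character(1), 2), ids)
  structure(list(pathways = pathways, names = descs, hierarchy = NULL),
            class = "pathway_db")
}

#' Attach a pathway hierarchy to a database
#'
#' @param db Pathway database from [load_gmt()].
#' @param path Two-column TSV (`parent_id`, `child_id`), with header.
#' @return The database with `hierarchy` set (data.frame parent/child).
#' @export
load_hierarchy <- function(db, path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("parent", "child")
  unknown <- setdiff(unique(c(tab$parent, tab$child)), names(db$pathways))
  if (length(unknown)) {
    stop("hierarchy references unknown pathway id(s): ",
         paste(unknown, collapse = ", "))
  }
  db$hierarchy <- tab[, c("parent", "child")]
  db
}

#' Benjamini-Hochberg step-up q-values
#'
#' Re-implemented (rather than delegated) so it is independently testable:
#' after sorting, `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  q_sorted <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

#' Hypergeometric pathway enrichment
#'
#' For each pathway, a one-sided hypergeometric test of the overlap
#' between the query and the pathway members (both restricted to the
#' universe): p = P(overlap >= observed). q-values are Benjamini-Hochberg
#' over all tested pathways; pathways with fewer than `min_size` members
#' in the universe are skipped.
#'
#' @param query Character vector of query proteins. Members outside the
#'   universe are dropped with a warning.
#' @param db Pathway database.
#' @param universe Character vector: the statistical background.
#' @param fdr Significance threshold on the q-value (default 0.01).
#' @param min_size Minimum pathway size within the universe (default 3).
#' @return A data.frame sorted by (q, p): `pathway`, `name`, `n_members`,
#'   `n_hits`, `p_value`, `q_value`, `significant`, plus a list-column
#'   `hits`. Attribute `"skipped"` holds ids of too-small pathways.
#' @export
enrich <- function(query, db, universe, fdr = 0.01, min_size = 3) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(query) == 0L || length(universe) == 0L) {
    stop("query and universe must be non-empty")
  }
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query protein(s) outside the universe dropped")
    query <- intersect(query, universe)
    if (length(query) == 0L) stop("no query protein in the universe")
  }
  members <- lapply(db$pathways, intersect, universe)
  sizes <- lengths(members)
  skipped <- names(members)[sizes < min_size]
  keep <- sizes >= min_size
  members <- members[keep]
  if (length(members) == 0L) stop("no pathway meets the minimum size")
  Nu <- length(universe)
  nq <- length(query)
  hits <- lapply(members, intersect, query)
  n_hits <- lengths(hits)
  n_mem <- lengths(members)
  p <- stats::phyper(n_hits - 1, m = n_mem, n = Nu - n_mem, k = nq,
                     lower.tail = FALSE)
  q <- bh_fdr(p)
  res <- data.frame(pathway = names(members),
                    name = unname(db$names[names(members)]),
                    n_members = n_mem, n_hits = n_hits,
                    p_value = unname(p), q_value = unname(q),
                    significant = unname(q <= fdr),
                    stringsAsFactors = FALSE)
  res$hits <- unname(hits)
  res <- res[order(res$q_value, res$p_value, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Write an enrichment result TSV
#'
#' @param result Output of [enrich()].
#' @param path Output path. The `hits` list-column is flattened with ";".
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
  flat <- result
  flat$hits <- vapply(result$hits, paste, character(1), collapse = ";")
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a pathway database as GMT
#'
#' @param db Pathway database.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db$pathways), function(id) {
    paste(c(id, db$names[[id]], db$pathways[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
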