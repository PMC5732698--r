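# Iterative disease-module expansion: at each step add the candidate node
# whose connectivity to the current seed set is most significant under a
# hypergeometric model (the DIAMOnD algorithm).

#' Hypergeometric connectivity p-value
#'
#' For a node of degree `k` with `ks` links into the current seed set of
#' size `s` on a network of `N` nodes, the p-value is the upper tail
#' `sum_{i = ks..k} Hyp(i | N, s, k)`: the probability that a random
#' degree-`k` node would hit the seed set at least `ks` times.
#'
#' @param k Node degree(s).
#' @param ks Links to the seed set; `0 <= ks <= min(k, s)`.
#' @param N Network size (node count).
#' @param s Current seed-set size.
#' @return p-value(s) in (0, 1]; monotone non-increasing in `ks`.
#' @export
connectivity_pvalue <- function(k, ks, N, s) {
  if (any(ks < 0) || any(ks > pmin(k, s)) || any(s > N) || any(k > N)) {
    stop("require 0 <= ks <= min(k, s) <= N")
  }
  stats::phyper(ks - 1, m = s, n = N - s, k = k, lower.tail = FALSE)
}

diamond_pvalue <- function(k, ks, N, s, alpha = 1) {
  if (alpha > 1) {
    # seed links count alpha times: inflate seed-side quantities
    k <- k + (alpha - 1) * ks
    ks <- alpha * ks
    s_eff <- alpha * s
    N <- N + (alpha - 1) * s
    s <- s_eff
  }
  connectivity_pvalue(k, ks, N, s)
}

#' Expand a seed set with the most connectivity-significant nodes
#'
#' At each of `n_iter` iterations every candidate node with at least one
#' link to the current (seed + added) set is scored with
#' [connectivity_pvalue()]; the node with the smallest p-value joins the
#' set. Ties are broken deterministically: larger `ks`, then larger `k`,
#' then lexicographically smallest node id. Node degrees are those of the
#' input network and do not change during expansion. p-values are recorded
#' at the iteration of addition and are not multiplicity-corrected (only
#' the ranking matters).
#'
#' @param graph igraph network.
#' @param seeds Non-empty character vector of seed nodes present on
#'   `graph`.
#' @param n_iter Number of nodes to add (default 200); fewer are added if
#'   the reachable graph is exhausted.
#' @param alpha Integer seed weight (default 1 = unweighted); when > 1,
#'   links to original seeds count `alpha` times.
#' @return A list with `added` (data.frame: `rank`, `node`, `degree`,
#'   `ks`, `p_value`) and `final_set` (seeds then added nodes, in order).
#' @export
diamond_expand <- function(graph, seeds, n_iter = 200, alpha = 1) {
  seeds <- unique(seeds)
  nodes <- igraph::V(graph)$name
  if (length(seeds) == 0L) stop("cannot expand empty module")
  if (!all(seeds %in% nodes)) {
    stop("seed(s) not on network: ",
         paste(setdiff(seeds, nodes), collapse = ", "))
  }
  if (n_iter < 1) stop("n_iter must be >= 1")
  N <- length(nodes)
  deg <- igraph::degree(graph)
  names(deg) <- nodes
  adj <- igraph::as_adj_list(graph, mode = "all")
  names(adj) <- nodes
  adj <- lapply(adj, function(v) nodes[as.integer(v)])

  in_set <- stats::setNames(rep(FALSE, N), nodes)
  in_set[seeds] <- TRUE
  # ks: current links into the set, for every node (only candidates used)
  ks <- stats::setNames(integer(N), nodes)
  for (sd in seeds) {
    nb <- adj[[sd]]
    ks[nb] <- ks[nb] + 1L
  }
  added <- character(0)
  rows <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    cand <- nodes[!in_set & ks > 0L]
    if (length(cand) == 0L) break
    s <- sum(in_set)
    p <- diamond_pvalue(deg[cand], ks[cand], N, s, alpha = alpha)
    # tie rule: smallest p, then largest ks, then largest k, then name
    ord <- order(p, -ks[cand], -deg[cand], cand)
    best <- cand[ord[1]]
    rows[[it]] <- data.frame(rank = it, node = best,
                             degree = unname(deg[best]),
                             ks = unname(ks[best]),
                             p_value = unname(p[ord[1]]),
                             stringsAsFactors = FALSE)
    in_set[best] <- TRUE
    nb <- adj[[best]]
    ks[nb] <- ks[nb] + 1L
    added <- c(added, best)
  }
  added_df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(added_df)) {
    added_df <- data.frame(rank = integer(), node = character(),
                           degree = integer(), ks = integer(),
                           p_value = numeric(), stringsAsFactors = FALSE)
  }
  list(added = added_df, final_set = c(seeds, added))
}

#' Write a module-expansion result
#'
#' Emits the ranked additions as TSV and the final set as a one-column
#' list file.
#'
#' @param expansion Result of [diamond_expand()].
#' @param added_path,final_path Output paths.
#' @return `added_path`, invisibly.
#' @export
write_expansion <- function(expansion, added_path, final_path) {
  utils::write.table(expansion$added, added_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(expansion$final_set, final_path)
  invisible(added_path)
}
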