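# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: explicit choose() sums, quadratic-time loops,
# full rescans.

# exact hypergeometric upper tail via binomial coefficients
oracle_hyper_tail <- function(k, ks, N, s) {
  i <- ks:min(k, s)
  sum(choose(s, i) * choose(N - s, k - i)) / choose(N, k)
}

# brute-force module expansion: rescans every node each round
oracle_diamond <- function(graph, seeds, n_iter) {
  nodes <- igraph::V(graph)$name
  N <- length(nodes)
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"),
                function(v) nodes[as.integer(v)])
  names(adj) <- nodes
  deg <- vapply(adj, length, integer(1))
  current <- seeds
  added <- character(0)
  for (it in seq_len(n_iter)) {
    cand <- setdiff(nodes, current)
    ks <- vapply(cand, function(v) length(intersect(adj[[v]], current)),
                 integer(1))
    cand <- cand[ks > 0]
    ks <- ks[ks > 0]
    if (length(cand) == 0) break
    p <- vapply(seq_along(cand), function(i) {
      oracle_hyper_tail(deg[[cand[i]]], ks[[i]], N, length(current))
    }, numeric(1))
    ord <- order(p, -ks, -deg[cand], cand)
    best <- cand[ord[1]]
    current <- c(current, best)
    added <- c(added, best)
  }
  added
}

# quadratic-time Benjamini-Hochberg reference
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    q_sorted[i] <- min(best, 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# compact builder for phosphopeptide record tables
make_records <- function(site_key, replicate, WT = NA, WT_FGF = NA,
                         FUS = NA, FUS_FGF = NA, id_fdr = 0.005,
                         protein = sub("\\(.*", "", site_key)) {
  df <- data.frame(
    peptide_id = site_key, protein = protein, gene = protein,
    sites = sub(".*\\((.*)\\)", "\\1", site_key),
    replicate = replicate, id_fdr = id_fdr,
    WT = WT, WT_FGF = WT_FGF, FUS = FUS, FUS_FGF = FUS_FGF,
    stringsAsFactors = FALSE
  )
  df$total_intensity <- rowSums(df[c("WT", "WT_FGF", "FUS", "FUS_FGF")],
                                na.rm = TRUE)
  df$site_key <- df$peptide_id
  class(df) <- c("phospho_records", "data.frame")
  df
}

write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}
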