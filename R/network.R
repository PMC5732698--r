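# Signalling-network handling: loading, tissue-expression filtering,
# seed mapping, and effective (seed-neighbourhood) sub-networks.

EXPRESSION_LEVELS <- c("NotDetected", "Low", "Medium", "High")

#' Load an undirected signalling network
#'
#' Accepts a two-column tab-separated edge list (extra columns ignored)
#' or SIF (`source<TAB>relation<TAB>target1 [target2 ...]`). The result is
#' a simple undirected graph: duplicate edges (either orientation) are
#' merged and self-loops dropped (a count is reported via message).
#'
#' @param path File path.
#' @param format `"auto"` (by extension; default), `"tsv"` or `"sif"`.
#' @param header Whether a TSV file carries a header row (default TRUE).
#' @return An igraph object with vertex `name` attributes.
#' @export
load_network <- function(path, format = c("auto", "tsv", "sif"),
                         header = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty network file: ", path)
    edges <- do.call(rbind, lapply(lines, function(ln) {
      f <- strsplit(ln, "\t")[[1]]
      if (length(f) < 3) return(NULL)  # isolated node line; ignored
      cbind(f[1], f[3:length(f)])
    }))
    if (is.null(edges)) stop("no edges in SIF file: ", path)
  } else {
    tab <- utils::read.delim(path, sep = "\t", header = header,
                             stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(tab) == 0L) stop("empty network file: ", path)
    if (ncol(tab) < 2L) stop("edge list needs at least two columns")
    edges <- as.matrix(tab[, 1:2])
  }
  mode(edges) <- "character"
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  n_loop <- sum(igraph::which_loop(g))
  if (n_loop > 0) message("dropped ", n_loop, " self-loop(s)")
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Load a tissue-expression table
#'
#' Long format TSV: columns `protein`, `tissue`, `level` with level in
#' NotDetected < Low < Medium < High.
#'
#' @param path File path.
#' @return A data.frame with `level` as an ordered factor.
#' @export
load_expression <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("protein", "tissue", "level")
  if (!all(need %in% names(tab))) {
    stop("expression table needs columns: ", paste(need, collapse = ", "))
  }
  bad <- !(tab$level %in% EXPRESSION_LEVELS)
  if (any(bad)) {
    stop("unknown expression level(s): ",
         paste(unique(tab$level[bad]), collapse = ", "))
  }
  tab$level <- factor(tab$level, levels = EXPRESSION_LEVELS, ordered = TRUE)
  tab
}

#' Tissue-expression network filter
#'
#' Removes proteins with positive evidence of absence: a node is retained
#' iff it reaches at least `min_level` in at least one of the listed
#' tissues (OR semantics across tissues), or has no entry at all in the
#' expression table (unknown proteins are retained, and tallied in the
#' `"no_data"` attribute of the result). Removed nodes take their incident
#' edges with them.
#'
#' @param graph igraph network.
#' @param expression Expression table from [load_expression()].
#' @param tissues Non-empty character vector of tissue names to consider.
#' @param min_level Minimum ordinal level counted as expressed
#'   (default `"Low"`).
#' @return The induced subgraph on retained nodes; attributes `"removed"`
#'   (character vector) and `"no_data"` (count of retained nodes without
#'   expression data).
#' @export
tissue_filter <- function(graph, expression, tissues, min_level = "Low") {
  if (length(tissues) == 0) stop("tissues must be non-empty")
  known <- unique(expression$tissue)
  unknown <- setdiff(tissues, known)
  if (length(unknown)) {
    stop("tissue(s) not in expression table: ",
         paste(unknown, collapse = ", "),
         "; known tissues: ", paste(known, collapse = ", "))
  }
  min_level <- factor(min_level, levels = EXPRESSION_LEVELS, ordered = TRUE)
  sub <- expression[expression$tissue %in% tissues, , drop = FALSE]
  expressed <- unique(sub$protein[sub$level >= min_level])
  with_data <- unique(sub$protein)
  nodes <- igraph::V(graph)$name
  keep <- nodes %in% expressed | !(nodes %in% with_data)
  out <- igraph::induced_subgraph(graph, which(keep))
  attr(out, "removed") <- nodes[!keep]
  attr(out, "no_data") <- sum(!(nodes[keep] %in% with_data))
  out
}

#' Classify seeds against the unfiltered and filtered networks
#'
#' @param seeds Character vector of seed protein ids.
#' @param full_graph Network before tissue filtering.
#' @param filtered_graph Network after tissue filtering (derived from
#'   `full_graph`).
#' @return A list with disjoint character vectors `mapped` (on the
#'   filtered network), `unmapped_filtered` (present before filtering
#'   only), `unmapped_absent` (never in the network); their union is the
#'   seed set.
#' @export
map_seeds <- function(seeds, full_graph, filtered_graph) {
  seeds <- unique(seeds)
  in_full <- seeds %in% igraph::V(full_graph)$name
  in_filt <- seeds %in% igraph::V(filtered_graph)$name
  list(mapped = sort(seeds[in_filt]),
       unmapped_filtered = sort(seeds[in_full & !in_filt]),
       unmapped_absent = sort(seeds[!in_full]))
}

#' Effective network around a seed set
#'
#' Default (`method = "neighbours"`): the induced subgraph on the seeds
#' and their first network neighbours. The alternative
#' (`method = "diffusion"`) is a random-walk-with-restart expansion:
#' personalised PageRank from the seeds with restart probability
#' `restart`; nodes whose steady-state mass is at least `mass_threshold`
#' are kept (seeds always are). The variant used is recorded in the
#' `"expansion"` attribute.
#'
#' @param graph Filtered signalling network.
#' @param seeds Seed proteins; must be present on `graph`.
#' @param method `"neighbours"` (default) or `"diffusion"`.
#' @param restart Restart probability for the diffusion variant
#'   (default 0.5).
#' @param mass_threshold Minimum steady-state mass for the diffusion
#'   variant (default `1 / vcount(graph)`).
#' @return Induced igraph subgraph.
#' @export
effective_network <- function(graph, seeds,
                              method = c("neighbours", "diffusion"),
                              restart = 0.5, mass_threshold = NULL) {
  method <- match.arg(method)
  nodes <- igraph::V(graph)$name
  seeds <- intersect(unique(seeds), nodes)
  if (length(seeds) == 0L) stop("no seed is present on the network")
  if (method == "neighbours") {
    nb <- unique(unlist(igraph::adjacent_vertices(
      graph, v = seeds)))
    keep <- union(match(seeds, nodes), nb)
  } else {
    if (is.null(mass_threshold)) mass_threshold <- 1 / igraph::vcount(graph)
    pers <- as.numeric(nodes %in% seeds)
    pr <- igraph::page_rank(graph, personalized = pers,
                            damping = 1 - restart)$vector
    keep <- which(pr >= mass_threshold | nodes %in% seeds)
  }
  out <- igraph::induced_subgraph(graph, sort(unique(keep)))
  attr(out, "expansion") <- method
  attr(out, "seeds") <- seeds
  out
}

#' Write a network as a two-column TSV edge list
#'
#' @param graph igraph network.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  utils::write.table(data.frame(from = el[, 1], to = el[, 2]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
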