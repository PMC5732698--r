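# Differential pathway classification: condition-unique / shared sets,
# HC validation, the 25%-more-hits rule, and graph exports.

#' Set operations on two significant-pathway lists
#'
#' @param a,b Character vectors of pathway ids significant in condition A
#'   and condition B.
#' @return List with `unique_a` (= A - B), `unique_b` (= B - A) and
#'   `shared` (= A intersect B), each sorted.
#' @export
set_ops <- function(a, b) {
  a <- unique(a); b <- unique(b)
  list(unique_a = sort(setdiff(a, b)),
       unique_b = sort(setdiff(b, a)),
       shared = sort(intersect(a, b)))
}

#' Validate pathways against the high-confidence protein set
#'
#' A pathway is retained only when at least one of the protein hits that
#' identified it belongs to the HC dataset.
#'
#' @param hits Named list: pathway id -> character vector of protein hits.
#' @param hc_proteins Character vector of HC proteins.
#' @return Character vector of retained pathway ids.
#' @export
hc_filter <- function(hits, hc_proteins) {
  keep <- vapply(hits, function(h) length(intersect(h, hc_proteins)) >= 1,
                 logical(1))
  names(hits)[keep]
}

#' Differentially regulated shared pathways (the 25% rule)
#'
#' A shared pathway is flagged toward condition A when
#' `hits_a >= (1 + fraction) * hits_b` (inclusive), and symmetrically for
#' B. With `hits_b = 0` and `hits_a > 0` the pathway is flagged A (limit
#' behaviour), and vice versa.
#'
#' @param shared Character vector of shared pathway ids.
#' @param hits_a,hits_b Named lists (pathway id -> protein hits) or named
#'   integer vectors of hit counts for the two conditions.
#' @param fraction Required relative excess (default 0.25).
#' @return data.frame: `pathway`, `hits_a`, `hits_b`, `direction`
#'   (`"A"`, `"B"` or `"none"`), restricted to `shared`.
#' @export
shared_differential <- function(shared, hits_a, hits_b, fraction = 0.25) {
  if (!is.numeric(fraction) || length(fraction) != 1 || fraction < 0) {
    stop("fraction must be a single non-negative number")
  }
  count_of <- function(h, id) {
    if (is.list(h)) length(h[[id]]) else if (id %in% names(h)) h[[id]] else 0L
  }
  na <- vapply(shared, function(id) as.numeric(count_of(hits_a, id)),
               numeric(1))
  nb <- vapply(shared, function(id) as.numeric(count_of(hits_b, id)),
               numeric(1))
  dir <- rep("none", length(shared))
  dir[na >= (1 + fraction) * nb & na > 0] <- "A"
  dir[nb >= (1 + fraction) * na & nb > 0] <- "B"
  # both tests can only fire together when fraction == 0 and na == nb
  both <- na >= (1 + fraction) * nb & nb >= (1 + fraction) * na &
    na > 0 & nb > 0
  dir[both] <- "none"
  data.frame(pathway = shared, hits_a = as.integer(na),
             hits_b = as.integer(nb), direction = dir,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble the differential pathway report
#'
#' Combines [set_ops()], [hc_filter()] and [shared_differential()] for a
#' pair of enrichment results.
#'
#' @param enr_a,enr_b Enrichment results ([enrich()]) for the two
#'   conditions; only `significant` rows are used.
#' @param hc_proteins HC protein set for validation.
#' @param fraction The 25% rule parameter (default 0.25).
#' @return List of class `differential_report`: `unique_a`, `unique_b`,
#'   `shared`, `hc_validated_unique_a`, `hc_validated_unique_b`,
#'   `shared_differential` (data.frame, flagged rows only), plus
#'   `hits_a` / `hits_b` (named lists of per-pathway protein hits).
#' @export
differential_report <- function(enr_a, enr_b, hc_proteins,
                                fraction = 0.25) {
  sig_a <- enr_a$pathway[enr_a$significant]
  sig_b <- enr_b$pathway[enr_b$significant]
  hits_a <- stats::setNames(enr_a$hits, enr_a$pathway)
  hits_b <- stats::setNames(enr_b$hits, enr_b$pathway)
  ops <- set_ops(sig_a, sig_b)
  sd <- shared_differential(ops$shared, hits_a, hits_b, fraction)
  sd <- sd[sd$direction != "none", , drop = FALSE]
  structure(list(
    unique_a = ops$unique_a,
    unique_b = ops$unique_b,
    shared = ops$shared,
    hc_validated_unique_a = hc_filter(hits_a[ops$unique_a], hc_proteins),
    hc_validated_unique_b = hc_filter(hits_b[ops$unique_b], hc_proteins),
    shared_differential = sd,
    hits_a = hits_a, hits_b = hits_b
  ), class = "differential_report")
}

#' @export
print.differential_report <- function(x, ...) {
  cat("Differential pathway report\n")
  cat("  unique to A:", length(x$unique_a),
      sprintf("(HC-validated: %d)\n", length(x$hc_validated_unique_a)))
  cat("  unique to B:", length(x$unique_b),
      sprintf("(HC-validated: %d)\n", length(x$hc_validated_unique_b)))
  cat("  shared:", length(x$shared), "\n")
  cat("  shared differential:", nrow(x$shared_differential),
      sprintf("(A: %d, B: %d)\n",
              sum(x$shared_differential$direction == "A"),
              sum(x$shared_differential$direction == "B")))
  invisible(x)
}

protein_confidence <- function(proteins, hc_proteins, qp_proteins) {
  ifelse(proteins %in% hc_proteins, "HC",
         ifelse(proteins %in% qp_proteins, "QP", "network-only"))
}

#' Export the pathway-protein graph
#'
#' Builds the bipartite pathway-protein graph of the differential report:
#' pathway nodes carry their class (unique_A / unique_B /
#' shared_differential), protein nodes their identification confidence
#' (HC / QP / network-only) and, when regulation calls are supplied, the
#' per-comparison regulation direction. Pathway-pathway hierarchy edges
#' are added where both endpoints are present. Written as GraphML and a
#' flat TSV edge list.
#'
#' @param report A `differential_report`.
#' @param db Pathway database (for hierarchy edges; optional hierarchy).
#' @param hc_proteins,qp_proteins Protein sets defining confidence tiers.
#' @param regulation Optional data.frame with columns `protein`,
#'   `comparison`, `regulation`.
#' @param graphml_path,tsv_path Output paths (either may be NULL to skip).
#' @return The igraph object, invisibly.
#' @export
export_pathway_graph <- function(report, db, hc_proteins = character(),
                                 qp_proteins = character(),
                                 regulation = NULL,
                                 graphml_path = NULL, tsv_path = NULL) {
  classes <- c(stats::setNames(rep("unique_A", length(report$unique_a)),
                               report$unique_a),
               stats::setNames(rep("unique_B", length(report$unique_b)),
                               report$unique_b),
               stats::setNames(rep("shared_differential",
                                   nrow(report$shared_differential)),
                               report$shared_differential$pathway))
  pw_ids <- names(classes)
  edges <- list()
  for (id in pw_ids) {
    h <- unique(c(report$hits_a[[id]], report$hits_b[[id]]))
    if (length(h)) edges[[id]] <- data.frame(from = id, to = h,
                                             type = "hit",
                                             stringsAsFactors = FALSE)
  }
  el <- do.call(rbind, edges)
  if (is.null(el)) el <- data.frame(from = character(), to = character(),
                                    type = character())
  if (!is.null(db$hierarchy) && nrow(db$hierarchy)) {
    hh <- db$hierarchy
    unknown <- !(hh$parent %in% names(db$pathways)) |
      !(hh$child %in% names(db$pathways))
    if (any(unknown)) {
      warning("skipping ", sum(unknown),
              " hierarchy edge(s) with unknown pathway id")
      hh <- hh[!unknown, , drop = FALSE]
    }
    hh <- hh[hh$parent %in% pw_ids & hh$child %in% pw_ids, , drop = FALSE]
    if (nrow(hh)) {
      el <- rbind(el, data.frame(from = hh$parent, to = hh$child,
                                 type = "hierarchy",
                                 stringsAsFactors = FALSE))
    }
  }
  prot_ids <- setdiff(unique(el$to[el$type == "hit"]), pw_ids)
  g <- igraph::graph_from_data_frame(
    el, directed = FALSE,
    vertices = data.frame(name = c(pw_ids, prot_ids),
                          kind = c(rep("pathway", length(pw_ids)),
                                   rep("protein", length(prot_ids))),
                          stringsAsFactors = FALSE))
  igraph::V(g)$class <- NA_character_
  igraph::V(g)$class[match(pw_ids, igraph::V(g)$name)] <- unname(classes)
  conf <- protein_confidence(prot_ids, hc_proteins, qp_proteins)
  igraph::V(g)$confidence <- NA_character_
  igraph::V(g)$confidence[match(prot_ids, igraph::V(g)$name)] <- conf
  if (!is.null(regulation) && nrow(regulation)) {
    lab <- tapply(paste0(regulation$comparison, ":", regulation$regulation),
                  regulation$protein, paste, collapse = ";")
    idx <- match(names(lab), igraph::V(g)$name)
    igraph::V(g)$regulation <- NA_character_
    igraph::V(g)$regulation[idx[!is.na(idx)]] <- unname(lab)[!is.na(idx)]
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(tsv_path)) {
    utils::write.table(el, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(g)
}

#' Local phospho-signalling context of a protein set
#'
#' The induced subgraph of the effective network on the given proteins,
#' their retained predicted kinases, and the first neighbours of the
#' proteins. Kinase-substrate edges present in the predictions are
#' annotated, nodes carry their role (substrate / kinase / both) and, when
#' available, a summary of regulated-site calls.
#'
#' @param proteins Character vector; at least one must be on the network.
#' @param graph Effective network (igraph).
#' @param predictions Retained kinase predictions ([retain_kinases()]);
#'   only rows with `retained == TRUE` are used.
#' @param regulation Optional data.frame `site_key`, `protein`,
#'   `regulation`.
#' @return Annotated igraph subgraph.
#' @export
local_phospho_context <- function(proteins, graph, predictions,
                                  regulation = NULL) {
  nodes <- igraph::V(graph)$name
  core <- intersect(unique(proteins), nodes)
  if (length(core) == 0L) stop("none of the proteins is on the network")
  pred <- predictions[predictions$retained &
                        predictions$protein %in% core, , drop = FALSE]
  kin <- intersect(unique(pred$kinase), nodes)
  nb <- nodes[unique(unlist(igraph::adjacent_vertices(graph, v = core)))]
  keep <- union(core, union(kin, nb))
  sg <- igraph::induced_subgraph(graph, match(keep, nodes))
  vn <- igraph::V(sg)$name
  role <- ifelse(vn %in% core & vn %in% kin, "both",
                 ifelse(vn %in% kin, "kinase",
                        ifelse(vn %in% core, "substrate", "neighbour")))
  igraph::V(sg)$role <- role
  # annotate predicted kinase->substrate edges that exist in the subgraph
  igraph::E(sg)$predicted <- FALSE
  if (nrow(pred)) {
    pairs <- unique(pred[, c("kinase", "protein")])
    for (i in seq_len(nrow(pairs))) {
      if (all(c(pairs$kinase[i], pairs$protein[i]) %in% vn)) {
        eid <- igraph::get_edge_ids(sg, c(pairs$kinase[i], pairs$protein[i]))
        if (eid > 0) igraph::E(sg)$predicted[eid] <- TRUE
      }
    }
  }
  if (!is.null(regulation) && nrow(regulation)) {
    lab <- tapply(regulation$regulation, regulation$protein,
                  function(x) paste(sort(unique(x)), collapse = ";"))
    idx <- match(names(lab), vn)
    igraph::V(sg)$regulation <- NA_character_
    igraph::V(sg)$regulation[idx[!is.na(idx)]] <- unname(lab)[!is.na(idx)]
  }
  sg
}
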