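# Deterministic synthetic-data generators emulating the statistical
# structure of the pipeline's inputs: four-channel isobaric quant tables
# with log-normal reporter noise and planted regulated sites, scale-free
# networks with a planted dense module, pathway sets overlapping the
# module, tissue-expression tables, and kinase motif models.

#' Synthetic-world specification
#'
#' One object stating every generator parameter. Defaults describe the
#' world the pipeline is validated against: three replicates with 10%
#' multiplicative reporter CV, planted log2 effects of 1.0, a 2,000-node
#' scale-free network carrying a 60-node dense module (within-module edge
#' probability 0.25 over a 0.01-density background option), 100 pathways,
#' and a two-tissue (normal/tumour) expression table.
#'
#' @param seed Integer master seed; all generators derive from it.
#' @param n_sites Number of phosphosites (composite site keys).
#' @param n_proteins Number of distinct proteins carrying the sites.
#' @param n_regulated Planted regulated sites per comparison.
#' @param effect_log2 Planted absolute log2 effect size.
#' @param replicate_cv Multiplicative coefficient of variation of a
#'   reporter channel across replicates (natural scale).
#' @param n_replicates Replicates per site.
#' @param channel_dropout Probability a single reporter value is missing.
#' @param intensity_dependent_variance If TRUE, low-abundance sites get
#'   up to 3x the stated CV (exercises intensity-binned significance).
#' @param network List: `n` nodes, `pa_m` edges per preferential-
#'   attachment step, `module_size`, `p_within`, `p_background`,
#'   `background` ("pa" or "er").
#' @param n_pathways,pathway_size Pathway count and size range.
#' @param frac_enriched_pathways Fraction of pathways enriched for
#'   planted-module members.
#' @param module_member_frac Fraction of an enriched pathway's members
#'   drawn from the module.
#' @param expression_dropout Fraction of proteins absent from the
#'   expression table.
#' @param notdetected_frac Fraction of table entries NotDetected in all
#'   tissues (the filter's victims).
#' @param n_kinases Number of kinase motif models.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_sites = 1500L, n_proteins = 800L,
                           n_regulated = 60L, effect_log2 = 1.0,
                           replicate_cv = 0.1, n_replicates = 3L,
                           channel_dropout = 0.05,
                           intensity_dependent_variance = FALSE,
                           network = list(n = 2000L, pa_m = 3L,
                                          module_size = 60L,
                                          p_within = 0.25,
                                          p_background = 0.01,
                                          background = "pa"),
                           n_pathways = 100L,
                           pathway_size = c(10L, 60L),
                           frac_enriched_pathways = 0.3,
                           module_member_frac = 0.5,
                           expression_dropout = 0.1,
                           notdetected_frac = 0.15,
                           n_kinases = 6L) {
  stopifnot(n_sites > 0, n_proteins > 0, n_regulated >= 0,
            n_replicates >= 1, replicate_cv >= 0,
            channel_dropout >= 0, channel_dropout <= 1,
            expression_dropout >= 0, expression_dropout <= 1,
            notdetected_frac >= 0, notdetected_frac <= 1)
  if (3L * n_regulated > n_sites) {
    stop("n_regulated exceeds available sites across the three comparisons")
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

# distinct sub-seeds per generator so outputs do not couple
sub_seed <- function(spec, offset) (spec$seed * 97L + offset) %% .Machine$integer.max

#' Generate a four-channel phosphopeptide quantitation table
#'
#' Log-normal base abundance per site, independent multiplicative
#' log-normal noise per channel and replicate with the stated CV, planted
#' log2 effects applied to the numerator channel of each comparison (FUS
#' for C1, FUS-FGF for C2, WT-FGF for C3), random channel dropout, and an
#' identification-FDR tier drawn per peptide so both the HC and QP
#' filters bite.
#'
#' @param spec A [synthetic_spec()].
#' @return List: `records` (a `phospho_records` data.frame, one row per
#'   site per replicate) and `truth` (data.frame `site_key`, `protein`,
#'   `comparison`, `direction`, `effect_log2`).
#' @export
gen_quant_table <- function(spec) {
  set.seed(sub_seed(spec, 1L))
  n <- spec$n_sites
  proteins <- paste0("P", seq_len(spec$n_proteins))
  prot_of <- proteins[((seq_len(n) - 1L) %% spec$n_proteins) + 1L]
  residues <- sample(c("S", "T", "Y"), n, replace = TRUE,
                     prob = c(0.75, 0.2, 0.05))
  positions <- sample(20:900, n, replace = TRUE)
  sites <- paste0(residues, positions)
  site_key <- paste0(prot_of, "(", sites, ")")

  # plant disjoint regulated site groups per comparison
  idx <- sample(n, 3L * spec$n_regulated)
  planted <- split(idx, rep(c("C1", "C2", "C3"), each = spec$n_regulated))
  truth <- do.call(rbind, lapply(names(planted), function(cmp) {
    ii <- planted[[cmp]]
    dir <- rep(c("up", "down"), length.out = length(ii))
    data.frame(site_key = site_key[ii], protein = prot_of[ii],
               comparison = cmp, direction = dir,
               effect_log2 = ifelse(dir == "up", spec$effect_log2,
                                    -spec$effect_log2),
               stringsAsFactors = FALSE)
  }))

  base <- stats::rlnorm(n, meanlog = log(1e6), sdlog = 1)
  cv <- rep(spec$replicate_cv, n)
  if (spec$intensity_dependent_variance) {
    r <- rank(base) / n
    cv <- spec$replicate_cv * (1 + 2 * (1 - r))  # up to 3x for low abundance
  }
  effect_on <- matrix(0, nrow = n, ncol = 4,
                      dimnames = list(NULL, CONDITIONS))
  numerator_of <- c(C1 = "FUS", C2 = "FUS_FGF", C3 = "WT_FGF")
  for (cmp in names(planted)) {
    ii <- planted[[cmp]]
    eff <- truth$effect_log2[truth$comparison == cmp]
    effect_on[ii, numerator_of[[cmp]]] <- eff
  }
  id_fdr <- sample(c(0.005, 0.03, 0.08), n, replace = TRUE,
                   prob = c(0.7, 0.2, 0.1))

  recs <- vector("list", spec$n_replicates)
  for (r in seq_len(spec$n_replicates)) {
    m <- matrix(stats::rlnorm(n * 4, meanlog = 0, sdlog = cv), nrow = n)
    m <- m * base * 2^effect_on
    drop <- matrix(stats::runif(n * 4) < spec$channel_dropout, nrow = n)
    m[drop] <- NA_real_
    df <- data.frame(peptide_id = paste0("pep", seq_len(n)),
                     protein = prot_of, gene = prot_of, sites = sites,
                     replicate = r, id_fdr = id_fdr,
                     stringsAsFactors = FALSE)
    colnames(m) <- CONDITIONS
    df <- cbind(df, as.data.frame(m))
    df$total_intensity <- rowSums(m, na.rm = TRUE)
    df$site_key <- site_key
    recs[[r]] <- df
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  class(records) <- c("phospho_records", "data.frame")
  list(records = records, truth = truth)
}

#' Generate a background network with a planted dense module
#'
#' Background: preferential attachment (heavy-tailed degrees; default) or
#' Erdos-Renyi at `p_background`. A `module_size`-node subset is overlaid
#' with internal edges at probability `p_within`; members are drawn at
#' random unless `anchor` nodes are supplied, in which case those are
#' placed in the module first (this is how [simulate_inputs()] couples
#' the regulated proteins to the module, so the planted quantitation
#' signal and the planted network signal agree).
#'
#' @param spec A [synthetic_spec()].
#' @param anchor Optional character vector of node names seeded into the
#'   planted module (truncated to `module_size`).
#' @return List: `graph` (igraph, nodes named `P1..Pn`) and `module`
#'   (character vector of planted-module members).
#' @export
gen_network <- function(spec, anchor = NULL) {
  set.seed(sub_seed(spec, 2L))
  nw <- spec$network
  n <- nw$n
  if (identical(nw$background, "er")) {
    g <- igraph::sample_gnp(n, nw$p_background)
  } else {
    g <- igraph::sample_pa(n, power = 1, m = nw$pa_m, directed = FALSE)
  }
  igraph::V(g)$name <- paste0("P", seq_len(n))
  nodes <- igraph::V(g)$name
  anchored <- utils::head(intersect(anchor, nodes), nw$module_size)
  module <- c(anchored,
              sample(setdiff(nodes, anchored),
                     nw$module_size - length(anchored)))
  pairs <- utils::combn(module, 2)
  pick <- stats::runif(ncol(pairs)) < nw$p_within
  if (any(pick)) {
    g <- igraph::add_edges(g, as.vector(pairs[, pick, drop = FALSE]))
  }
  g <- igraph::simplify(g)
  list(graph = g, module = sort(module))
}

#' Generate a pathway database over a network
#'
#' Pathways are sampled from network nodes; a stated fraction is enriched
#' for planted-module members (a `module_member_frac` share of their
#' members). A shallow random hierarchy links some pathway pairs.
#'
#' @param spec A [synthetic_spec()].
#' @param network Output of [gen_network()].
#' @return A `pathway_db` (as from [load_gmt()]) with `hierarchy` set;
#'   enriched pathway ids in attribute `"enriched"`.
#' @export
gen_pathways <- function(spec, network) {
  set.seed(sub_seed(spec, 3L))
  nodes <- igraph::V(network$graph)$name
  module <- network$module
  np <- spec$n_pathways
  n_enriched <- round(spec$frac_enriched_pathways * np)
  ids <- sprintf("PW%04d", seq_len(np))
  enriched <- ids[seq_len(n_enriched)]
  pathways <- vector("list", np)
  for (i in seq_len(np)) {
    sz <- sample(spec$pathway_size[1]:spec$pathway_size[2], 1)
    if (i <= n_enriched) {
      n_mod <- min(length(module), round(spec$module_member_frac * sz))
      mem <- c(sample(module, n_mod),
               sample(setdiff(nodes, module), sz - n_mod))
    } else {
      mem <- sample(nodes, sz)
    }
    pathways[[i]] <- unique(mem)
  }
  names(pathways) <- ids
  n_h <- max(1L, np %/% 10L)
  parent <- sample(ids, n_h, replace = TRUE)
  child <- sample(ids, n_h, replace = TRUE)
  ok <- parent != child
  hierarchy <- unique(data.frame(parent = parent[ok], child = child[ok],
                                 stringsAsFactors = FALSE))
  db <- structure(list(
    pathways = pathways,
    names = stats::setNames(paste("Synthetic pathway", seq_len(np)), ids),
    hierarchy = hierarchy
  ), class = "pathway_db")
  attr(db, "enriched") <- enriched
  db
}

#' Generate a two-tissue expression table
#'
#' Tissues `"normal"` and `"tumour"`. A stated fraction of network
#' proteins is absent from the table entirely (no-data dropout); of those
#' present, a stated fraction is NotDetected in both tissues (removed by
#' the filter), the rest reach at least Low in one tissue.
#'
#' @param spec A [synthetic_spec()].
#' @param network Output of [gen_network()].
#' @return Expression data.frame (`protein`, `tissue`, `level`).
#' @export
gen_expression <- function(spec, network) {
  set.seed(sub_seed(spec, 4L))
  nodes <- igraph::V(network$graph)$name
  present <- nodes[stats::runif(length(nodes)) >= spec$expression_dropout]
  nd <- stats::runif(length(present)) < spec$notdetected_frac
  rows <- lapply(seq_along(present), function(i) {
    if (nd[i]) {
      lev <- c("NotDetected", "NotDetected")
    } else {
      lev <- sample(EXPRESSION_LEVELS[-1], 2, replace = TRUE)
      if (stats::runif(1) < 0.2) lev[sample(2, 1)] <- "NotDetected"
    }
    data.frame(protein = present[i], tissue = c("normal", "tumour"),
               level = lev, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate kinase motif models
#'
#' Each kinase gets an 11-position PWM concentrated on a random consensus
#' (consensus residue probability `concentration`, remainder uniform);
#' the central position favours S/T/Y. Background is uniform.
#'
#' @param spec A [synthetic_spec()] (uses `n_kinases` and the seed), or
#'   NULL with `n_kinases`/`seed` given directly.
#' @param n_kinases,seed Overrides.
#' @param concentration Consensus probability mass (default 0.6).
#' @return Named list of motif models (`K1`, `K2`, ...), each with `mat`
#'   and `background`.
#' @export
gen_pwms <- function(spec = NULL, n_kinases = NULL, seed = NULL,
                     concentration = 0.6) {
  if (!is.null(spec)) {
    if (is.null(n_kinases)) n_kinases <- spec$n_kinases
    if (is.null(seed)) seed <- sub_seed(spec, 5L)
  }
  set.seed(seed)
  out <- lapply(seq_len(n_kinases), function(i) {
    mat <- matrix(0, nrow = 11, ncol = 20,
                  dimnames = list(as.character(-5:5), AMINO_ACIDS))
    for (p in 1:11) {
      cons <- if (p == 6) sample(c("S", "T", "Y"), 1) else
        sample(AMINO_ACIDS, 1)
      row <- rep((1 - concentration) / 19, 20)
      names(row) <- AMINO_ACIDS
      row[cons] <- concentration
      mat[p, ] <- row
    }
    list(mat = mat,
         background = stats::setNames(rep(1 / 20, 20), AMINO_ACIDS))
  })
  names(out) <- paste0("K", seq_len(n_kinases))
  out
}

#' Sample a sequence context from a motif model
#'
#' @param model Motif model (`mat`, `background`).
#' @return An 11-character context string drawn position-wise.
#' @export
sample_context <- function(model) {
  paste(vapply(seq_len(nrow(model$mat)), function(p) {
    sample(colnames(model$mat), 1, prob = model$mat[p, ])
  }, character(1)), collapse = "")
}

#' Generate two pathway-id sets with exact sizes and overlap
#'
#' Desk-scale fixture for the set-operation stage: two sets of enriched-
#' pathway ids with the requested cardinalities and intersection, drawn
#' from a universe of synthetic ids.
#'
#' @param universe_size Total pathway universe (default 2050).
#' @param size_a,size_b Set sizes (defaults 322 and 309).
#' @param overlap Intersection size (default 299).
#' @param seed Integer seed.
#' @return List with character vectors `a` and `b`.
#' @export
gen_fixture_enrichment_sets <- function(universe_size = 2050,
                                        size_a = 322, size_b = 309,
                                        overlap = 299, seed = 1L) {
  if (overlap > min(size_a, size_b)) {
    stop("overlap exceeds a set size")
  }
  if (size_a + size_b - overlap > universe_size) {
    stop("requested sets do not fit in the universe")
  }
  set.seed(seed)
  ids <- sprintf("RID%05d", seq_len(universe_size))
  pool <- sample(ids, size_a + size_b - overlap)
  shared <- pool[seq_len(overlap)]
  only_a <- pool[overlap + seq_len(size_a - overlap)]
  only_b <- pool[overlap + size_a - overlap + seq_len(size_b - overlap)]
  list(a = sort(c(shared, only_a)), b = sort(c(shared, only_b)))
}

#' Write a quantitation table TSV
#'
#' @param records `phospho_records` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_tsv <- function(records, path) {
  cols <- c("peptide_id", "protein", "gene", "sites", "replicate",
            CONDITIONS, "id_fdr", "total_intensity")
  utils::write.table(records[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write an expression table TSV
#'
#' @param expression Expression data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expression, path) {
  utils::write.table(expression, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
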