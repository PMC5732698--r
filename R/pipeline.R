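# End-to-end orchestration: one config drives quantitation statistics,
# seeding, network filtering, module expansion, enrichment and the
# differential pathway report, with every intermediate written out.

#' Build a run configuration
#'
#' All statistical parameters carry the protocol defaults: HC
#' identification FDR 1%, QP 5%, log2 regulation threshold 0.5, interval
#' multiplier 1.96, significance-B bin size 300 and level 0.05, proximity
#' decay lambda = 1 with reference distance 2 and ceiling 6, 200 module-
#' expansion iterations with seed weight 1, enrichment FDR 1%, and the
#' 25% shared-differential rule.
#'
#' @param quant,network,gmt,expression Required input paths (quant TSV,
#'   edge list/SIF, GMT, expression TSV).
#' @param hierarchy,contexts,pwm_dir Optional inputs: pathway hierarchy
#'   TSV, site-context TSV (`site_key`, `context`), directory of PWM
#'   files (one per kinase, named `<kinase>.tsv`). Without contexts/PWMs
#'   the kinase-seed stage is skipped and seeds are substrates only.
#' @param outdir Output directory (created).
#' @param comparisons The two comparisons analysed (default C1 and C3).
#' @param tissues Tissues for the expression filter.
#' @param hc_fdr,qp_fdr,log2_threshold,ci_mult,sigb_bin_size,sigb_alpha
#'   Quantitation-stage parameters.
#' @param lambda,d0,d_max Kinase proximity parameters.
#' @param min_level Minimum expression level retained.
#' @param diamond_n_iter,diamond_alpha Module-expansion parameters.
#' @param enrichment_fdr,min_pathway_size Enrichment parameters.
#' @param shared_fraction The 25% rule parameter.
#' @param universe `"network_and_pathways"` (default) or
#'   `"all_network_nodes"`.
#' @param expansion `"neighbours"` or `"diffusion"` effective-network
#'   variant.
#' @param seed Random seed recorded in metadata (the pipeline itself is
#'   deterministic given its inputs).
#' @return A list of class `dragon_config`.
#' @export
dragon_config <- function(quant, network, gmt, expression,
                          hierarchy = NULL, contexts = NULL,
                          pwm_dir = NULL,
                          outdir = tempfile("dragon_run_"),
                          comparisons = c("C1", "C3"),
                          tissues = c("normal", "tumour"),
                          hc_fdr = 0.01, qp_fdr = 0.05,
                          log2_threshold = 0.5, ci_mult = 1.96,
                          sigb_bin_size = 300, sigb_alpha = 0.05,
                          lambda = 1, d0 = 2, d_max = 6,
                          min_level = "Low",
                          diamond_n_iter = 200, diamond_alpha = 1,
                          enrichment_fdr = 0.01, min_pathway_size = 3,
                          shared_fraction = 0.25,
                          universe = c("network_and_pathways",
                                       "all_network_nodes"),
                          expansion = c("neighbours", "diffusion"),
                          seed = 1L) {
  universe <- match.arg(universe)
  expansion <- match.arg(expansion)
  structure(as.list(environment()), class = "dragon_config")
}

#' Validate a run configuration
#'
#' Always returns a report; [run_dragon()] refuses to start when the
#' report contains errors.
#'
#' @param config A `dragon_config`.
#' @return data.frame with columns `level` ("error"/"warning"), `field`,
#'   `message`; zero rows when fully valid.
#' @export
validate_config <- function(config) {
  issues <- list()
  add <- function(level, field, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      level = level, field = field, message = message,
      stringsAsFactors = FALSE)
  }
  for (f in c("quant", "network", "gmt", "expression")) {
    p <- config[[f]]
    if (is.null(p) || !file.exists(p)) {
      add("error", f, paste0("input file missing: ",
                             if (is.null(p)) "(unset)" else p))
    }
  }
  for (f in c("hierarchy", "contexts")) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p)) {
      add("error", f, paste0("optional input set but missing: ", p))
    }
  }
  if (!is.null(config$pwm_dir) && !dir.exists(config$pwm_dir)) {
    add("error", "pwm_dir", paste0("directory missing: ", config$pwm_dir))
  }
  for (f in c("hc_fdr", "qp_fdr", "sigb_alpha", "enrichment_fdr",
              "shared_fraction")) {
    v <- config[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      add("error", f, "must be a probability in [0, 1]")
    }
  }
  for (f in c("log2_threshold", "ci_mult", "lambda", "d0", "d_max")) {
    if (!is.numeric(config[[f]]) || config[[f]] < 0) {
      add("error", f, "must be non-negative")
    }
  }
  for (f in c("sigb_bin_size", "diamond_n_iter", "min_pathway_size")) {
    if (!is.numeric(config[[f]]) || config[[f]] < 1) {
      add("error", f, "must be a positive count")
    }
  }
  if (length(config$comparisons) != 2 ||
      !all(config$comparisons %in% comparison_definitions()$id)) {
    add("error", "comparisons", "must be two of C1, C2, C3")
  }
  if (length(config$tissues) == 0) {
    add("error", "tissues", "must list at least one tissue")
  }
  defaults <- formals(dragon_config)
  for (f in c("hc_fdr", "qp_fdr", "log2_threshold", "ci_mult",
              "diamond_n_iter", "enrichment_fdr", "shared_fraction")) {
    if (!identical(as.numeric(config[[f]]), as.numeric(defaults[[f]]))) {
      add("warning", f, paste0("non-default value: ", config[[f]]))
    }
  }
  if (length(issues) == 0L) {
    return(data.frame(level = character(), field = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
  })
}

read_contexts <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("site_key", "context") %in% names(tab))) {
    stop("contexts file needs columns site_key, context")
  }
  tab
}

load_pwm_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  pwms <- lapply(files, read_pwm)
  names(pwms) <- sub("\\.tsv$", "", basename(files))
  pwms
}

#' Run the full differential-pathway protocol
#'
#' Executes, for each of the two configured comparisons: HC/QP dataset
#' construction, per-site statistics with significance-B, the
#' most-significant-site report, substrate seeding (QP), optional kinase
#' seeding (motif x proximity with the median filter), seed mapping onto
#' the tissue-filtered network, effective-network extraction, module
#' expansion, and pathway enrichment; then the cross-comparison
#' differential pathway report and graph export. Every intermediate is
#' written under `config$outdir`, along with `run_metadata.json`
#' (parameters, input hashes, stage counts).
#'
#' @param config A validated `dragon_config`.
#' @return The output directory, invisibly. The assembled results are
#'   attached as attribute `"results"`.
#' @export
run_dragon <- function(config) {
  report <- validate_config(config)
  if (any(report$level == "error")) {
    stop("invalid config:\n",
         paste(sprintf("  [%s] %s: %s", report$level, report$field,
                       report$message), collapse = "\n"))
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  counts <- list()
  log_stage <- function(name, ...) {
    kv <- c(...)
    counts[[name]] <<- as.list(kv)
    message(sprintf("[%s] %s", name,
                    paste(names(kv), kv, sep = "=", collapse = " ")))
  }

  records <- stage("load_quant", load_quant_table(config$quant))
  hc <- stage("hc_dataset", build_hc_dataset(records, config$hc_fdr))
  qp <- stage("qp_dataset", build_qp_dataset(records, config$qp_fdr))
  log_stage("datasets", records = nrow(records), hc = nrow(hc),
            qp = nrow(qp),
            hc_qp_overlap_pct = round(hc_qp_protein_overlap(hc, qp), 1))
  write_quant_tsv(hc, out("hc_dataset.tsv"))
  write_quant_tsv(qp, out("qp_dataset.tsv"))

  full_net <- stage("load_network", load_network(config$network))
  expression <- stage("load_expression", load_expression(config$expression))
  filtered <- stage("tissue_filter",
                    tissue_filter(full_net, expression, config$tissues,
                                  config$min_level))
  log_stage("network", nodes = igraph::vcount(full_net),
            filtered_nodes = igraph::vcount(filtered),
            removed = length(attr(filtered, "removed")))
  db <- stage("load_pathways", load_gmt(config$gmt))
  if (!is.null(config$hierarchy)) {
    db <- stage("load_hierarchy", load_hierarchy(db, config$hierarchy))
  }
  contexts <- if (!is.null(config$contexts)) {
    stage("load_contexts", read_contexts(config$contexts))
  } else NULL
  pwms <- if (!is.null(config$pwm_dir)) {
    stage("load_pwms", load_pwm_dir(config$pwm_dir))
  } else NULL

  universe <- if (config$universe == "network_and_pathways") {
    intersect(igraph::V(filtered)$name, unique(unlist(db$pathways)))
  } else {
    igraph::V(filtered)$name
  }

  per_cmp <- list()
  for (cmp in config$comparisons) {
    hc_sum <- stage("summarise_hc",
                    summarise_comparison(hc, cmp, config$ci_mult))
    hc_sum <- stage("significance_b",
                    significance_b(hc_sum, config$sigb_bin_size))
    sig_sites <- stage("select_sites",
                       select_significant_sites(hc_sum,
                                                config$log2_threshold,
                                                config$sigb_alpha,
                                                config$sigb_bin_size))
    write_site_report(sig_sites, out(paste0("sites_", cmp, ".tsv")))

    qp_sum <- stage("summarise_qp",
                    summarise_comparison(qp, cmp, config$ci_mult))
    substrates <- stage("substrate_seeds", substrate_seeds(qp_sum))
    kinases <- character(0)
    predictions <- NULL
    if (!is.null(pwms) && !is.null(contexts)) {
      seed_sites <- qp_sum[qp_sum$protein %in% substrates, , drop = FALSE]
      seed_sites <- merge(seed_sites, contexts, by = "site_key")
      predictions <- stage("predict_kinases",
                           predict_kinases(seed_sites, pwms, filtered,
                                           config$lambda, config$d0,
                                           config$d_max))
      predictions <- stage("retain_kinases", retain_kinases(predictions))
      kinases <- attr(predictions, "kinase_seeds")
      utils::write.table(predictions,
                         out(paste0("kinase_predictions_", cmp, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    seed_set <- build_seed_set(substrates, kinases, cmp)
    utils::write.table(seed_set, out(paste0("seeds_", cmp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mapping <- stage("map_seeds",
                     map_seeds(seed_set$protein, full_net, filtered))
    log_stage(paste0("seeds_", cmp),
              substrates = length(substrates), kinases = length(kinases),
              seeds = nrow(seed_set), mapped = length(mapping$mapped),
              filtered = length(mapping$unmapped_filtered),
              absent = length(mapping$unmapped_absent))
    writeLines(c(paste0("# mapped: ", length(mapping$mapped)),
                 mapping$mapped),
               out(paste0("mapped_seeds_", cmp, ".txt")))

    eff <- stage("effective_network",
                 effective_network(filtered, mapping$mapped,
                                   method = config$expansion))
    write_edge_tsv(eff, out(paste0("effective_network_", cmp, ".tsv")))

    expansion <- stage("diamond",
                       diamond_expand(filtered, mapping$mapped,
                                      n_iter = config$diamond_n_iter,
                                      alpha = config$diamond_alpha))
    write_expansion(expansion,
                    out(paste0("diamond_added_", cmp, ".tsv")),
                    out(paste0("diamond_final_", cmp, ".txt")))
    log_stage(paste0("diamond_", cmp),
              added = nrow(expansion$added),
              final = length(expansion$final_set))

    query <- intersect(expansion$final_set, universe)
    enr <- stage("enrichment",
                 enrich(query, db, universe, fdr = config$enrichment_fdr,
                        min_size = config$min_pathway_size))
    write_enrichment(enr, out(paste0("enrichment_", cmp, ".tsv")))
    log_stage(paste0("enrichment_", cmp),
              tested = nrow(enr), significant = sum(enr$significant))
    per_cmp[[cmp]] <- list(sig_sites = sig_sites, qp_summary = qp_sum,
                           seed_set = seed_set, mapping = mapping,
                           effective = eff, expansion = expansion,
                           enrichment = enr, predictions = predictions)
  }

  a <- config$comparisons[1]; b <- config$comparisons[2]
  hc_proteins <- unique(hc$protein)
  diff <- stage("differential",
                differential_report(per_cmp[[a]]$enrichment,
                                    per_cmp[[b]]$enrichment,
                                    hc_proteins, config$shared_fraction))
  log_stage("differential",
            unique_a = length(diff$unique_a),
            unique_b = length(diff$unique_b),
            shared = length(diff$shared),
            hc_validated_a = length(diff$hc_validated_unique_a),
            hc_validated_b = length(diff$hc_validated_unique_b),
            shared_differential = nrow(diff$shared_differential))
  writeLines(jsonlite::toJSON(
    diff[c("unique_a", "unique_b", "shared", "hc_validated_unique_a",
           "hc_validated_unique_b")], pretty = TRUE),
    out("differential_pathways.json"))
  utils::write.table(diff$shared_differential,
                     out("shared_differential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage("export_graph",
        export_pathway_graph(diff, db, hc_proteins,
                             unique(qp$protein),
                             graphml_path = out("pathway_graph.graphml"),
                             tsv_path = out("pathway_graph_edges.tsv")))

  inputs <- Filter(Negate(is.null),
                   config[c("quant", "network", "gmt", "expression",
                            "hierarchy", "contexts")])
  meta <- list(
    parameters = config[setdiff(names(config),
                                c("quant", "network", "gmt", "expression",
                                  "hierarchy", "contexts", "pwm_dir"))],
    input_md5 = lapply(inputs, function(p) unname(tools::md5sum(p))),
    comparisons = config$comparisons,
    counts = counts
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             out("run_metadata.json"))
  res <- structure(config$outdir, results = list(per_comparison = per_cmp,
                                                 differential = diff))
  invisible(res)
}

#' Write a full synthetic input bundle
#'
#' Materialises every file the pipeline consumes from one synthetic
#' specification: quant TSV, network edge TSV, GMT + hierarchy,
#' expression TSV, PWM directory and a site-context TSV (a fraction of
#' contexts drawn from a randomly assigned kinase's motif, the rest
#' background).
#'
#' @param spec A [synthetic_spec()].
#' @param dir Target directory (created).
#' @return Named list of the written paths plus the `truth` table and
#'   planted `module`, invisibly.
#' @export
simulate_inputs <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  q <- gen_quant_table(spec)
  # anchor the planted module on the regulated proteins so the planted
  # quantitation signal propagates through seeding and module expansion
  nw <- gen_network(spec, anchor = unique(q$truth$protein))
  db <- gen_pathways(spec, nw)
  expr <- gen_expression(spec, nw)
  pwms <- gen_pwms(spec)
  paths <- list(
    quant = file.path(dir, "quant.tsv"),
    network = file.path(dir, "network.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    hierarchy = file.path(dir, "hierarchy.tsv"),
    expression = file.path(dir, "expression.tsv"),
    contexts = file.path(dir, "contexts.tsv"),
    pwm_dir = file.path(dir, "pwms"),
    truth = file.path(dir, "truth.tsv"),
    module = file.path(dir, "module.txt")
  )
  write_quant_tsv(q$records, paths$quant)
  write_edge_tsv(nw$graph, paths$network)
  write_gmt(db, paths$gmt)
  utils::write.table(db$hierarchy, paths$hierarchy, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_expression_tsv(expr, paths$expression)
  dir.create(paths$pwm_dir, showWarnings = FALSE)
  for (k in names(pwms)) {
    write_pwm(pwms[[k]], file.path(paths$pwm_dir, paste0(k, ".tsv")))
  }
  set.seed(sub_seed(spec, 6L))
  keys <- unique(q$records$site_key)
  ctx <- vapply(keys, function(kk) {
    if (stats::runif(1) < 0.5) {
      sample_context(pwms[[sample(names(pwms), 1)]])
    } else {
      paste(sample(AMINO_ACIDS, 11, replace = TRUE), collapse = "")
    }
  }, character(1))
  utils::write.table(data.frame(site_key = keys, context = unname(ctx),
                                stringsAsFactors = FALSE),
                     paths$contexts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(q$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(nw$module, paths$module)
  invisible(c(paths, list(truth = q$truth, module = nw$module)))
}
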