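# Seed derivation: substrate seeds from QP summaries, kinase seeds from
# motif x network-proximity likelihood ratios with a median filter.

AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
PAD_SYMBOL <- "_"

#' Substrate seeds for one comparison
#'
#' A protein becomes a substrate seed when at least one of its phosphosites
#' was observed in more than one replicate and its `mu +/- 1.96 sigma`
#' interval strictly excludes 0 on the log2 scale. Note this is the
#' interval criterion alone -- the 0.5 magnitude threshold used for the
#' "most significant" HC report deliberately does not apply here, so the
#' seed pool is broader.
#'
#' @param qp_summary Site summary of the QP dataset for one comparison.
#' @return Character vector of seed protein identifiers (sorted, unique).
#' @export
substrate_seeds <- function(qp_summary) {
  pass <- qp_summary$n_replicates > 1 &
    (qp_summary$ci_low > 0 | qp_summary$ci_high < 0)
  sort(unique(qp_summary$protein[pass]))
}

#' Score a phosphosite sequence context against a kinase motif model
#'
#' The context is an 11-mer centred on the phosphosite (positions -5..+5);
#' termini are padded with `"_"`, which contributes a neutral factor of 1.
#' The likelihood ratio is the product over positions of
#' `P(residue | model) / P(residue | background)`.
#'
#' @param context Character scalar, 11 characters.
#' @param model A motif model as returned by [read_pwm()] or [gen_pwms()]:
#'   a list with `mat` (11 x 20 probability matrix, rows positions -5..+5,
#'   columns amino acids) and `background` (named length-20 vector).
#' @return Positive likelihood ratio.
#' @export
motif_score <- function(context, model) {
  chars <- strsplit(context, "")[[1]]
  if (length(chars) != nrow(model$mat)) {
    stop("context length must be ", nrow(model$mat))
  }
  valid <- chars %in% c(AMINO_ACIDS, PAD_SYMBOL)
  if (!all(valid)) {
    stop("invalid symbol(s) in context: ",
         paste(unique(chars[!valid]), collapse = ", "))
  }
  lr <- 1
  for (i in seq_along(chars)) {
    aa <- chars[i]
    if (aa == PAD_SYMBOL) next
    lr <- lr * model$mat[i, aa] / model$background[[aa]]
  }
  unname(lr)
}

#' Network-proximity likelihood ratio for a kinase/substrate pair
#'
#' A simple exponential-decay form `LR = exp(lambda * (d0 - d))` in the
#' shortest-path distance `d` between kinase and substrate on the
#' signalling network. It is calibrated so LR = 1 at the reference
#' distance `d0` (default 2, a typical kinase-substrate separation);
#' unreachable or unmapped proteins are scored at the ceiling distance
#' `d_max`.
#'
#' @param kinase,substrate Protein identifiers (either may be absent from
#'   the network).
#' @param graph An igraph network.
#' @param lambda Decay rate per edge (default 1).
#' @param d0 Reference distance at which LR = 1 (default 2).
#' @param d_max Effective distance for unreachable/unmapped pairs
#'   (default 6).
#' @return Positive likelihood ratio.
#' @export
proximity_score <- function(kinase, substrate, graph,
                            lambda = 1, d0 = 2, d_max = 6) {
  nodes <- igraph::V(graph)$name
  if (!(kinase %in% nodes) || !(substrate %in% nodes)) {
    return(exp(lambda * (d0 - d_max)))
  }
  d <- igraph::distances(graph, v = kinase, to = substrate)[1, 1]
  if (!is.finite(d)) d <- d_max
  exp(lambda * (d0 - min(d, d_max)))
}

#' Predict candidate kinases for a set of phosphosites
#'
#' For each (site, kinase) pair, the combined likelihood ratio is the
#' product of the motif likelihood ([motif_score()]) and the network
#' proximity likelihood ([proximity_score()]).
#'
#' @param sites A data.frame with columns `site_key`, `protein`, `context`
#'   (the 11-mer sequence context).
#' @param pwms Named list of motif models, one per candidate kinase.
#' @param graph Signalling network (igraph).
#' @param lambda,d0,d_max Passed to [proximity_score()].
#' @return A data.frame with one row per (site, kinase): `site_key`,
#'   `protein`, `kinase`, `motif_lr`, `proximity_lr`, `combined_lr`.
#' @export
predict_kinases <- function(sites, pwms, graph,
                            lambda = 1, d0 = 2, d_max = 6) {
  if (nrow(sites) == 0L || length(pwms) == 0L) {
    return(data.frame(site_key = character(), protein = character(),
                      kinase = character(), motif_lr = numeric(),
                      proximity_lr = numeric(), combined_lr = numeric(),
                      stringsAsFactors = FALSE))
  }
  kinases <- names(pwms)
  # proximity depends only on (kinase, protein); cache per pair
  prox <- matrix(NA_real_, nrow = length(kinases),
                 ncol = length(unique(sites$protein)),
                 dimnames = list(kinases, unique(sites$protein)))
  for (kin in kinases) {
    for (prot in colnames(prox)) {
      prox[kin, prot] <- proximity_score(kin, prot, graph,
                                         lambda = lambda, d0 = d0,
                                         d_max = d_max)
    }
  }
  out <- vector("list", nrow(sites) * length(kinases))
  j <- 0L
  for (i in seq_len(nrow(sites))) {
    for (kin in kinases) {
      m <- motif_score(sites$context[i], pwms[[kin]])
      p <- prox[kin, sites$protein[i]]
      j <- j + 1L
      out[[j]] <- data.frame(site_key = sites$site_key[i],
                             protein = sites$protein[i], kinase = kin,
                             motif_lr = m, proximity_lr = p,
                             combined_lr = m * p,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Retain kinases at or above the median combined likelihood ratio
#'
#' The median is computed globally over all (site, kinase) predictions for
#' the comparison; predictions at the median are kept (ties included), so
#' at least half of all predictions always survive.
#'
#' @param predictions Output of [predict_kinases()].
#' @return The predictions with a logical `retained` column; the retained
#'   kinases (unique, sorted) are in attribute `"kinase_seeds"`.
#' @export
retain_kinases <- function(predictions) {
  if (nrow(predictions) == 0L) {
    warning("no kinase predictions to filter")
    predictions$retained <- logical(0)
    attr(predictions, "kinase_seeds") <- character(0)
    return(predictions)
  }
  med <- stats::median(predictions$combined_lr)
  predictions$retained <- predictions$combined_lr >= med
  attr(predictions, "kinase_seeds") <-
    sort(unique(predictions$kinase[predictions$retained]))
  predictions
}

#' Assemble the seed set for one comparison
#'
#' @param substrates Character vector of substrate-seed proteins.
#' @param kinases Character vector of retained kinase-seed proteins.
#' @param comparison Comparison id recorded in the output.
#' @return A data.frame with columns `protein`, `provenance`
#'   (`"substrate"`, `"kinase"`, or `"both"`), `comparison`.
#' @export
build_seed_set <- function(substrates, kinases, comparison = NA_character_) {
  members <- sort(union(substrates, kinases))
  prov <- ifelse(members %in% substrates & members %in% kinases, "both",
                 ifelse(members %in% substrates, "substrate", "kinase"))
  data.frame(protein = members, provenance = prov,
             comparison = comparison, stringsAsFactors = FALSE)
}

#' Read a position weight matrix from a tabular file
#'
#' Expected layout: tab-separated, a `position` column with integers
#' -5..+5 (and optionally a row labelled `background`), plus one column
#' per amino acid containing probabilities that sum to 1 per row. When no
#' background row is present a uniform background (1/20) is used.
#'
#' @param path File path.
#' @return A motif model list with `mat` and `background`.
#' @export
read_pwm <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"position" %in% names(tab)) stop("PWM file needs a 'position' column")
  missing_aa <- setdiff(AMINO_ACIDS, names(tab))
  if (length(missing_aa)) {
    stop("PWM file missing amino-acid column(s): ",
         paste(missing_aa, collapse = ", "))
  }
  bg_row <- tab$position == "background"
  if (any(bg_row)) {
    background <- as.numeric(tab[which(bg_row)[1], AMINO_ACIDS])
    names(background) <- AMINO_ACIDS
    tab <- tab[!bg_row, , drop = FALSE]
  } else {
    background <- stats::setNames(rep(1 / 20, 20), AMINO_ACIDS)
  }
  pos <- as.integer(tab$position)
  tab <- tab[order(pos), , drop = FALSE]
  mat <- as.matrix(tab[, AMINO_ACIDS])
  rownames(mat) <- sort(pos)
  rs <- rowSums(mat)
  if (any(abs(rs - 1) > 1e-6)) stop("PWM rows must sum to 1")
  list(mat = mat, background = background)
}

#' Write a motif model to the tabular PWM format
#'
#' @param model Motif model list (`mat`, `background`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(model, path) {
  tab <- data.frame(position = rownames(model$mat),
                    model$mat[, AMINO_ACIDS],
                    check.names = FALSE, stringsAsFactors = FALSE)
  bg <- data.frame(position = "background",
                   t(model$background[AMINO_ACIDS]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(rbind(tab, bg), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
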