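# Phosphopeptide quantitation: HC/QP dataset construction and per-site
# comparison statistics on the log2 scale.

CONDITIONS <- c("WT", "WT_FGF", "FUS", "FUS_FGF")

#' Comparison definitions
#'
#' The three pairwise condition comparisons quantified by the four-channel
#' design: C1 = fusion vs wild-type unstimulated, C2 = fusion vs wild-type
#' under FGF1 stimulation, C3 = wild-type stimulated vs unstimulated.
#' Ratios are oriented numerator/denominator so that fusion-driven (C1, C2)
#' and stimulation-driven (C3) increases come out as positive log2 ratios.
#'
#' @return A data.frame with columns `id`, `numerator`, `denominator`.
#' @export
comparison_definitions <- function() {
  data.frame(
    id          = c("C1", "C2", "C3"),
    numerator   = c("FUS", "FUS_FGF", "WT_FGF"),
    denominator = c("WT", "WT_FGF", "WT"),
    stringsAsFactors = FALSE
  )
}

get_comparison <- function(comparison) {
  defs <- comparison_definitions()
  if (is.character(comparison) && length(comparison) == 1L) {
    i <- match(comparison, defs$id)
    if (is.na(i)) stop("unknown comparison id: ", comparison)
    return(defs[i, ])
  }
  stopifnot(is.data.frame(comparison),
            all(c("id", "numerator", "denominator") %in% names(comparison)))
  comparison[1, ]
}

#' Parse phosphosite annotation strings
#'
#' A site string is one or more residue/position tokens joined by "/",
#' e.g. `"Y132"` or `"T401/S405"`. Residues must be S, T or Y and positions
#' (1-based on the protein) must be strictly increasing. Multi-site peptides
#' are kept as one composite key; no site splitting is performed.
#'
#' @param x Character vector of site strings.
#' @return A list (one element per input) of data.frames with columns
#'   `position` (integer) and `residue` (character), or `NULL` where the
#'   string is unparsable.
#' @export
parse_sites <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(NULL)
    toks <- strsplit(s, "/", fixed = TRUE)[[1]]
    ok <- grepl("^[A-Z][0-9]+$", toks)
    if (!all(ok)) return(NULL)
    res <- substr(toks, 1, 1)
    pos <- as.integer(sub("^[A-Z]", "", toks))
    if (!all(res %in% c("S", "T", "Y"))) {
      return(structure(list(), bad_residue = TRUE))
    }
    if (length(pos) > 1 && any(diff(pos) <= 0)) return(NULL)
    data.frame(position = pos, residue = res, stringsAsFactors = FALSE)
  })
}

default_quant_schema <- function() {
  c(peptide_id = "peptide_id", protein = "protein", gene = "gene",
    sites = "sites", replicate = "replicate",
    WT = "WT", WT_FGF = "WT_FGF", FUS = "FUS", FUS_FGF = "FUS_FGF",
    id_fdr = "id_fdr", total_intensity = "total_intensity")
}

#' Load a phosphopeptide quantitation table
#'
#' Reads a TSV with one row per phosphopeptide per replicate carrying the
#' four reporter-ion intensities (arbitrary units; empty cells or "NA" are
#' missing), an identification-FDR tier and a site annotation string.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param schema Named character vector mapping internal field names
#'   (`peptide_id`, `protein`, `gene`, `sites`, `replicate`, `WT`, `WT_FGF`,
#'   `FUS`, `FUS_FGF`, `id_fdr`, `total_intensity`) to column names in the
#'   file. Defaults to the identity mapping.
#' @return A data.frame of phosphopeptide records (class `phospho_records`).
#'   `total_intensity` is computed as the row sum of observed channels when
#'   the column is absent from the file.
#' @export
load_quant_table <- function(path, schema = default_quant_schema()) {
  if (!file.exists(path)) stop("quant table not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           na.strings = c("", "NA"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  full <- default_quant_schema()
  full[names(schema)] <- schema
  required <- setdiff(names(full), "total_intensity")
  missing <- required[!(full[required] %in% names(raw))]
  if (length(missing)) {
    stop("quant table is missing required column(s): ",
         paste(full[missing], collapse = ", "))
  }
  rec <- data.frame(
    peptide_id = as.character(raw[[full["peptide_id"]]]),
    protein    = as.character(raw[[full["protein"]]]),
    gene       = as.character(raw[[full["gene"]]]),
    sites      = as.character(raw[[full["sites"]]]),
    replicate  = as.integer(raw[[full["replicate"]]]),
    id_fdr     = as.numeric(raw[[full["id_fdr"]]]),
    stringsAsFactors = FALSE
  )
  for (cond in CONDITIONS) {
    v <- as.numeric(raw[[full[cond]]])
    if (any(v < 0, na.rm = TRUE)) stop("negative intensity in channel ", cond)
    rec[[cond]] <- v
  }
  if (full["total_intensity"] %in% names(raw)) {
    rec$total_intensity <- as.numeric(raw[[full["total_intensity"]]])
  } else {
    rec$total_intensity <- rowSums(as.matrix(rec[CONDITIONS]), na.rm = TRUE)
  }
  parsed <- parse_sites(rec$sites)
  bad_res <- vapply(parsed, function(p) isTRUE(attr(p, "bad_residue")),
                    logical(1))
  if (any(bad_res)) {
    stop("residue outside S/T/Y in site string at row(s): ",
         paste(which(bad_res), collapse = ", "))
  }
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad)) {
    stop("unparsable site string(s) at row(s): ",
         paste(which(bad), collapse = ", "))
  }
  if (any(!is.finite(rec$id_fdr) | rec$id_fdr < 0 | rec$id_fdr > 1)) {
    stop("id_fdr must lie in [0, 1]")
  }
  rec$site_key <- paste0(rec$protein, "(", rec$sites, ")")
  class(rec) <- c("phospho_records", "data.frame")
  rec
}

#' High-confidence (HC) dataset
#'
#' Retains records identified at a stringent FDR tier. No channel
#' completeness is required, so a record may support some comparisons but
#' not others.
#'
#' @param records Phosphopeptide records.
#' @param hc_fdr Identification FDR ceiling (default 0.01).
#' @return The records passing the filter.
#' @export
build_hc_dataset <- function(records, hc_fdr = 0.01) {
  records[records$id_fdr <= hc_fdr, , drop = FALSE]
}

#' Quantitative phosphoproteomics (QP) dataset
#'
#' Broader seed-generation dataset: a relaxed identification FDR (5%) but
#' all four condition channels must be observed and positive, so every
#' comparison ratio is computable for every record.
#'
#' @param records Phosphopeptide records.
#' @param qp_fdr Identification FDR ceiling (default 0.05).
#' @return The records passing both filters.
#' @export
build_qp_dataset <- function(records, qp_fdr = 0.05) {
  m <- as.matrix(records[CONDITIONS])
  complete <- rowSums(is.na(m) | m <= 0) == 0
  records[records$id_fdr <= qp_fdr & complete, , drop = FALSE]
}

#' Per-site comparison summaries
#'
#' Groups records by composite site key and computes, per replicate, the
#' log2 reporter-intensity ratio of the comparison's numerator over its
#' denominator, then the replicate mean `mu`, standard deviation `sigma`
#' (0 when only one replicate) and the `mu +/- 1.96 sigma` interval.
#' Records missing either needed channel (or with a non-positive value)
#' are skipped for the comparison rather than raising an error.
#'
#' @param records Phosphopeptide records (typically the HC or QP dataset).
#' @param comparison A comparison id ("C1", "C2", "C3") or one row of
#'   [comparison_definitions()].
#' @param ci_mult Interval half-width multiplier in units of sigma
#'   (default 1.96).
#' @return A data.frame with one row per site: `site_key`, `protein`,
#'   `gene`, `comparison`, `n_replicates`, `mu`, `sigma`, `ci_low`,
#'   `ci_high`, `mean_total_intensity`.
#' @export
summarise_comparison <- function(records, comparison, ci_mult = 1.96) {
  cmp <- get_comparison(comparison)
  num <- records[[cmp$numerator]]
  den <- records[[cmp$denominator]]
  usable <- !is.na(num) & !is.na(den) & num > 0 & den > 0
  rec <- records[usable, , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(data.frame(site_key = character(), protein = character(),
                      gene = character(), comparison = character(),
                      n_replicates = integer(), mu = numeric(),
                      sigma = numeric(), ci_low = numeric(),
                      ci_high = numeric(),
                      mean_total_intensity = numeric(),
                      stringsAsFactors = FALSE))
  }
  lr <- log2(rec[[cmp$numerator]] / rec[[cmp$denominator]])
  key <- rec$site_key
  ord <- order(key)
  rec <- rec[ord, ]; lr <- lr[ord]; key <- key[ord]
  grp <- split(seq_along(key), factor(key, levels = unique(key)))
  out <- lapply(grp, function(idx) {
    x <- lr[idx]
    n <- length(x)
    mu <- mean(x)
    sigma <- if (n > 1) stats::sd(x) else 0
    data.frame(
      site_key = key[idx[1]],
      protein = rec$protein[idx[1]],
      gene = rec$gene[idx[1]],
      comparison = cmp$id,
      n_replicates = n,
      mu = mu,
      sigma = sigma,
      ci_low = mu - ci_mult * sigma,
      ci_high = mu + ci_mult * sigma,
      mean_total_intensity = mean(rec$total_intensity[idx], na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify site regulation from the mean log2 ratio
#'
#' A site is up-regulated when `mu >= threshold`, down-regulated when
#' `mu <= -threshold`, otherwise unchanged. Both thresholds are inclusive.
#'
#' @param mu Numeric vector of mean log2 ratios, or a summary data.frame
#'   with an `mu` column.
#' @param threshold Non-negative log2 magnitude threshold (default 0.5).
#' @return Character vector in `{"up", "down", "unchanged"}`.
#' @export
classify_regulation <- function(mu, threshold = 0.5) {
  if (is.data.frame(mu)) mu <- mu$mu
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    stop("threshold must be a single non-negative number")
  }
  ifelse(mu >= threshold, "up", ifelse(mu <= -threshold, "down", "unchanged"))
}

#' Strict regulation filter
#'
#' A site passes only when it was observed in more than one replicate and
#' the interval `mu +/- 1.96 sigma` excludes 0 on the log2 scale (i.e.
#' ratio 1 on the linear scale).
#'
#' @param summary A site summary data.frame from [summarise_comparison()].
#' @return Logical vector, one element per summary row.
#' @export
strict_filter <- function(summary) {
  summary$n_replicates > 1 &
    (summary$ci_low > 0 | summary$ci_high < 0)
}

#' Intensity-binned outlier significance (significance B)
#'
#' Orders sites by mean total reporter intensity (descending), partitions
#' them into consecutive bins of at least `bin_size` sites (the last short
#' bin is merged into its predecessor), and within each bin scores each
#' site's `mu` against an asymmetric robust null: the bin median `m` and
#' the side-specific spreads estimated from the 15.87 / 84.13 percentiles
#' (the one-sigma quantiles of a normal). The signed score
#' `z = (mu - m) / spread(side)` is converted to an upper-tail p-value
#' `p = erfc(z / sqrt(2)) / 2`, so p is ~uniform under a symmetric null:
#' strong up-outliers give p near 0 and strong down-outliers p near 1.
#' Use [sigb_significant()] for a two-tailed outlier call.
#'
#' @param summary Site summary data.frame with `mu` and
#'   `mean_total_intensity`.
#' @param bin_size Minimum sites per intensity bin (default 300). When
#'   fewer summaries than `bin_size` exist a single bin is used.
#' @return The summary with an added `sigb_p` column. In a degenerate bin
#'   (zero spread on a side) p is 1 at the median and NA elsewhere.
#' @export
significance_b <- function(summary, bin_size = 300) {
  n <- nrow(summary)
  summary$sigb_p <- rep(NA_real_, n)
  if (n == 0L) return(summary)
  ord <- order(summary$mean_total_intensity, decreasing = TRUE)
  n_bins <- max(1L, n %/% bin_size)
  bin_of <- pmin(((seq_len(n) - 1L) %/% bin_size) + 1L, n_bins)
  p <- numeric(n)
  for (b in seq_len(n_bins)) {
    idx <- ord[bin_of == b]
    mu <- summary$mu[idx]
    m <- stats::median(mu)
    q <- stats::quantile(mu, c(0.1587, 0.8413), names = FALSE, type = 7)
    s_lo <- m - q[1]
    s_hi <- q[2] - m
    z <- numeric(length(mu))
    hi <- mu >= m
    z[hi]  <- if (s_hi > 0) (mu[hi] - m) / s_hi else NA_real_
    z[!hi] <- if (s_lo > 0) (mu[!hi] - m) / s_lo else NA_real_
    pb <- stats::pnorm(z, lower.tail = FALSE)
    # degenerate side (zero spread): p = 1 at the median, undefined else
    pb[is.na(z) & mu == m] <- 1
    p[idx] <- pb
  }
  summary$sigb_p <- p
  summary
}

#' Two-tailed significance-B outlier call
#'
#' @param sigb_p Upper-tail p-values from [significance_b()].
#' @param alpha Per-tail significance level (default 0.05).
#' @return Logical: TRUE when the site is an outlier on either side.
#' @export
sigb_significant <- function(sigb_p, alpha = 0.05) {
  !is.na(sigb_p) & (sigb_p <= alpha | sigb_p >= 1 - alpha)
}

#' Select the most significantly regulated sites
#'
#' Applies the substantial-change threshold ([classify_regulation()]) and
#' the strict replicate/interval filter ([strict_filter()]) to an HC site
#' summary, flags each retained site's significance-B status, and sorts by
#' absolute effect size.
#'
#' @param summary HC site summary for one comparison, with `sigb_p` set
#'   (it is computed here if absent).
#' @param threshold Log2 magnitude threshold (default 0.5).
#' @param sigb_alpha Per-tail significance-B level for the flag.
#' @param bin_size Passed to [significance_b()] when `sigb_p` is missing.
#' @return Summary rows passing both filters, with `regulation`, `strict`,
#'   `sigb_flag` columns, ordered by decreasing `|mu|`.
#' @export
select_significant_sites <- function(summary, threshold = 0.5,
                                     sigb_alpha = 0.05, bin_size = 300) {
  if (!"sigb_p" %in% names(summary)) {
    summary <- significance_b(summary, bin_size = bin_size)
  }
  summary$regulation <- classify_regulation(summary$mu, threshold)
  summary$strict <- strict_filter(summary)
  summary$sigb_flag <- sigb_significant(summary$sigb_p, sigb_alpha)
  keep <- summary$regulation != "unchanged" & summary$strict
  out <- summary[keep, , drop = FALSE]
  out <- out[order(-abs(out$mu)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Protein-level overlap between the HC and QP datasets
#'
#' @param hc,qp Record data.frames (from [build_hc_dataset()] and
#'   [build_qp_dataset()]).
#' @param denominator `"union"` (Jaccard-style, default) or `"hc"`.
#' @return Overlap as a percentage; `NA` when both sets are empty.
#' @export
hc_qp_protein_overlap <- function(hc, qp, denominator = c("union", "hc")) {
  denominator <- match.arg(denominator)
  a <- unique(hc$protein); b <- unique(qp$protein)
  if (length(a) == 0 && length(b) == 0) return(NA_real_)
  inter <- length(intersect(a, b))
  den <- if (denominator == "union") length(union(a, b)) else length(a)
  if (den == 0) return(NA_real_)
  100 * inter / den
}

#' Write a site report TSV
#'
#' @param report Output of [select_significant_sites()] (or any summary
#'   with the same columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(report, path) {
  cols <- c("site_key", "comparison", "n_replicates", "mu", "sigma",
            "ci_low", "ci_high", "regulation", "strict", "sigb_p",
            "sigb_flag")
  cols <- intersect(cols, names(report))
  utils::write.table(report[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
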