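# phosphopeptide loading, HC/QP construction, per-site statistics

quant_fixture <- function(n = 10) {
  data.frame(
    peptide_id = paste0("pep", seq_len(n)),
    protein = paste0("P", seq_len(n)), gene = paste0("G", seq_len(n)),
    sites = rep(c("S12", "T45/S48", "Y132"), length.out = n),
    replicate = 1L, id_fdr = 0.005,
    WT = 100, WT_FGF = 110, FUS = 120, FUS_FGF = 130,
    total_intensity = 460, stringsAsFactors = FALSE
  )
}

test_that("load_quant_table reads, validates and keys records", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_fixture(quant_fixture(10), path)
  rec <- load_quant_table(path)
  expect_equal(nrow(rec), 10)
  expect_true(all(rec$site_key == paste0(rec$protein, "(", rec$sites, ")")))

  # site parsing: single sites, multi-site composites, 1-based positions
  p <- parse_sites(c("Y132", "T401/S405"))
  expect_equal(p[[1]], data.frame(position = 132L, residue = "Y",
                                  stringsAsFactors = FALSE))
  expect_equal(p[[2]]$position, c(401L, 405L))

  # invalid residue names the offending row
  bad <- quant_fixture(3)
  bad$sites[2] <- "A70"
  write_tsv_fixture(bad, path)
  expect_error(load_quant_table(path), "residue outside S/T/Y.*2")

  # non-increasing composite positions are unparsable
  bad$sites[2] <- "S48/T45"
  write_tsv_fixture(bad, path)
  expect_error(load_quant_table(path), "unparsable.*2")

  # missing required column is a schema error naming the column
  write_tsv_fixture(quant_fixture(2)[, -5], path)
  expect_error(load_quant_table(path), "replicate")

  # empty intensity cells become NA
  fx <- quant_fixture(2)
  fx$WT[1] <- NA
  write_tsv_fixture(fx, path)
  expect_true(is.na(load_quant_table(path)$WT[1]))
})

test_that("HC filter is an FDR threshold; QP also requires all channels", {
  rec <- make_records(paste0("P", 1:4, "(S10)"), replicate = 1L,
                      WT = c(10, 10, 10, NA), WT_FGF = 10, FUS = 10,
                      FUS_FGF = 10, id_fdr = c(0.005, 0.03, 0.06, 0.03))
  expect_equal(build_hc_dataset(rec)$protein, "P1")
  # no channel-completeness requirement: P4 keeps its NA channel
  expect_equal(build_hc_dataset(rec, hc_fdr = 0.05)$protein,
               c("P1", "P2", "P4"))
  expect_equal(nrow(build_hc_dataset(rec[0, ])), 0)
  # QP: 5% FDR and 4/4 channels observed and positive
  qp <- build_qp_dataset(rec)
  expect_equal(qp$protein, c("P1", "P2"))
  rec$WT[4] <- 0  # zero counts as unquantified
  expect_false("P4" %in% build_qp_dataset(rec)$protein)
})

test_that("summarise_comparison computes replicate log2 ratio statistics", {
  # three replicates with linear C1 ratios 1.6, 2.1, 1.9
  rec <- make_records(rep("P1(S10)", 3), replicate = 1:3,
                      WT = c(100, 100, 100), FUS = c(160, 210, 190))
  s <- summarise_comparison(rec, "C1")
  expect_equal(s$mu, mean(log2(c(1.6, 2.1, 1.9))))  # = 0.8914869
  expect_equal(s$sigma, sd(log2(c(1.6, 2.1, 1.9))))
  expect_equal(s$n_replicates, 3L)
  expect_equal(s$ci_low, s$mu - 1.96 * s$sigma)

  # constant ratio 2.0 across replicates: mu = 1, sigma = 0
  rec <- make_records(rep("P1(S10)", 2), replicate = 1:2,
                      WT = 50, FUS = 100)
  s <- summarise_comparison(rec, "C1")
  expect_equal(s$mu, 1); expect_equal(s$sigma, 0)

  # equal channels give mu = 0 for every comparison
  rec <- make_records(paste0("P", 1:3, "(S1)"), replicate = 1L,
                      WT = 7, WT_FGF = 7, FUS = 7, FUS_FGF = 7)
  for (cmp in c("C1", "C2", "C3")) {
    expect_equal(summarise_comparison(rec, cmp)$mu, rep(0, 3))
  }

  # records missing a needed channel are skipped, not fatal
  rec <- make_records(c("P1(S1)", "P2(S2)"), replicate = 1L,
                      WT = c(10, NA), FUS = c(20, 30))
  expect_equal(summarise_comparison(rec, "C1")$site_key, "P1(S1)")
  # orientation: FUS/WT, so fusion-high sites come out positive
  expect_gt(summarise_comparison(rec, "C1")$mu, 0)
})

test_that("regulation thresholds are inclusive and antisymmetric", {
  expect_equal(classify_regulation(c(0.5, -0.5, 0.49, -0.49, 2)),
               c("up", "down", "unchanged", "unchanged", "up"))
  expect_error(classify_regulation(1, threshold = -0.1), "non-negative")
  # antisymmetry: negating mu swaps up and down exactly
  set.seed(11)
  mu <- rnorm(500)
  a <- classify_regulation(mu); b <- classify_regulation(-mu)
  expect_equal(sum(a == "up"), sum(b == "down"))
  expect_equal(sum(a == "down"), sum(b == "up"))
})

test_that("strict filter needs >1 replicate and a 0-excluding interval", {
  s <- data.frame(n_replicates = c(1L, 3L, 2L, 2L),
                  mu = c(2.0, 0.8, 0.3, -0.7),
                  sigma = c(0, 0.1, 0.2, 0.2))
  s$ci_low <- s$mu - 1.96 * s$sigma
  s$ci_high <- s$mu + 1.96 * s$sigma
  # row 1: huge mu but single replicate; row 2: CI [0.604, 0.996];
  # row 3: CI [-0.092, 0.692] includes 0; row 4: negative, CI below 0
  expect_equal(strict_filter(s), c(FALSE, TRUE, FALSE, TRUE))
  expect_true(all(s$n_replicates[strict_filter(s)] >= 2))
})

test_that("select_significant_sites applies both filters and sorts", {
  s <- data.frame(site_key = paste0("P", 1:4, "(S1)"),
                  protein = paste0("P", 1:4), gene = paste0("P", 1:4),
                  comparison = "C1", n_replicates = c(3L, 3L, 1L, 3L),
                  mu = c(0.8, 0.4, 1.5, -1.2),
                  sigma = c(0.1, 0.05, 0.1, 0.2),
                  mean_total_intensity = c(4, 3, 2, 1) * 100)
  s$ci_low <- s$mu - 1.96 * s$sigma
  s$ci_high <- s$mu + 1.96 * s$sigma
  out <- select_significant_sites(s)
  # P2 fails the 0.5 threshold despite a clean CI; P3 is single-replicate
  expect_equal(out$site_key, c("P4(S1)", "P1(S1)"))  # by |mu| descending
  expect_equal(out$regulation, c("down", "up"))
  expect_s3_class(out, "data.frame")
  expect_equal(nrow(select_significant_sites(s[abs(s$mu) < 0.45, ])), 0)
})

test_that("HC/QP protein overlap supports union and HC denominators", {
  hc <- make_records(c("A(S1)", "B(S1)", "C(S1)"), 1L, WT = 1, FUS = 2)
  qp <- make_records(c("B(S1)", "C(S1)", "D(S1)"), 1L, WT = 1, FUS = 2)
  expect_equal(hc_qp_protein_overlap(hc, qp), 50)           # 2 / 4
  expect_equal(hc_qp_protein_overlap(hc, qp, "hc"), 200 / 3) # 2 / 3
  expect_equal(hc_qp_protein_overlap(hc, hc), 100)
  expect_equal(hc_qp_protein_overlap(hc, qp[0, ]), 0)
  expect_true(is.na(hc_qp_protein_overlap(hc[0, ], qp[0, ])))
})
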