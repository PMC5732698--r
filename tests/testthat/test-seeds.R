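# substrate seeding, motif and proximity likelihoods, median kinase filter

test_that("substrate seeds use the interval criterion without the 0.5 gate", {
  s <- data.frame(
    site_key = c("A(S1)", "B(S1)", "C(S1)", "C(S2)", "D(S1)"),
    protein = c("A", "B", "C", "C", "D"),
    n_replicates = c(2L, 1L, 2L, 2L, 3L),
    mu = c(0.25, 3.0, -0.1, -0.9, 0.1),
    ci_low = c(0.1, 2.9, -0.5, -1.2, -0.2),
    ci_high = c(0.4, 3.1, 0.3, -0.6, 0.4))
  # A: CI [0.1, 0.4] excludes 0 though |mu| < 0.5 -> seed
  # B: excluded, single replicate regardless of effect size
  # C: one null site, one clean down site -> seed (any site suffices)
  # D: interval straddles 0 -> not a seed
  expect_equal(substrate_seeds(s), c("A", "C"))
})

test_that("null substrate-seed rate matches the t-distribution oracle", {
  # with n replicates, mu +/- 1.96*s excludes 0 iff |t| > 1.96*sqrt(n);
  # under the null that happens with probability 2*P(t_{n-1} < -1.96*sqrt(n))
  spec <- synthetic_spec(seed = 101, n_sites = 4000, n_proteins = 4000,
                         n_regulated = 0, n_replicates = 3,
                         channel_dropout = 0)
  q <- gen_quant_table(spec)
  qs <- summarise_comparison(build_qp_dataset(q$records), "C1")
  rate <- length(substrate_seeds(qs)) / length(unique(qs$protein))
  expected <- 2 * pt(-1.96 * sqrt(3), df = 2)  # 0.0769 for n = 3
  expect_lt(abs(rate - expected), 0.02)
})

test_that("motif score is a product of per-position likelihood ratios", {
  # 3-position toy model with uniform background
  aa <- dragonet:::AMINO_ACIDS
  mat <- matrix(1 / 20, nrow = 3, ncol = 20, dimnames = list(-1:1, aa))
  mat[1, ] <- 0.01; mat[1, "R"] <- 1 - 19 * 0.01
  mat[2, ] <- 0.02; mat[2, "S"] <- 1 - 19 * 0.02
  mat[3, ] <- 1 / 20
  model <- list(mat = mat, background = setNames(rep(1 / 20, 20), aa))
  # consensus context: hand product (0.81/0.05) * (0.62/0.05) * 1
  expect_equal(motif_score("RSA", model),
               (0.81 / 0.05) * (0.62 / 0.05) * 1)
  # model equal to background scores 1 whatever the context
  flat <- list(mat = matrix(1 / 20, 3, 20, dimnames = list(-1:1, aa)),
               background = setNames(rep(1 / 20, 20), aa))
  expect_equal(motif_score("WYC", flat), 1)
  # pads contribute factor 1; a fully padded context scores 1
  expect_equal(motif_score("___", model), 1)
  expect_equal(motif_score("_S_", model), 0.62 / 0.05)
  expect_error(motif_score("RSX", model), "invalid symbol")
  expect_error(motif_score("RS", model), "length")
})

test_that("proximity likelihood follows exp(lambda*(d0 - d))", {
  g <- igraph::make_graph(~ A - B - C - D - E - F - G)
  expect_equal(proximity_score("A", "C", g), 1)            # d = 2 = d0
  expect_equal(proximity_score("A", "B", g), exp(1))       # d = 1
  expect_equal(proximity_score("A", "D", g), exp(-1))      # d = 3
  # unmapped proteins and unreachable pairs score the d_max floor
  expect_equal(proximity_score("Z", "A", g), exp(-4))
  g2 <- g + igraph::vertices("H")
  expect_equal(proximity_score("H", "A", g2), exp(-4))
  # distances beyond d_max are clamped to it
  expect_equal(proximity_score("A", "G", g), exp(2 - 6))
})

test_that("median filter keeps ties and at least half of predictions", {
  pred <- data.frame(site_key = "P1(S1)", protein = "P1",
                     kinase = c("K1", "K2", "K3"),
                     motif_lr = 1, proximity_lr = 1,
                     combined_lr = c(0.2, 1.0, 5.0),
                     stringsAsFactors = FALSE)
  out <- retain_kinases(pred)
  expect_equal(out$retained, c(FALSE, TRUE, TRUE))
  expect_equal(attr(out, "kinase_seeds"), c("K2", "K3"))
  # single prediction is its own median
  one <- retain_kinases(pred[1, ])
  expect_true(one$retained)
  # property: >= half survive for random score vectors
  set.seed(3)
  for (i in 1:20) {
    p <- pred[rep(1, 1 + rpois(1, 10)), ]
    p$combined_lr <- rlnorm(nrow(p))
    expect_gte(sum(retain_kinases(p)$retained), nrow(p) / 2)
  }
  expect_warning(retain_kinases(pred[0, ]), "no kinase predictions")
})

test_that("combined LR is the motif x proximity product (log-additive)", {
  g <- igraph::make_ring(5)
  igraph::V(g)$name <- c("P1", "K1", "K2", "X", "Y")
  pwms <- gen_pwms(n_kinases = 2, seed = 9)
  sites <- data.frame(site_key = "P1(S5)", protein = "P1",
                      context = sample_context(pwms$K1),
                      stringsAsFactors = FALSE)
  pred <- predict_kinases(sites, pwms, g)
  expect_equal(pred$combined_lr, pred$motif_lr * pred$proximity_lr)
  expect_equal(log(pred$combined_lr),
               log(pred$motif_lr) + log(pred$proximity_lr),
               tolerance = 1e-12)
})

test_that("a kinase that is also a substrate gets provenance 'both'", {
  ss <- build_seed_set(c("AKT1", "GSK3B", "HGS"), c("AKT1", "GSK3B", "FGR"),
                       comparison = "C1")
  expect_equal(ss$provenance[ss$protein == "AKT1"], "both")
  expect_equal(ss$provenance[ss$protein == "HGS"], "substrate")
  expect_equal(ss$provenance[ss$protein == "FGR"], "kinase")
  expect_setequal(ss$protein, c("AKT1", "GSK3B", "HGS", "FGR"))
})

test_that("the planted kinase ranks first for most of its sites", {
  set.seed(17)
  pwms <- gen_pwms(n_kinases = 5, seed = 23, concentration = 0.6)
  # star network: K1 adjacent to the substrate, other kinases far away
  g <- igraph::make_graph(~ P1 - K1, P1 - H1, H1 - H2, H2 - H3,
                          H3 - K2, H3 - K3, H3 - K4, H3 - K5)
  hits <- 0
  n_sites <- 50
  for (i in seq_len(n_sites)) {
    sites <- data.frame(site_key = sprintf("P1(S%d)", i), protein = "P1",
                        context = sample_context(pwms$K1),
                        stringsAsFactors = FALSE)
    pred <- predict_kinases(sites, pwms, g)
    if (pred$kinase[which.max(pred$combined_lr)] == "K1") hits <- hits + 1
  }
  expect_gte(hits / n_sites, 0.9)
})

test_that("PWM files round-trip", {
  pwms <- gen_pwms(n_kinases = 1, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pwm(pwms$K1, path)
  back <- read_pwm(path)
  expect_equal(back$mat, pwms$K1$mat, tolerance = 1e-12,
               ignore_attr = FALSE)
  expect_equal(back$background, pwms$K1$background, tolerance = 1e-12)
})
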