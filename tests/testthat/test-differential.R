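# condition-unique / shared pathway sets, HC validation, the 25% rule,
# and graph exports

test_that("set operations are exact differences and intersection", {
  a <- c("R1", "R2", "R3"); b <- c("R2", "R3", "R4")
  ops <- set_ops(a, b)
  expect_equal(ops$unique_a, "R1")
  expect_equal(ops$unique_b, "R4")
  expect_equal(ops$shared, c("R2", "R3"))
  # identity and disjoint cases
  same <- set_ops(a, a)
  expect_length(same$unique_a, 0); expect_equal(same$shared, sort(a))
  disj <- set_ops(a, c("X1", "X2"))
  expect_length(disj$shared, 0)
  # cardinality invariant |unique_A| + |shared| = |A|
  set.seed(8)
  for (i in 1:20) {
    aa <- sample(paste0("R", 1:50), sample(5:30, 1))
    bb <- sample(paste0("R", 1:50), sample(5:30, 1))
    o <- set_ops(aa, bb)
    expect_equal(length(o$unique_a) + length(o$shared), length(unique(aa)))
    expect_equal(length(o$unique_b) + length(o$shared), length(unique(bb)))
    expect_length(intersect(o$unique_a, o$unique_b), 0)
  }
})

test_that("HC validation keeps pathways with at least one HC hit", {
  hits <- list(PW1 = c("LMNA", "X1"), PW2 = c("X2", "X3"),
               PW3 = c("TLN1", "SSR1"))
  hc <- c("LMNA", "TLN1", "SSR1")
  expect_equal(hc_filter(hits, hc), c("PW1", "PW3"))
  expect_length(hc_filter(hits, character(0)), 0)
  # monotone in the HC set: enlarging HC never removes a pathway
  more <- hc_filter(hits, c(hc, "X2"))
  expect_true(all(c("PW1", "PW3") %in% more))
})

test_that("the 25% rule is inclusive with a zero-hit limit", {
  sd <- shared_differential(c("P1", "P2", "P3", "P4", "P5"),
                            hits_a = c(P1 = 5, P2 = 4, P3 = 6,
                                       P4 = 3, P5 = 0),
                            hits_b = c(P1 = 4, P2 = 4, P3 = 5,
                                       P4 = 0, P5 = 2))
  # P1: 5 >= 1.25*4 = 5.0 inclusive -> A; P2: equal -> none;
  # P3: 6 < 6.25 -> none; P4: B zero, A positive -> A; P5: reverse -> B
  expect_equal(sd$direction, c("A", "none", "none", "A", "B"))
  expect_error(shared_differential("P1", c(P1 = 1), c(P1 = 1), -0.5),
               "non-negative")
  # flags for A and B are mutually exclusive when both counts positive
  set.seed(12)
  for (i in 1:30) {
    ha <- c(PX = sample(1:10, 1)); hb <- c(PX = sample(1:10, 1))
    d <- shared_differential("PX", ha, hb, 0.25)$direction
    expect_true(d %in% c("A", "B", "none"))
  }
})

fake_enrichment <- function(ids, sig, hits) {
  data.frame(pathway = ids, name = ids, n_members = 10,
             n_hits = lengths(hits), p_value = 0.001, q_value = 0.001,
             significant = sig, stringsAsFactors = FALSE) |>
    (\(d) { d$hits <- hits; d })()
}

test_that("differential_report assembles all classifications", {
  enr_a <- fake_enrichment(c("PA", "PS1", "PS2"), rep(TRUE, 3),
                           list(c("HCP", "Q1"), c("Q2", "Q3", "Q4"),
                                c("Q5")))
  enr_b <- fake_enrichment(c("PB", "PS1", "PS2"), rep(TRUE, 3),
                           list(c("Q9"), c("Q2"), c("Q5")))
  rep <- differential_report(enr_a, enr_b, hc_proteins = "HCP",
                             fraction = 0.25)
  expect_equal(rep$unique_a, "PA"); expect_equal(rep$unique_b, "PB")
  expect_equal(rep$shared, c("PS1", "PS2"))
  expect_equal(rep$hc_validated_unique_a, "PA")  # has HCP
  expect_length(rep$hc_validated_unique_b, 0)
  # PS1 has 3 vs 1 hits -> A; PS2 tied -> unflagged
  expect_equal(rep$shared_differential$pathway, "PS1")
  expect_equal(rep$shared_differential$direction, "A")
  expect_output(print(rep), "unique to A: 1")
})

test_that("pathway graph export round-trips through GraphML", {
  enr_a <- fake_enrichment(c("PA", "PS"), c(TRUE, TRUE),
                           list(c("HCP", "Q1"), c("Q2", "Q3")))
  enr_b <- fake_enrichment(c("PB", "PS"), c(TRUE, TRUE),
                           list(c("Q1"), c("Q2")))
  rep <- differential_report(enr_a, enr_b, "HCP")
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("PA\ta\tHCP\tQ1\tX", "PB\tb\tQ1\tX\tY",
               "PS\ts\tQ2\tQ3\tZ"), gmt)
  db <- load_gmt(gmt)
  h <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("parent\tchild", "PA\tPS"), h)
  db <- load_hierarchy(db, h)
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  g <- export_pathway_graph(rep, db, hc_proteins = "HCP",
                            qp_proteins = c("Q1", "Q2"),
                            graphml_path = gml, tsv_path = tsv)
  # node attributes: pathway class and protein confidence tiers
  v <- igraph::V(g)
  expect_equal(v$class[v$name == "PA"], "unique_A")
  expect_equal(v$confidence[v$name == "HCP"], "HC")
  expect_equal(v$confidence[v$name == "Q1"], "QP")
  expect_equal(v$confidence[v$name == "Q3"], "network-only")
  # hierarchy edge present between the two retained pathways
  expect_true(igraph::are_adjacent(g, "PA", "PS"))
  # GraphML round trip preserves node and edge sets
  back <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(back)$name, v$name)
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  el <- read.delim(tsv)
  expect_true(all(c("from", "to", "type") %in% names(el)))
})

test_that("a two-pathway one-shared-protein report gives a 3-node graph", {
  enr_a <- fake_enrichment("PA", TRUE, list("Q1"))
  enr_b <- fake_enrichment("PB", TRUE, list("Q1"))
  rep <- differential_report(enr_a, enr_b, character(0))
  db <- list(pathways = list(PA = "Q1", PB = "Q1"),
             names = c(PA = "a", PB = "b"), hierarchy = NULL)
  g <- export_pathway_graph(rep, db)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
})

test_that("local phospho context collects kinases and neighbours", {
  g <- igraph::make_graph(~ P1 - K1, P1 - N1, P2 - K1, P2 - N2, N2 - F1)
  pred <- data.frame(site_key = c("P1(S1)", "P2(S2)"),
                     protein = c("P1", "P2"), kinase = c("K1", "K1"),
                     motif_lr = 1, proximity_lr = 1, combined_lr = 1,
                     retained = TRUE, stringsAsFactors = FALSE)
  sg <- local_phospho_context(c("P1", "P2"), g, pred,
                              regulation = data.frame(
                                site_key = "P1(S1)", protein = "P1",
                                regulation = "up"))
  # core proteins, their kinase, and first neighbours; F1 is two hops out
  expect_setequal(igraph::V(sg)$name, c("P1", "P2", "K1", "N1", "N2"))
  v <- igraph::V(sg)
  expect_equal(v$role[v$name == "K1"], "kinase")
  expect_equal(v$role[v$name == "P1"], "substrate")
  expect_equal(v$regulation[v$name == "P1"], "up")
  eid <- igraph::get_edge_ids(sg, c("K1", "P1"))
  expect_true(igraph::E(sg)$predicted[eid])
  # a protein that is both kinase and substrate keeps one node, role both
  pred2 <- rbind(pred, data.frame(site_key = "K1(S9)", protein = "K1",
                                  kinase = "P1", motif_lr = 1,
                                  proximity_lr = 1, combined_lr = 1,
                                  retained = TRUE))
  sg2 <- local_phospho_context(c("P1", "K1"), g, pred2)
  expect_equal(sum(igraph::V(sg2)$name == "P1"), 1)
  expect_equal(igraph::V(sg2)$role[igraph::V(sg2)$name == "P1"], "both")
  expect_error(local_phospho_context("ZZ", g, pred), "none of the proteins")
})
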