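test_that("the depression case-study graph has the expected shape", {
  tab2 <- fixture_corpus("table2_depression.csv")
  g <- build_network(tab2)
  expect_equal(igraph::ecount(g), 28)
  expect_equal(sum(igraph::V(g)$role == "condition"), 1)
  expect_equal(sum(igraph::V(g)$role == "predictor"), 27) # physical activity twice
  expect_equal(condition_degree(g, "Depression"), 28)
  expect_equal(condition_degree(g, "depression", distinct = TRUE), 27)
  expect_equal(condition_degree(g, "no such condition"), 0)
})

test_that("the bipartite handshake identity holds on every corpus", {
  corpora <- list(
    fixture_corpus("table2_depression.csv"),
    fixture_corpus("table3_sii.csv"),
    generate_corpus(synthetic_config(n_studies = 120, seed = 3))$corpus
  )
  for (corp in corpora) {
    g <- build_network(corp)
    tbl <- degree_table(g)
    expect_equal(sum(tbl$papers[tbl$role == "condition"]), nrow(corp))
    expect_equal(sum(tbl$papers[tbl$role == "predictor"]), nrow(corp))
  }
})

test_that("node degrees match the generator's ground-truth edge counts", {
  sim <- generate_corpus(synthetic_config(n_studies = 150, seed = 8))
  g <- build_network(sim$corpus)
  truth_deg <- table(sprintf("condition_%03d", sim$truth$condition_idx))
  for (lab in names(truth_deg)) {
    expect_equal(condition_degree(g, lab), as.integer(truth_deg[[lab]]))
  }
})

test_that("build_network is invariant to record order", {
  corp <- fixture_corpus("table2_depression.csv")
  shuffled <- corp[rev(seq_len(nrow(corp))), ]
  attr(shuffled, "provenance") <- attr(corp, "provenance")
  g1 <- build_network(corp)
  g2 <- build_network(shuffled)
  expect_equal(degree_table(g1), degree_table(g2))
})

test_that("multifactorial_conditions applies the degree threshold", {
  tab2 <- fixture_corpus("table2_depression.csv")
  g <- build_network(tab2)
  expect_equal(multifactorial_conditions(g, min_edges = 4)$label, "depression")
  expect_equal(nrow(multifactorial_conditions(g, min_edges = 29)), 0)
  # min_edges = 1 returns every condition
  sim <- generate_corpus(synthetic_config(n_studies = 80, seed = 12))
  gs <- build_network(sim$corpus)
  expect_equal(
    sort(multifactorial_conditions(gs, 1)$label),
    sort(unique(normalize_label(sim$corpus$outcome)))
  )
  expect_error(multifactorial_conditions(g, 0), "min_edges")
})

test_that("dual-role variables are detected with supporting studies", {
  corp <- toy_corpus(
    toy_row("37481511", "CRP", "periodontitis"),
    toy_row("38628050", "health behavior index", "CRP")
  )
  dr <- dual_role_variables(corp)
  expect_equal(dr$label, "crp")
  expect_equal(dr$predictor_ids, "37481511")
  expect_equal(dr$outcome_ids, "38628050")
  expect_equal(nrow(attr(dr, "reversed_pairs")), 0)

  # no dual roles in the depression table
  expect_equal(nrow(dual_role_variables(fixture_corpus("table2_depression.csv"))), 0)

  rev2 <- toy_corpus(toy_row("s1", "A", "B"), toy_row("s2", "B", "A"))
  dr2 <- dual_role_variables(rev2)
  expect_equal(dr2$label, c("a", "b"))
  rp <- attr(dr2, "reversed_pairs")
  expect_equal(nrow(rp), 1)
  expect_equal(c(rp$label_a, rp$label_b), c("a", "b"))
})

test_that("GraphML export round-trips losslessly", {
  for (corp in list(
    fixture_corpus("table2_depression.csv"),
    generate_corpus(synthetic_config(n_studies = 60, seed = 21))$corpus
  )) {
    g <- build_network(corp)
    path <- withr::local_tempfile(fileext = ".graphml")
    export_graphml(g, path)
    g2 <- read_graphml(path)
    expect_equal(igraph::ecount(g2), igraph::ecount(g))
    expect_equal(degree_table(g2), degree_table(g))
    edge_sig <- function(gr) {
      ends <- igraph::ends(gr, igraph::E(gr))
      sort(paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]),
        igraph::E(gr)$study_id,
        sep = "|"
      ))
    }
    expect_equal(edge_sig(g2), edge_sig(g))
  }

  empty <- build_network(fixture_corpus("table2_depression.csv")[0, ])
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(empty, path)
  expect_equal(igraph::vcount(read_graphml(path)), 0)
})
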