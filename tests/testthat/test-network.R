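test_that("pearson_matrix reproduces exact correlations and p-values", {
  ctrl <- named_matrix(cbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(5, 1, 4, 2)), "A")
  cohort <- make_cohort(ctrl, named_matrix(matrix(rexp(12) + 1, 4, 3), "A"))
  cr <- pearson_matrix(cohort, "control")
  expect_equal(cr$r["A01", "A02"], 1)
  expect_equal(cr$p["A01", "A02"], 0)
  expect_true(isSymmetric(cr$r))
  expect_true(isSymmetric(cr$p))
  expect_equal(unname(diag(cr$r)), rep(1, 3))
  # p from the t transform agrees with cor.test
  ct <- cor.test(ctrl[, 1], ctrl[, 3])
  expect_equal(cr$p["A01", "A03"], ct$p.value, tolerance = 1e-10)
  expect_error(pearson_matrix(cohort[c(1, 5), ], "control"),
               class = "plasmanet_validation_error")
})

test_that("zero-variance analytes are excluded with a warning", {
  ctrl <- named_matrix(cbind(rnorm(5), rep(7, 5)), "A")
  cohort <- make_cohort(ctrl, named_matrix(matrix(rnorm(10) + 9, 5, 2), "A"))
  expect_warning(cr <- pearson_matrix(cohort, "control"), "zero-variance")
  expect_identical(cr$analyte_ids, "A01")
})

test_that("threshold_graph applies the inclusive edge rule and drops isolates", {
  set.seed(7)
  x1 <- rnorm(30)
  ctrl <- named_matrix(cbind(x1, x1, rnorm(30)), "A")  # A2 copies A1
  cohort <- make_cohort(ctrl, named_matrix(matrix(rnorm(90), 30, 3), "A"))
  g <- threshold_graph(pearson_matrix(cohort, "control"), r_min = 0.8)
  expect_equal(nrow(g$edges), 1)
  expect_setequal(g$nodes, c("A01", "A02"))
  expect_equal(g$n_isolated, 1)

  # boundary: r exactly at the threshold forms an edge (>= is inclusive)
  ids <- c("A", "B", "C")
  r <- diag(3); r[1, 2] <- r[2, 1] <- 0.8; r[1, 3] <- r[3, 1] <- 0.7999999
  p <- matrix(1e-6, 3, 3); diag(p) <- 0
  dimnames(r) <- dimnames(p) <- list(ids, ids)
  cr_exact <- structure(list(analyte_ids = ids, r = r, p = p, n = 30,
                             group = "control", stage = NULL),
                        class = "plasmanet_correlation")
  g_at <- threshold_graph(cr_exact, r_min = 0.8)
  expect_equal(nrow(g_at$edges), 1)
  expect_setequal(g_at$nodes, c("A", "B"))

  # everything below the threshold: empty graph, no nodes
  g_none <- threshold_graph(cr_exact, r_min = 0.9)
  expect_equal(length(g_none$nodes), 0)
  expect_equal(nrow(g_none$edges), 0)
})

test_that("signed thresholding distinguishes anticorrelation", {
  x <- c(1, 2, 3, 4, 5)
  ctrl <- named_matrix(cbind(x, -x + 0.001 * c(1, -1, 0, 1, -1), x * 0), "A")
  ctrl[, 3] <- rnorm(5)
  cohort <- make_cohort(ctrl, named_matrix(matrix(rnorm(15), 5, 3), "A"))
  cr <- pearson_matrix(cohort, "control")
  pos_only <- threshold_graph(cr, r_min = 0.9, signed = TRUE)
  both <- threshold_graph(cr, r_min = 0.9, signed = FALSE)
  expect_equal(nrow(pos_only$edges), 0)
  expect_equal(nrow(both$edges), 1)
})

test_that("clustering coefficients match hand calculations", {
  expect_equal(clustering_coefficients(k_complete(3))$clustering, rep(1, 3))
  path <- metabolite_graph(data.frame(from = c("a", "b"), to = c("b", "c")))
  cc <- clustering_coefficients(path)
  expect_equal(cc$clustering[cc$analyte_id == "b"], 0)
  # K4 minus one edge: the two degree-3 nodes see 2 of 3 neighbour pairs
  k4m <- metabolite_graph(data.frame(
    from = c("a", "a", "a", "b", "b"), to = c("b", "c", "d", "c", "d")))
  cc4 <- clustering_coefficients(k4m)
  expect_equal(sort(cc4$clustering), c(2 / 3, 2 / 3, 1, 1))
  expect_equal(mean(cc4$clustering), 5 / 6)
})

test_that("closed-form graphs give the printed-formula parameter values", {
  k5 <- topology_report(k_complete(5))
  expect_equal(k5$density, 1)
  expect_equal(k5$avg_clustering, 1)
  expect_equal(k5$heterogeneity, 0)
  expect_equal(k5$diameter, 1L)
  expect_equal(k5$avg_shortest_path, 1)
  expect_equal(k5$avg_degree, 4)
  expect_equal(k5$centralization, 0)
  expect_equal(k5$connected_components, 1L)

  star <- topology_report(star_graph(3))
  expect_equal(star$heterogeneity, sqrt(0.75) / 1.5)
  expect_equal(star$centralization, 1)
  expect_equal(star$assortativity, -1)
  expect_equal(star$avg_shortest_path, (2 * 3 + 6 * 2) / 12)

  tri2 <- topology_report(two_triangles())
  expect_equal(tri2$connected_components, 2L)
  expect_equal(tri2$modularity, 0.5)
  expect_equal(tri2$diameter, 1L)
})

test_that("every topology metric agrees with brute-force oracles on random graphs", {
  cases <- expand.grid(seed = 1:12, p = c(0.1, 0.3, 0.6))
  for (i in seq_len(nrow(cases))) {
    g <- random_er_graph(n = sample(5:25, 1), p = cases$p[i],
                         seed = 1000 + 37 * i)
    tp <- topology_report(g)
    a <- oracle_adjacency(g$nodes, g$edges)
    k <- rowSums(a)
    n <- length(g$nodes)
    expect_equal(tp$n_links, sum(a) / 2)
    expect_equal(tp$avg_degree, mean(k))
    expect_equal(tp$density, sum(a) / (n * (n - 1)))
    expect_equal(tp$avg_clustering, mean(oracle_clustering(a)))
    expect_equal(tp$centralization, sum(max(k) - k) / ((n - 1) * (n - 2)))
    if (nrow(g$edges) > 0) {
      expect_equal(tp$heterogeneity, sqrt(mean((k - mean(k))^2)) / mean(k))
      d <- oracle_distances(a)
      finite <- d[is.finite(d) & d > 0]
      expect_equal(tp$avg_shortest_path, mean(finite))
      expect_equal(tp$diameter, as.integer(max(finite)))
      expect_equal(tp$assortativity, oracle_assortativity(a, g$edges),
                   tolerance = 1e-12)
      expect_equal(tp$modularity,
                   oracle_modularity(a, g$edges, tp$membership))
    }
  }
})

test_that("topology metrics cross-check against igraph", {
  for (s in 1:5) {
    g <- random_er_graph(15, 0.3, seed = 555 + s)
    tp <- topology_report(g)
    ig <- igraph::graph_from_data_frame(g$edges[, 1:2], directed = FALSE,
                                        vertices = g$nodes)
    expect_equal(tp$avg_clustering,
                 mean(igraph::transitivity(ig, type = "localundirected",
                                           isolates = "zero")))
    dd <- igraph::distances(ig)
    finite <- dd[is.finite(dd) & dd > 0]
    expect_equal(tp$avg_shortest_path, mean(finite))
    expect_equal(tp$assortativity,
                 igraph::assortativity_degree(ig), tolerance = 1e-12)
    expect_equal(tp$modularity,
                 igraph::modularity(ig, tp$membership[igraph::V(ig)$name]),
                 tolerance = 1e-12)
  }
})

test_that("degenerate graphs report undefined statistics without crashing", {
  empty <- metabolite_graph(data.frame(from = character(),
                                       to = character()))
  tp <- topology_report(empty)
  expect_equal(tp$n_nodes, 0)
  expect_true(is.na(tp$density))
  expect_true(is.na(tp$avg_shortest_path))
  expect_true(is.na(tp$modularity))

  lone_edge <- metabolite_graph(data.frame(from = "a", to = "b"))
  tp2 <- topology_report(lone_edge)
  expect_true(is.na(tp2$centralization))  # N < 3
  expect_true(is.na(tp2$assortativity))   # no degree variance on stubs
  expect_equal(tp2$avg_shortest_path, 1)
})

test_that("graph construction ignores sample and analyte order", {
  cfg <- simulation_config(n_control = 30, n_case = 30, n_case_early = 0,
                           seed = 12)
  cohort <- simulate_cohort(cfg)
  g1 <- threshold_graph(pearson_matrix(cohort, "case"))
  shuffled <- cohort[sample(nrow(cohort)),
                     c(reserved <- c("sample_id", "group", "stage"),
                       sample(cohort_analytes(cohort)))]
  g2 <- threshold_graph(pearson_matrix(shuffled, "case"))
  expect_identical(g1$nodes, g2$nodes)
  expect_equal(as.data.frame(g1$edges), as.data.frame(g2$edges))
})

test_that("hub nodes carry the maximal degree with all ties listed", {
  g <- metabolite_graph(data.frame(
    from = c("h1", "h1", "h1", "h2", "h2", "h2"),
    to   = c("a", "b", "c", "a", "b", "c")))
  tp <- topology_report(g)
  expect_setequal(tp$hubs$analyte_id, c("h1", "h2"))
  expect_equal(unique(tp$hubs$degree), 3L)
})

test_that("stage subsampling is seeded, uniform, and bounded", {
  cohort <- simulate_cohort(simulation_config(n_control = 5, n_case = 30,
                                              n_case_early = 20, seed = 2))
  s1 <- subsample_group(cohort, "early", 10, seed = 4)
  s2 <- subsample_group(cohort, "early", 10, seed = 4)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 10)
  expect_true(all(s1$stage == "early"))
  all20 <- subsample_group(cohort, "early", 20, seed = 4)
  expect_setequal(all20$sample_id,
                  cohort$sample_id[!is.na(cohort$stage) &
                                     cohort$stage == "early"])
  expect_error(subsample_group(cohort, "advanced", 11, seed = 1))
  # inclusion frequencies are uniform across seeds
  counts <- table(unlist(lapply(1:200, function(s) {
    subsample_group(cohort, "early", 10, seed = s)$sample_id
  })))
  p <- 10 / 20
  se <- sqrt(p * (1 - p) / 200)
  expect_true(all(abs(counts / 200 - p) < 4 * se))
})

test_that("edge lists and GraphML exports are written", {
  g <- two_triangles()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), 6)
  xml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, xml)
  doc <- xml2::read_xml(xml)
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='node']")), 6)
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='edge']")), 6)
})
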