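# PageRank, flux, edge selection, and the assembled disease network.

test_that("pagerank on trivial graphs matches hand solutions", {
  single <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(single)$name <- "A"
  expect_equal(unname(personalized_pagerank(single, "A")["A"]), 1.0)

  edge <- interactome(data.frame(node_a = "A", node_b = "B", weight = 1))
  pr <- personalized_pagerank(edge, "A", alpha = 0.5)
  expect_equal(unname(pr["A"]), 2 / 3, tolerance = 1e-10)
  expect_equal(unname(pr["B"]), 1 / 3, tolerance = 1e-10)

  # vertex-transitive graph, all nodes seeds -> uniform
  ring <- igraph::make_ring(4)
  igraph::V(ring)$name <- LETTERS[1:4]
  igraph::E(ring)$weight <- 1
  pr4 <- personalized_pagerank(ring, LETTERS[1:4], alpha = 0.5)
  expect_equal(unname(pr4), rep(0.25, 4), tolerance = 1e-10)
})

test_that("iterative pagerank equals the dense linear-system solution", {
  set.seed(31)
  for (i in 1:25) {
    g <- random_weighted_graph(sample(3:10, 1), p = 0.4, seed = 300 + i)
    seeds <- sample(igraph::V(g)$name, sample(1:3, 1))
    got <- personalized_pagerank(g, seeds, alpha = runif(1, 0.2, 0.9))
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
  for (i in 1:10) {
    g <- random_weighted_graph(sample(3:10, 1), p = 0.5, seed = 400 + i)
    seeds <- sample(igraph::V(g)$name, 2)
    alpha <- 0.5
    got <- personalized_pagerank(g, seeds, alpha)
    want <- pagerank_oracle(g, seeds, alpha)
    expect_lt(max(abs(got - want[names(got)])), 1e-10)
  }
})

test_that("pagerank errors on an empty seed set", {
  g <- random_weighted_graph(5, seed = 9)
  expect_error(personalized_pagerank(g, character(0)),
               class = "cohortnet_missing_seeds")
  expect_error(personalized_pagerank(g, "ZZZ"),
               class = "cohortnet_missing_seeds")
})

test_that("flux matches its defining formula and invariances", {
  edge <- interactome(data.frame(node_a = "A", node_b = "B", weight = 1))
  pr <- personalized_pagerank(edge, "A", alpha = 0.5)
  fl <- edge_flux(edge, pr)
  expect_equal(fl$flux, 1 / 3, tolerance = 1e-10)  # min(2/3, 1/3)
  fl_sum <- edge_flux(edge, pr, mode = "sum")
  expect_equal(fl_sum$flux, 1, tolerance = 1e-10)

  # uniform pr on a regular graph -> equal fluxes
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- LETTERS[1:6]
  igraph::E(ring)$weight <- 1
  pru <- setNames(rep(1 / 6, 6), LETTERS[1:6])
  expect_equal(length(unique(round(edge_flux(ring, pru)$flux, 12))), 1)

  # weight rescaling leaves fluxes unchanged
  g <- random_weighted_graph(8, seed = 17)
  prg <- personalized_pagerank(g, igraph::V(g)$name[1:2])
  f1 <- edge_flux(g, prg)
  g2 <- g; igraph::E(g2)$weight <- igraph::E(g)$weight * 7.5
  f2 <- edge_flux(g2, prg)
  expect_equal(f1$flux, f2$flux, tolerance = 1e-12)
})

test_that("edge selection honors the quantile threshold and the edge cap", {
  # 5-edge GGN with distinct fluxes: tau = 0.8 keeps only the top edge
  df <- data.frame(node_a = c("A", "B", "C", "D", "E"),
                   node_b = c("B", "C", "D", "E", "A"), weight = 1)
  g <- interactome(df)
  ggn <- list(graph = g)
  fl <- edge_flux(g, setNames(rep(0.2, 5), LETTERS[1:5]))
  fl$flux <- c(5, 4, 3, 2, 1)
  pr <- setNames(rep(0.2, 5), LETTERS[1:5])
  sel <- select_network(ggn, fl, pr, inference_params(tau = 0.8))
  expect_equal(nrow(sel$edges), 1)
  expect_equal(sel$edges$flux, 5)

  sel0 <- select_network(ggn, fl, pr, inference_params(tau = 0))
  expect_equal(nrow(sel0$edges), 5)

  cap <- select_network(ggn, fl, pr, inference_params(tau = 0,
                                                      edge_cap = 3))
  expect_equal(nrow(cap$edges), 3)
  expect_equal(cap$edges$flux, c(5, 4, 3))
})

test_that("raising tau never increases the selected edge count", {
  study <- simulate_study(generator_params(rng_seed = 6, n_genes = 400,
                                           module_size = 20,
                                           n_driver_genes = 12,
                                           n_ndd_genes = 60))
  g <- study$interactome
  seeds <- sort(unique(study$driver_list$gene))
  set.seed(5)
  ggn <- suppressWarnings(build_ggn(g, seeds,
                                    inference_params(n_rewires = 30)))
  pr <- personalized_pagerank(g, ggn$seeds)
  fl <- edge_flux(ggn$graph, pr)
  counts <- vapply(c(0, 0.25, 0.5, 0.8, 0.95), function(tau)
    nrow(select_network(ggn, fl, pr,
                        inference_params(tau = tau))$edges), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("inference is deterministic and nested in GGN and interactome", {
  study <- simulate_study(generator_params(rng_seed = 2, n_genes = 400,
                                           module_size = 20,
                                           n_driver_genes = 12,
                                           n_ndd_genes = 60))
  g <- study$interactome
  seeds <- sort(unique(study$driver_list$gene))
  params <- inference_params(n_rewires = 30)
  n1 <- suppressWarnings(infer_disease_network(g, seeds, params,
                                               rng_seed = 77))
  n2 <- suppressWarnings(infer_disease_network(g, seeds, params,
                                               rng_seed = 77))
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$nodes, n2$nodes)

  # network edges within GGN edges within interactome edges
  sel_ids <- igraph::get_edge_ids(
    n1$ggn$graph, as.vector(t(as.matrix(n1$edges[, c("from", "to")]))))
  expect_true(all(sel_ids > 0))
  ggn_ids <- igraph::get_edge_ids(
    g, as.vector(t(igraph::as_edgelist(n1$ggn$graph))))
  expect_true(all(ggn_ids > 0))
  expect_lte(nrow(n1$edges), params$edge_cap)
})
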