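# Generator determinism, construction guarantees, and round-tripping.

test_that("every generator output is a pure function of the seed", {
  s1 <- simulate_study(generator_params(rng_seed = 12, n_genes = 300,
                                        module_size = 15,
                                        n_ndd_genes = 50))
  s2 <- simulate_study(generator_params(rng_seed = 12, n_genes = 300,
                                        module_size = 15,
                                        n_ndd_genes = 50))
  expect_identical(igraph::as_edgelist(s1$interactome),
                   igraph::as_edgelist(s2$interactome))
  expect_identical(igraph::E(s1$interactome)$weight,
                   igraph::E(s2$interactome)$weight)
  expect_identical(s1$catalog_a$records, s2$catalog_a$records)
  expect_identical(s1$catalog_b$records, s2$catalog_b$records)
  expect_identical(s1$reg$pairs, s2$reg$pairs)
  expect_identical(s1$pathways, s2$pathways)
  expect_identical(s1$z_table, s2$z_table)
  s3 <- simulate_study(generator_params(rng_seed = 13, n_genes = 300,
                                        module_size = 15,
                                        n_ndd_genes = 50))
  expect_false(identical(s1$z_table, s3$z_table))
})

test_that("interactome is simple and the planted module is denser than background", {
  dens_ratio <- vapply(1:10, function(s) {
    ia <- generate_interactome(generator_params(rng_seed = 600 + s))
    g <- ia$graph
    expect_false(igraph::any_loop(g))
    expect_false(igraph::any_multiple(g))
    expect_true(all(igraph::E(g)$weight > 0 & igraph::E(g)$weight <= 1))
    mod <- ia$truth$planted_module
    dm <- igraph::edge_density(igraph::induced_subgraph(g, mod))
    dm / igraph::edge_density(g)
  }, numeric(1))
  expect_true(all(dens_ratio > 5))
})

test_that("cohorts encode the planted recurrence asymmetry", {
  wins <- 0L
  for (s in 1:20) {
    study <- simulate_study(generator_params(rng_seed = 700 + s,
                                             n_genes = 400,
                                             module_size = 20,
                                             n_ndd_genes = 80))
    drv_keys <- paste(study$driver_list$gene,
                      study$driver_list$protein_change, sep = ":")
    f_drv <- mutation_frequency(study$catalog_b, drv_keys)
    f_ndd <- mutation_frequency(study$catalog_a,
                                study$catalog_a$unique_mutations)
    if (mean(10^f_drv - 1) > mean(10^f_ndd - 1)) wins <- wins + 1L
    # shared-mutation construction is exact
    n_expected <- round(study$params$shared_fraction *
                          length(study$catalog_a$unique_mutations))
    expect_equal(length(study$truth$shared_mutations), n_expected)
    expect_true(all(study$truth$shared_mutations %in%
                      study$catalog_b$unique_mutations))
  }
  expect_equal(binom.test(wins, 20, alternative = "greater")$p.value < 0.01,
               TRUE)
})

test_that("recurrence-based seed selection recovers the planted driver genes", {
  recovered <- vapply(1:10, function(s) {
    study <- simulate_study(generator_params(rng_seed = 800 + s))
    seeds <- select_seed_genes(study$catalog_b, 3)
    mean(unique(study$driver_list$gene) %in% seeds)
  }, numeric(1))
  expect_gte(mean(recovered), 0.8)
})

test_that("planted TF targets its pathway at the constructed fraction", {
  for (s in 1:5) {
    study <- simulate_study(generator_params(rng_seed = 900 + s))
    tf <- study$truth$planted_tf
    targets <- study$reg$pairs$target[study$reg$pairs$tf == tf]
    expect_equal(length(targets), study$params$planted_tf_targets)
    expect_gte(mean(targets %in%
                      study$pathways[[study$truth$planted_pathway]]),
               study$params$planted_target_frac)
    expect_false(anyDuplicated(study$reg$pairs) > 0)
  }
})

test_that("unshifted expression matches the half-normal mean", {
  es <- vapply(1:10, function(s) {
    params <- generator_params(rng_seed = 1100 + s, strong_shift = 0,
                               weak_shift = 0,
                               pathway_size_range = c(80, 80))
    study <- simulate_study(params)
    pw <- study$pathways[[study$truth$planted_pathway]]
    expression_score(pw, study$z_table["CANCER", ])$es
  }, numeric(1))
  # E|N(0,1)| = sqrt(2/pi) = 0.7979
  expect_equal(mean(es), sqrt(2 / pi), tolerance = 0.05)
})

test_that("strong shifts score higher than weak shifts on the planted pathway", {
  wins <- 0L
  for (s in 1:20) {
    study <- simulate_study(generator_params(rng_seed = 1000 + s))
    pw <- study$pathways[[study$truth$planted_pathway]]
    es_strong <- expression_score(pw, study$z_table["CANCER", ])$es
    es_weak <- expression_score(pw, study$z_table["NDD", ])$es
    if (es_strong > es_weak) wins <- wins + 1L
  }
  expect_gte(wins, 19)
})

test_that("written files round-trip through the pipeline parsers", {
  study <- simulate_study(generator_params(rng_seed = 4, n_genes = 300,
                                           module_size = 15,
                                           n_ndd_genes = 50))
  dir <- withr::local_tempdir()
  paths <- write_synthetic_study(study, dir)
  expect_true(all(file.exists(paths)))

  cat_a <- parse_catalog(paths["catalog_a"], "NDD")
  expect_equal(cat_a$unique_mutations, study$catalog_a$unique_mutations)
  expect_equal(nrow(cat_a$records), nrow(study$catalog_a$records))

  g <- read_interactome(paths["interactome"])
  expect_equal(igraph::ecount(g), igraph::ecount(study$interactome))
  expect_equal(sort(igraph::V(g)$name),
               sort(igraph::V(study$interactome)$name))

  reg <- read_regulatory_map(paths["reg"])
  expect_equal(reg$pairs, study$reg$pairs)

  pw <- read_gmt(paths["pathways"])
  expect_equal(unclass(pw)[order(names(pw))],
               unclass(study$pathways)[order(names(study$pathways))],
               ignore_attr = TRUE)

  z <- read_expression_table(paths["expression"])
  shared_genes <- intersect(colnames(z), colnames(study$z_table))
  expect_equal(z["NDD", shared_genes], study$z_table["NDD", shared_genes])

  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$planted_module, study$truth$planted_module)
  expect_equal(truth$planted_tf, study$truth$planted_tf)
})
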