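# Expression score, propensity score, TF-profile clustering.

test_that("expression score is the mean absolute z over measured genes", {
  z <- c(a = 1, b = -1, c = 2)
  res <- expression_score(c("a", "b", "c"), z)
  expect_equal(res$es, 4 / 3)
  expect_equal(res$n_scored, 3)

  expect_equal(expression_score(c("a", "b", "c"),
                                c(a = 0, b = 0, c = 0))$es, 0)

  # missing genes drop out of numerator and denominator
  part <- expression_score(c("a", "b", "c"), c(a = 2, b = -2))
  expect_equal(part$es, 2)
  expect_equal(part$n_scored, 2)
  # pathway-size denominator mode
  full <- expression_score(c("a", "b", "c"), c(a = 2, b = -2),
                           denominator = "pathway")
  expect_equal(full$es, 4 / 3)

  none <- expression_score(c("x", "y"), c(a = 1))
  expect_true(is.na(none$es))
  expect_error(expression_score(character(0), z),
               class = "cohortnet_config_error")
})

test_that("expression score is invariant to sign flips and gene order", {
  set.seed(3)
  z <- setNames(rnorm(10), letters[1:10])
  genes <- letters[1:6]
  base <- expression_score(genes, z)$es
  expect_equal(expression_score(rev(genes), z)$es, base)
  flip <- z; flip[2] <- -flip[2]; flip[5] <- -flip[5]
  expect_equal(expression_score(genes, flip)$es, base)
})

test_that("propensity score is unique mutations over pathway size", {
  cat_x <- toy_catalog(list(
    c("s1", "G1", "A1C"), c("s2", "G1", "A1C"),  # same mutation twice
    c("s1", "G1", "D2E"), c("s3", "G1", "F3G"),
    c("s1", "G2", "H4I")))
  # G1 has 3 unique, G2 has 1, G3/G4 none -> PS = 4/4 = 1
  expect_equal(propensity_score(c("G1", "G2", "G3", "G4"), cat_x), 1.0)
  expect_equal(propensity_score(c("G7", "G8"), cat_x), 0)
  # unscored gene joins the denominator only
  expect_equal(propensity_score(c("G1", "G2", "G3", "G4", "G5"), cat_x),
               4 / 5)
  expect_error(propensity_score(character(0), cat_x),
               class = "cohortnet_config_error")
})

test_that("propensity equals a brute-force scan on synthetic data", {
  study <- simulate_study(generator_params(rng_seed = 9, n_genes = 300,
                                           module_size = 15,
                                           n_ndd_genes = 50))
  cat_b <- study$catalog_b
  set.seed(9)
  pw <- sample(gene_names <- colnames(study$z_table), 30)
  got <- propensity_score(pw, cat_b)
  want <- sum(vapply(pw, function(g)
    length(unique(cat_b$records$protein_change[cat_b$records$gene == g])),
    numeric(1))) / length(pw)
  expect_equal(got, want)
})

test_that("panel scoring crosses pathways and diseases deterministically", {
  z <- expression_table(rep(c("D1", "D2", "D3"), each = 2),
                        rep(c("a", "b"), 3), c(1, 2, 0, 0, -3, 1))
  pw <- list(p1 = c("a", "b"), p2 = c("a", "zz"))
  panel <- score_pathway_panel(pw, z)
  expect_equal(nrow(panel), 6)
  expect_equal(panel$pathway_id, rep(c("p1", "p2"), each = 3))
  expect_true(all(is.na(panel$propensity_score)))
  expect_equal(panel$expression_score[panel$pathway_id == "p1" &
                                        panel$disease == "D1"], 1.5)
  # a catalog for one disease only
  cat1 <- toy_catalog(list(c("s1", "A", "A1C")))
  panel2 <- score_pathway_panel(pw, z, catalogs = list(D1 = cat1))
  expect_equal(panel2$propensity_score[panel2$disease == "D1" &
                                         panel2$pathway_id == "p1"], 0.5)
  expect_true(all(is.na(panel2$propensity_score[panel2$disease != "D1"])))
})

test_that("well-separated profile blobs cluster purely", {
  set.seed(8)
  m <- rbind(matrix(rnorm(12, 3, 0.2), 6, 2),
             matrix(rnorm(12, -3, 0.2), 6, 2))
  rownames(m) <- paste0("TF", 1:12)
  colnames(m) <- c("D1", "D2")
  cl <- cluster_tf_profiles(m, k = 2)
  expect_equal(length(unique(cl$assignment[1:6])), 1)
  expect_equal(length(unique(cl$assignment[7:12])), 1)
  expect_false(cl$assignment[1] == cl$assignment[7])

  one <- cluster_tf_profiles(m, k = 1)
  expect_equal(unname(unique(one$assignment)), 1)
  expect_error(cluster_tf_profiles(m[1:2, ], k = 3),
               class = "cohortnet_insufficient_data")
})

test_that("clustering agrees with a naive average-linkage implementation", {
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(rnorm(30), 10, 3,
                dimnames = list(paste0("TF", 1:10), paste0("D", 1:3)))
    for (k in 2:4) {
      got <- cluster_tf_profiles(m, k = k)$assignment
      want <- naive_average_linkage(m, k)
      expect_equal(canonical_partition(got), canonical_partition(want))
    }
  }
})

test_that("incomplete profiles are excluded before clustering", {
  m <- matrix(rnorm(20), 10, 2,
              dimnames = list(paste0("TF", 1:10), c("D1", "D2")))
  m[3, 1] <- NA
  cl <- cluster_tf_profiles(m, k = 2)
  expect_equal(cl$n_incomplete, 1)
  expect_false("TF3" %in% names(cl$assignment))
})

test_that("differential TF selection thresholds on the z gap", {
  m <- rbind(TF1 = c(ASD = 2, C1 = 0, C2 = 1.5),
             TF2 = c(ASD = 1, C1 = 1, C2 = 1),
             TF3 = c(ASD = 0, C1 = NA, C2 = 0.5))
  expect_equal(select_differential_tfs(m, "ASD", delta = 1), "TF1")
  expect_setequal(select_differential_tfs(m, "ASD", delta = 0),
                  c("TF1", "TF2", "TF3"))
  expect_length(select_differential_tfs(m[2, , drop = FALSE], "ASD",
                                        delta = 1), 0)
  expect_error(select_differential_tfs(m, "NOPE"),
               class = "cohortnet_config_error")
})
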