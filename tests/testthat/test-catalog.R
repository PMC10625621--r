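# Catalog parsing, frequencies, seed selection, per-residue profiles.

test_that("parsing drops non-point changes only when asked and collapses duplicates", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgene\tprotein_change",
               "s1\tPTEN\tp.R130Q",
               "s2\tPTEN\tp.?",
               "s3\tTP53\tR175H",
               "s3\tTP53\tR175H"), tf)
  cat_point <- parse_catalog(tf, "x", point_only = TRUE)
  expect_equal(nrow(cat_point$records), 2)
  expect_equal(cat_point$parse_report$n_dropped_nonpoint, 1)
  expect_equal(cat_point$parse_report$n_collapsed_duplicates, 1)
  expect_true(all(cat_point$records$protein_change %in%
                    c("R130Q", "R175H")))

  cat_all <- parse_catalog(tf, "x", point_only = FALSE)
  expect_equal(nrow(cat_all$records), 3)

  writeLines("sample_id\tgene\tprotein_change", tf)
  expect_error(parse_catalog(tf, "x"), class = "cohortnet_empty_catalog")
  writeLines(c("sample\tgene\tchange", "a\tb\tC1D"), tf)
  expect_error(parse_catalog(tf, "x"), class = "cohortnet_config_error")
})

test_that("mutation frequency is log10(patients + 1), counting distinct carriers", {
  rows <- c(lapply(1:9, function(i) c(paste0("s", i), "G1", "A5T")),
            list(c("s1", "G1", "A5T")),  # duplicate carrier row
            list(c("s1", "G2", "C7G")))
  cat_x <- toy_catalog(rows)
  expect_equal(mutation_frequency(cat_x, "G1:A5T"), 1.0) # 9 carriers
  expect_equal(mutation_frequency(cat_x, "G3:R1K"), 0.0) # absent
  n99 <- toy_catalog(lapply(1:99, function(i) c(paste0("s", i), "G", "A1C")))
  expect_equal(mutation_frequency(n99, "G:A1C"), 2.0)
})

test_that("frequency is monotone in carrier count and zero iff absent", {
  set.seed(7)
  for (n in c(0, 1, 5, 30)) {
    rows <- if (n == 0) list(c("s0", "OTHER", "A1C")) else
      lapply(seq_len(n), function(i) c(paste0("s", i), "G", "A1C"))
    f <- mutation_frequency(toy_catalog(rows), "G:A1C")
    expect_equal(f, log10(n + 1))
  }
})

test_that("seed selection is inclusive at the threshold and order-invariant", {
  rows <- c(lapply(1:3, function(i) c(paste0("s", i), "REC3", "A1C")),
            lapply(1:2, function(i) c(paste0("s", i), "REC2", "C2D")),
            lapply(1:5, function(i) c(paste0("s", i), "REC5", "E3F")))
  cat_x <- toy_catalog(rows)
  expect_equal(select_seed_genes(cat_x, 3), c("REC5", "REC3"))
  expect_equal(select_seed_genes(cat_x, 1), c("REC5", "REC3", "REC2"))
  set.seed(1)
  shuffled <- cat_x
  shuffled$records <- cat_x$records[sample(nrow(cat_x$records)), ]
  expect_equal(select_seed_genes(shuffled, 3), select_seed_genes(cat_x, 3))
})

test_that("gene-class summary counts marginals and combinations", {
  ann <- data.frame(gene = c("A", "B", "D"),
                    is_tf = c(TRUE, FALSE, TRUE),
                    is_tsg = c(FALSE, TRUE, FALSE),
                    is_oncogene = c(FALSE, FALSE, TRUE))
  cat_x <- toy_catalog(list(c("s1", "A", "A1C"), c("s1", "B", "C2D"),
                            c("s2", "C", "E3F"), c("s2", "D", "G4H")))
  res <- annotate_gene_classes(cat_x, ann)
  expect_equal(unname(res$marginal["tf"]), 2)       # A and D
  expect_equal(unname(res$marginal["tsg"]), 1)
  expect_equal(unname(res$marginal["oncogene"]), 1) # D
  expect_equal(unname(res$marginal["none"]), 1)     # C
  expect_true("TF+OG" %in% res$combinations$classes)
})

test_that("phenotype network connects phenotypes sharing mutated genes", {
  df <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    gene = c("A", "B", "B", "C"),
    protein_change = c("A1C", "C2D", "C2D", "E3F"),
    phenotype = c("P1", "P1", "P2", "P3"),
    stringsAsFactors = FALSE)
  net <- phenotype_overlap_network(mutation_catalog(df, "x"))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$shared_genes, 1)
  expect_setequal(c(net$edges$phenotype_a, net$edges$phenotype_b),
                  c("P1", "P2"))
  expect_equal(net$nodes$n_samples[net$nodes$phenotype == "P1"], 2)
  expect_equal(net$nodes$n_mutated_genes[net$nodes$phenotype == "P1"], 2)
})

test_that("residue profile matches the worked hotspot example", {
  a <- toy_catalog(list(c("s1", "PTEN", "R130*"), c("s2", "PTEN", "R130*")))
  b <- toy_catalog(c(list(c("t1", "PTEN", "R130*")),
                     lapply(1:5, function(i)
                       c(paste0("t", i + 1), "PTEN", "R130Q"))))
  prof <- residue_profile(a, b, "PTEN")
  expect_equal(nrow(prof), 2)
  star <- prof[prof$alt == "*", ]
  expect_equal(c(star$n_a, star$n_b), c(2, 1))
  expect_true(star$shared)
  q <- prof[prof$alt == "Q", ]
  expect_equal(c(q$n_a, q$n_b), c(0, 5))
  expect_false(q$shared)
  expect_warning(residue_profile(a, b, "ABSENT"), "absent")
})

test_that("residue profile equals a brute-force record scan on synthetic catalogs", {
  study <- simulate_study(generator_params(rng_seed = 3, n_genes = 300,
                                           n_ndd_genes = 60,
                                           module_size = 20))
  a <- study$catalog_a; b <- study$catalog_b
  genes <- union(a$mutated_genes, b$mutated_genes)
  for (gene in sample(genes, 15)) {
    prof <- suppressWarnings(residue_profile(a, b, gene))
    for (i in seq_len(nrow(prof))) {
      ch <- paste0(prof$ref[i], prof$position[i], prof$alt[i])
      na <- length(unique(a$records$sample_id[
        a$records$gene == gene & a$records$protein_change == ch]))
      nb <- length(unique(b$records$sample_id[
        b$records$gene == gene & b$records$protein_change == ch]))
      expect_equal(prof$n_a[i], na)
      expect_equal(prof$n_b[i], nb)
    }
  }
})
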