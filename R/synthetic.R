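# Synthetic study generator: every pipeline input with planted ground
# truth, so recovery of the truth can be measured end-to-end.

#' Parameters of the synthetic study generator
#'
#' Defaults encode the qualitative asymmetries the pipeline is built to
#' detect: a cancer-like cohort whose driver mutations recur in many
#' patients (zero-truncated negative binomial, mean 20 carriers) versus an
#' NDD-like cohort of rare mutations (mean 2 carriers) with a small shared
#' set; a scale-free interactome with a dense planted module around the
#' driver genes; a regulatory map whose planted TF targets one pathway; and
#' expression z-scores with a strong pathway shift in the cancer-like
#' disease (delta 2.0) against a weak shift in the NDD-like disease
#' (delta 0.5) over unit-variance noise.
#'
#' @param n_genes gene-universe size.
#' @param pa_edges preferential-attachment edges added per backbone node.
#' @param module_size planted-module size.
#' @param module_density intra-module edge probability.
#' @param n_samples_a,n_samples_b cohort sizes (NDD-like, cancer-like).
#' @param n_driver_genes,n_ndd_genes mutated-gene counts per cohort.
#' @param driver_module_frac,ndd_module_frac fraction of each cohort's
#'   mutated genes drawn from the planted module.
#' @param driver_mean_carriers,ndd_mean_carriers means of the
#'   zero-truncated negative binomial carrier-count laws.
#' @param carrier_dispersion negative-binomial size parameter.
#' @param muts_per_gene_max max unique mutations per mutated gene.
#' @param shared_fraction fraction of NDD unique mutations copied into the
#'   cancer catalog (at NDD-like carrier counts).
#' @param n_pathways,pathway_size_range pathway collection shape.
#' @param n_tfs background TF count; `tf_targets_range` targets per TF.
#' @param planted_tf_targets target count of the planted TF;
#'   `planted_target_frac` of them drawn from the planted pathway.
#' @param strong_shift,weak_shift,noise_sd expression effect sizes (z
#'   units) and baseline noise.
#' @param missing_frac fraction of genes unmeasured per disease.
#' @param rng_seed master seed; every output is a pure function of the
#'   parameters and this seed.
#' @return a list of class `generator_params`.
#' @export
generator_params <- function(n_genes = 2000, pa_edges = 3,
                             module_size = 40, module_density = 0.3,
                             n_samples_a = 500, n_samples_b = 500,
                             n_driver_genes = 25, n_ndd_genes = 300,
                             driver_module_frac = 0.8,
                             ndd_module_frac = 0.1,
                             driver_mean_carriers = 20,
                             ndd_mean_carriers = 2,
                             carrier_dispersion = 2,
                             muts_per_gene_max = 3,
                             shared_fraction = 0.02,
                             n_pathways = 50,
                             pathway_size_range = c(20, 80),
                             n_tfs = 40, tf_targets_range = c(10, 30),
                             planted_tf_targets = 30,
                             planted_target_frac = 0.7,
                             strong_shift = 2.0, weak_shift = 0.5,
                             noise_sd = 1.0, missing_frac = 0.1,
                             rng_seed = 1) {
  p <- as.list(environment())
  stopifnot(p$n_genes >= p$module_size, p$shared_fraction >= 0,
            p$shared_fraction <= 1, p$driver_mean_carriers > 0,
            p$ndd_mean_carriers > 0, p$noise_sd > 0)
  structure(p, class = "generator_params")
}

gene_universe <- function(params)
  sprintf("G%04d", seq_len(params$n_genes))

# zero-truncated negative binomial via rejection; mean is of the
# untruncated law
rztnbinom <- function(n, mu, size) {
  x <- stats::rnbinom(n, size = size, mu = mu)
  while (any(x == 0))
    x[x == 0] <- stats::rnbinom(sum(x == 0), size = size, mu = mu)
  x
}

random_protein_change <- function(n) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  ref <- sample(aa, n, replace = TRUE)
  pos <- sample(30:900, n, replace = TRUE)
  alt <- ifelse(runif(n) < 0.05, "*", sample(aa, n, replace = TRUE))
  # avoid synonymous-looking strings
  fix <- alt == ref
  alt[fix] <- "*"
  paste0(ref, pos, alt)
}

#' Generate a synthetic weighted interactome with a planted module
#'
#' Scale-free (preferential attachment) backbone over the gene universe
#' with a dense planted module wired at `module_density`, edge confidences
#' drawn from Beta(5, 2) so they lie in (0, 1].
#'
#' @param params a [generator_params()] list.
#' @return list with `graph` (weighted `igraph`) and `truth` (list with
#'   `planted_module`, `rng_seed`).
#' @export
generate_interactome <- function(params = generator_params()) {
  set.seed(child_seed(params$rng_seed, 1))
  genes <- gene_universe(params)
  g <- igraph::sample_pa(params$n_genes, m = params$pa_edges,
                         directed = FALSE)
  igraph::V(g)$name <- genes
  module <- sort(sample(genes, params$module_size))
  pairs <- t(combn(module, 2))
  add <- runif(nrow(pairs)) < params$module_density
  if (any(add))
    g <- igraph::add_edges(g, t(pairs[add, , drop = FALSE]))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::E(g)$weight <- rbeta(igraph::ecount(g), 5, 2)
  truth <- list(planted_module = module, rng_seed = params$rng_seed)
  list(graph = g, truth = truth)
}

#' Generate paired synthetic mutation cohorts
#'
#' Builds an NDD-like catalog (many genes, low recurrence) and a
#' cancer-like catalog whose driver mutations concentrate in the planted
#' module at high recurrence. A `shared_fraction` of NDD unique mutations
#' is copied into the cancer catalog at NDD-like (low) carrier counts, so
#' shared mutations are rare in the cancer cohort. NDD samples carry one of
#' four phenotype labels; pathogenicity scores are drawn high for driver
#' records and moderate for NDD records.
#'
#' @param params a [generator_params()] list.
#' @param truth truth list from [generate_interactome()].
#' @return list with `catalog_a` (NDD-like), `catalog_b` (cancer-like),
#'   `driver_list` (data frame gene/protein_change) and updated `truth`
#'   (adds `driver_genes`, `ndd_genes`, `shared_mutations`).
#' @export
generate_cohorts <- function(params, truth) {
  set.seed(child_seed(params$rng_seed, 2))
  genes <- gene_universe(params)
  module <- truth$planted_module
  pick_genes <- function(n, frac_module) {
    n_mod <- min(round(n * frac_module), length(module))
    c(sample(module, n_mod), sample(setdiff(genes, module), n - n_mod))
  }
  driver_genes <- sort(pick_genes(params$n_driver_genes,
                                  params$driver_module_frac))
  ndd_genes <- sort(pick_genes(params$n_ndd_genes, params$ndd_module_frac))

  make_mutations <- function(gs) {
    counts <- sample(seq_len(params$muts_per_gene_max), length(gs),
                     replace = TRUE)
    data.frame(gene = rep(gs, counts),
               protein_change = random_protein_change(sum(counts)),
               stringsAsFactors = FALSE)
  }
  expand_records <- function(muts, carriers, sample_pool) {
    idx <- rep(seq_len(nrow(muts)), carriers)
    data.frame(
      sample_id = unlist(lapply(carriers, function(k)
        sample(sample_pool, min(k, length(sample_pool))))),
      gene = muts$gene[idx], protein_change = muts$protein_change[idx],
      stringsAsFactors = FALSE)
  }
  samples_a <- sprintf("NDD_S%04d", seq_len(params$n_samples_a))
  samples_b <- sprintf("CAN_S%04d", seq_len(params$n_samples_b))

  ndd_muts <- unique(make_mutations(ndd_genes))
  ndd_carriers <- pmin(rztnbinom(nrow(ndd_muts), params$ndd_mean_carriers,
                                 params$carrier_dispersion),
                       params$n_samples_a)
  rec_a <- expand_records(ndd_muts, ndd_carriers, samples_a)
  phen <- c("ASD", "DD", "ID", "EPI")
  phen_of <- setNames(sample(phen, params$n_samples_a, replace = TRUE),
                      samples_a)
  rec_a$phenotype <- unname(phen_of[rec_a$sample_id])
  rec_a$pathogenicity <- round(rbeta(nrow(rec_a), 4, 4), 4)

  driver_muts <- unique(make_mutations(driver_genes))
  driver_carriers <- pmin(rztnbinom(nrow(driver_muts),
                                    params$driver_mean_carriers,
                                    params$carrier_dispersion),
                          params$n_samples_b)
  rec_b <- expand_records(driver_muts, driver_carriers, samples_b)
  rec_b$pathogenicity <- round(rbeta(nrow(rec_b), 8, 2), 4)

  n_shared <- round(params$shared_fraction * nrow(ndd_muts))
  shared <- ndd_muts[sample(nrow(ndd_muts), n_shared), , drop = FALSE]
  if (n_shared > 0) {
    shared_carriers <- pmin(rztnbinom(n_shared, params$ndd_mean_carriers,
                                      params$carrier_dispersion),
                            params$n_samples_b)
    rec_s <- expand_records(shared, shared_carriers, samples_b)
    rec_s$pathogenicity <- round(rbeta(nrow(rec_s), 4, 4), 4)
    rec_b <- rbind(rec_b, rec_s)
  }

  catalog_a <- mutation_catalog(rec_a, "NDD", point_only = TRUE)
  catalog_b <- mutation_catalog(rec_b, "CANCER", point_only = TRUE)
  truth$driver_genes <- driver_genes
  truth$ndd_genes <- ndd_genes
  truth$shared_mutations <-
    sort(paste(shared$gene, shared$protein_change, sep = ":"))
  list(catalog_a = catalog_a, catalog_b = catalog_b,
       driver_list = driver_muts[order(driver_muts$gene,
                                       driver_muts$protein_change), ],
       truth = truth)
}

#' Generate a synthetic regulatory map and pathway collection
#'
#' Pathways are overlapping random gene sets; one planted pathway receives
#' the planted TF, whose targets are drawn at least `planted_target_frac`
#' from that pathway. Background TFs (drawn partly from the planted module
#' so they surface in inferred networks) target uniform random genes.
#'
#' @param params a [generator_params()] list.
#' @param truth truth list from [generate_cohorts()].
#' @return list with `reg` (a `regulatory_map`), `pathways` (named list of
#'   gene sets) and updated `truth` (adds `planted_pathway`,
#'   `planted_tf`).
#' @export
generate_regulation_and_pathways <- function(params, truth) {
  set.seed(child_seed(params$rng_seed, 3))
  genes <- gene_universe(params)
  module <- truth$planted_module
  sizes <- sample(params$pathway_size_range[1]:params$pathway_size_range[2],
                  params$n_pathways, replace = TRUE)
  # the planted pathway must be able to host the planted TF's targets
  n_in <- ceiling(params$planted_target_frac * params$planted_tf_targets)
  sizes[1] <- min(max(sizes[1], n_in + 5), params$n_genes)
  pathways <- lapply(sizes, function(k) sort(sample(genes, k)))
  names(pathways) <- sprintf("PW%03d", seq_len(params$n_pathways))
  planted_pathway <- "PW001"

  n_mod_tf <- min(10, length(module))
  tf_pool <- c(sample(module, n_mod_tf),
               sample(setdiff(genes, module), params$n_tfs - n_mod_tf))
  planted_tf <- sample(module, 1)
  tf_pool <- setdiff(tf_pool, planted_tf)

  lo <- params$tf_targets_range[1]; hi <- params$tf_targets_range[2]
  pairs <- do.call(rbind, lapply(tf_pool, function(tf) {
    k <- sample(lo:hi, 1)
    data.frame(tf = tf, target = sample(setdiff(genes, tf), k),
               stringsAsFactors = FALSE)
  }))
  in_path <- sample(setdiff(pathways[[planted_pathway]], planted_tf), n_in)
  out_path <- sample(setdiff(genes, c(pathways[[planted_pathway]],
                                      planted_tf)),
                     params$planted_tf_targets - n_in)
  pairs <- rbind(pairs, data.frame(tf = planted_tf,
                                   target = c(in_path, out_path),
                                   stringsAsFactors = FALSE))
  reg <- regulatory_map(pairs$tf, pairs$target)
  truth$planted_pathway <- planted_pathway
  truth$planted_tf <- planted_tf
  list(reg = reg, pathways = structure(pathways,
                                       class = "gene_set_collection"),
       truth = truth)
}

#' Generate synthetic expression z-scores with planted pathway shifts
#'
#' Two diseases share a standard-normal baseline (sd `noise_sd`); genes of
#' the planted pathway are shifted by the disease's delta with a random
#' sign per gene — the cancer-like disease gets `strong_shift`, the
#' NDD-like disease `weak_shift` — so mean |z| of the planted pathway
#' separates the two. A `missing_frac` of genes per disease is unmeasured.
#'
#' @param params a [generator_params()] list.
#' @param truth truth list from [generate_regulation_and_pathways()].
#' @param pathways the pathway collection holding the planted pathway.
#' @return list with `z_table` (disease x gene matrix, rows `"NDD"` and
#'   `"CANCER"`) and updated `truth` (adds `shift_by_disease`).
#' @export
generate_expression <- function(params, truth, pathways) {
  set.seed(child_seed(params$rng_seed, 4))
  genes <- gene_universe(params)
  planted <- pathways[[truth$planted_pathway]]
  shifts <- c(NDD = params$weak_shift, CANCER = params$strong_shift)
  z <- matrix(rnorm(2 * length(genes), 0, params$noise_sd), nrow = 2,
              dimnames = list(names(shifts), genes))
  for (d in names(shifts)) {
    sgn <- sample(c(-1, 1), length(planted), replace = TRUE)
    z[d, planted] <- z[d, planted] + sgn * shifts[[d]]
    z[d, sample(length(genes), round(params$missing_frac *
                                       length(genes)))] <- NA_real_
  }
  truth$shift_by_disease <- as.list(shifts)
  list(z_table = z, truth = truth)
}

#' Generate a complete synthetic study
#'
#' Runs all four generators in sequence and returns every pipeline input
#' plus the ground-truth manifest.
#'
#' @param params a [generator_params()] list.
#' @return list with `interactome`, `catalog_a`, `catalog_b`,
#'   `driver_list`, `reg`, `pathways`, `z_table`, `truth`, `params`.
#' @export
simulate_study <- function(params = generator_params()) {
  ia <- generate_interactome(params)
  co <- generate_cohorts(params, ia$truth)
  rp <- generate_regulation_and_pathways(params, co$truth)
  ex <- generate_expression(params, rp$truth, rp$pathways)
  list(interactome = ia$graph, catalog_a = co$catalog_a,
       catalog_b = co$catalog_b, driver_list = co$driver_list,
       reg = rp$reg, pathways = rp$pathways, z_table = ex$z_table,
       truth = ex$truth, params = params)
}

#' Write a synthetic study to disk in the pipeline's input dialects
#'
#' Emits `catalog_ndd.tsv`, `catalog_cancer.tsv`, `driver_list.tsv`,
#' `interactome.tsv` (edge list), `regulatory_map.tsv` (TF/target),
#' `pathways.gmt`, `expression_z.tsv` (long format) and `truth.json`.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if absent).
#' @return named character vector of written paths, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(catalog_a = file.path(dir, "catalog_ndd.tsv"),
             catalog_b = file.path(dir, "catalog_cancer.tsv"),
             driver_list = file.path(dir, "driver_list.tsv"),
             interactome = file.path(dir, "interactome.tsv"),
             reg = file.path(dir, "regulatory_map.tsv"),
             pathways = file.path(dir, "pathways.gmt"),
             expression = file.path(dir, "expression_z.tsv"),
             truth = file.path(dir, "truth.json"))
  write_tsv(study$catalog_a$records, paths["catalog_a"])
  write_tsv(study$catalog_b$records, paths["catalog_b"])
  write_tsv(study$driver_list, paths["driver_list"])
  el <- igraph::as_edgelist(study$interactome)
  write_tsv(data.frame(node_a = el[, 1], node_b = el[, 2],
                       weight = igraph::E(study$interactome)$weight),
            paths["interactome"])
  write_tsv(setNames(study$reg$pairs, c("tf", "target")), paths["reg"])
  write_gmt(study$pathways, paths["pathways"])
  zl <- expand.grid(disease = rownames(study$z_table),
                    gene = colnames(study$z_table),
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  zl$z <- study$z_table[cbind(zl$disease, zl$gene)]
  zl <- zl[!is.na(zl$z), , drop = FALSE]
  zl <- zl[order(zl$disease, zl$gene), , drop = FALSE]
  write_tsv(zl, paths["expression"])
  jsonlite::write_json(study$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
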