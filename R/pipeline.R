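# Config-driven orchestration: catalogs -> seeds -> networks -> common
# regulation -> ORA -> pathway panel -> TF clusters, with a manifest.

#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()]: input paths
#' (all required unless noted), inference parameters, thresholds, and the
#' run seed. Unknown keys in a user configuration are rejected.
#'
#' @param ... overrides of the defaults, as `key = value`.
#' @return a named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    catalog_a = NULL, catalog_b = NULL, driver_list = NULL,
    interactome = NULL, regulatory_map = NULL, pathways = NULL,
    expression = NULL, out_dir = "cohortnet_run",
    cohort_a_name = "NDD", cohort_b_name = "CANCER",
    min_patients = 3, use_driver_seeds_b = TRUE,
    alpha = 0.5, tau = 0.8, edge_cap = 2000, n_rewires = 100,
    z_threshold = 1.65, max_per_seed = 50000,
    p_cut = 0.05, fdr_cut = 0.05, delta = 1.0, k_clusters = 3,
    reference_disease = NULL, rng_seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop_cohortnet(paste0("unknown config key(s): ",
                          paste(unknown, collapse = ", ")),
                   "cohortnet_config_error")
  structure(modifyList(cfg, over), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file of `key: value` pairs (keys as in
#'   [default_config()]).
#' @return a `run_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

stage_log <- function(log, stage, t0, ...) {
  entry <- c(list(stage = stage,
                  wall_time_s = round(as.numeric(Sys.time()) - t0, 3)),
             list(...))
  message(sprintf("[%s] done in %.2fs", stage, entry$wall_time_s))
  c(log, list(entry))
}

#' Run the full comparison pipeline
#'
#' Stage order: parse catalogs; seed selection for both cohorts; network
#' inference for both; common TF/target identification; overrepresentation
#' analysis of the common targets; expression/propensity scoring of the
#' significant pathways; TF-profile clustering and differential-TF
#' selection. Every stage's output is written under `out_dir` with fixed
#' names, and `manifest.json` records input hashes, parameters, package
#' version and per-stage wall time. A stage failure aborts with the stage
#' name and leaves a `FAILED` marker file.
#'
#' @param config a `run_config` from [default_config()] or
#'   [read_config()].
#' @return list of in-memory stage results (invisibly also written to
#'   `out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  log <- list()
  res <- list(config = cfg)
  on.exit({
    if (!identical(stage, "done")) {
      writeLines(paste("failed at stage:", stage),
                 file.path(out, "FAILED"))
    }
  })
  run_stage <- function(name, expr) {
    stage <<- name
    t0 <- as.numeric(Sys.time())
    val <- tryCatch(expr, error = function(e)
      stop_cohortnet(paste0("stage '", name, "' failed: ",
                            conditionMessage(e)),
                     "cohortnet_stage_error"))
    log <<- stage_log(log, name, t0)
    val
  }

  inputs <- c(catalog_a = cfg$catalog_a, catalog_b = cfg$catalog_b,
              driver_list = cfg$driver_list, interactome = cfg$interactome,
              regulatory_map = cfg$regulatory_map, pathways = cfg$pathways,
              expression = cfg$expression)
  missing_in <- inputs[!file.exists(unlist(inputs))]
  if (length(missing_in) > 0)
    stop_cohortnet(paste0("missing input file(s): ",
                          paste(missing_in, collapse = ", ")),
                   "cohortnet_config_error")
  params <- inference_params(alpha = cfg$alpha, tau = cfg$tau,
                             edge_cap = cfg$edge_cap,
                             n_rewires = cfg$n_rewires,
                             z_threshold = cfg$z_threshold,
                             max_per_seed = cfg$max_per_seed)

  parsed <- run_stage("parse_inputs", {
    list(cat_a = parse_catalog(cfg$catalog_a, cfg$cohort_a_name),
         cat_b = parse_catalog(cfg$catalog_b, cfg$cohort_b_name),
         g = read_interactome(cfg$interactome),
         reg = read_regulatory_map(cfg$regulatory_map),
         pathways = read_gmt(cfg$pathways),
         z = read_expression_table(cfg$expression),
         drivers = if (!is.null(cfg$driver_list))
           read.delim(cfg$driver_list, stringsAsFactors = FALSE) else NULL)
  })

  seeds <- run_stage("seed_selection", {
    sa <- select_seed_genes(parsed$cat_a, cfg$min_patients)
    sb <- if (cfg$use_driver_seeds_b && !is.null(parsed$drivers))
      sort(unique(toupper(parsed$drivers$gene)))
    else select_seed_genes(parsed$cat_b, cfg$min_patients)
    writeLines(sa, file.path(out, "seeds_a.txt"))
    writeLines(sb, file.path(out, "seeds_b.txt"))
    list(a = sa, b = sb)
  })

  net_a <- run_stage("network_a", {
    n <- infer_disease_network(parsed$g, seeds$a, params,
                               rng_seed = child_seed(cfg$rng_seed, 11))
    write_disease_network(n, file.path(out, "network_a"))
    n
  })
  net_b <- run_stage("network_b", {
    n <- infer_disease_network(parsed$g, seeds$b, params,
                               rng_seed = child_seed(cfg$rng_seed, 12))
    write_disease_network(n, file.path(out, "network_b"))
    n
  })

  comparison <- run_stage("compare_mutations", {
    cmp <- compare_catalogs(parsed$cat_a, parsed$cat_b,
                            frequency_source = parsed$cat_b)
    write_tsv(summary(cmp), file.path(out, "comparison.tsv"))
    cmp
  })

  reg_common <- run_stage("common_regulation", {
    cr <- common_regulation(net_a, net_b, parsed$reg)
    writeLines(cr$common_tfs, file.path(out, "common_tfs.txt"))
    writeLines(cr$common_targets, file.path(out, "common_targets.txt"))
    cr
  })

  enrichment <- run_stage("enrichment", {
    if (length(reg_common$common_targets) == 0)
      stop("no common targets to test")
    en <- ora_enrich(reg_common$common_targets, parsed$pathways,
                     p_cut = cfg$p_cut, fdr_cut = cfg$fdr_cut)
    write_tsv(en$table, file.path(out, "enrichment.tsv"))
    en
  })

  panel <- run_stage("pathway_scores", {
    sig <- significant_pathways(enrichment)$pathway_id
    use <- if (length(sig) > 0) parsed$pathways[sig] else parsed$pathways
    catalogs <- setNames(list(parsed$cat_a, parsed$cat_b),
                         c(cfg$cohort_a_name, cfg$cohort_b_name))
    catalogs <- catalogs[intersect(names(catalogs), rownames(parsed$z))]
    p <- score_pathway_panel(use, parsed$z, catalogs)
    write_tsv(p, file.path(out, "pathway_scores.tsv"))
    p
  })

  tf_stage <- run_stage("tf_profiles", {
    tfs <- sort(unique(c(reg_common$a$stfs, reg_common$b$stfs)))
    prof <- t(parsed$z[, intersect(tfs, colnames(parsed$z)),
                       drop = FALSE])
    ref <- cfg$reference_disease %||% rownames(parsed$z)[1]
    diff_tfs <- if (ncol(prof) >= 2 && nrow(prof) > 0)
      select_differential_tfs(prof, ref, delta = cfg$delta)
    else character(0)
    clusters <- tryCatch(
      cluster_tf_profiles(prof[diff_tfs, , drop = FALSE],
                          k = cfg$k_clusters),
      cohortnet_error = function(e) NULL)
    if (!is.null(clusters))
      write_tsv(data.frame(tf = names(clusters$assignment),
                           cluster = unname(clusters$assignment)),
                file.path(out, "tf_clusters.tsv"))
    writeLines(diff_tfs, file.path(out, "differential_tfs.txt"))
    list(profiles = prof, differential_tfs = diff_tfs,
         clusters = clusters, reference = ref)
  })

  stage <- "manifest"
  manifest <- list(
    package = "cohortnet",
    version = as.character(utils::packageVersion("cohortnet")),
    rng_seed = cfg$rng_seed,
    parameters = unclass(params),
    thresholds = cfg[c("min_patients", "p_cut", "fdr_cut", "delta",
                       "k_clusters")],
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    stages = log)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage <- "done"
  invisible(list(seeds = seeds, network_a = net_a, network_b = net_b,
                 comparison = comparison, regulation = reg_common,
                 enrichment = enrichment, pathway_scores = panel,
                 tf_profiles = tf_stage, manifest = manifest,
                 out_dir = out))
}
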