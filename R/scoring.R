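# Pathway-level assessment: expression score (mean |z|), mutation
# propensity score (unique mutations per gene), TF-profile clustering.

#' Expression score of a pathway
#'
#' Mean absolute differential-expression z-score over a pathway's genes —
#' the magnitude of the pathway's deviation from normal expression
#' regardless of direction. Genes without a measured z-score are excluded
#' from numerator and denominator by default; `denominator = "pathway"`
#' divides by the full pathway size instead.
#'
#' @param pathway_genes nonempty character vector of gene symbols.
#' @param z named numeric vector of z-scores for one disease (`NA` or
#'   absent = unmeasured).
#' @param denominator `"scored"` (default) or `"pathway"`.
#' @return list with `es` (NA if no gene is scored), `n_scored`,
#'   `n_total`.
#' @export
expression_score <- function(pathway_genes, z,
                             denominator = c("scored", "pathway")) {
  denominator <- match.arg(denominator)
  if (length(pathway_genes) == 0)
    stop_cohortnet("empty pathway", "cohortnet_config_error")
  genes <- unique(toupper(pathway_genes))
  if (!is.null(names(z))) names(z) <- toupper(names(z))
  zg <- z[intersect(genes, names(z))]
  zg <- zg[!is.na(zg)]
  n_scored <- length(zg)
  es <- if (n_scored == 0) NA_real_ else
    sum(abs(zg)) / if (denominator == "scored") n_scored else length(genes)
  list(es = es, n_scored = n_scored, n_total = length(genes))
}

#' Mutation propensity score of a pathway
#'
#' Total number of distinct (gene, protein change) mutations falling in the
#' pathway's genes, normalized by the number of gene members of the
#' pathway — a measure of how vulnerable the pathway is to mutation in a
#' cohort. Genes with no mutations contribute zero.
#'
#' @param pathway_genes nonempty character vector of gene symbols.
#' @param catalog a `mutation_catalog`.
#' @return the propensity score (>= 0).
#' @export
propensity_score <- function(pathway_genes, catalog) {
  if (length(pathway_genes) == 0)
    stop_cohortnet("empty pathway", "cohortnet_config_error")
  genes <- unique(toupper(pathway_genes))
  muts <- catalog$unique_mutations
  mut_genes <- sub(":.*$", "", muts)
  sum(mut_genes %in% genes) / length(genes)
}

#' Expression and propensity scores across a pathway-by-disease panel
#'
#' Computes the full cross of pathways and diseases: per cell the
#' expression score from that disease's z-scores and, when a mutation
#' catalog is supplied for the disease, the propensity score.
#'
#' @param pathways named list of gene sets.
#' @param z_table disease x gene numeric matrix (see
#'   [read_expression_table()]).
#' @param catalogs optional named list of `mutation_catalog`s keyed by
#'   disease; diseases without a catalog get `NA` propensity.
#' @param denominator passed to [expression_score()].
#' @return data frame with columns `pathway_id`, `disease`,
#'   `expression_score`, `propensity_score`, `n_genes_scored`,
#'   `n_genes_total`, ordered by (pathway_id, disease).
#' @export
score_pathway_panel <- function(pathways, z_table, catalogs = list(),
                                denominator = "scored") {
  stopifnot(length(pathways) > 0, is.matrix(z_table))
  diseases <- rownames(z_table)
  grid <- expand.grid(pathway_id = sort(names(pathways)),
                      disease = sort(diseases),
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$pathway_id, grid$disease), , drop = FALSE]
  res <- lapply(seq_len(nrow(grid)), function(i) {
    pid <- grid$pathway_id[i]; dis <- grid$disease[i]
    es <- expression_score(pathways[[pid]], z_table[dis, ],
                           denominator = denominator)
    ps <- if (!is.null(catalogs[[dis]]))
      propensity_score(pathways[[pid]], catalogs[[dis]]) else NA_real_
    data.frame(pathway_id = pid, disease = dis,
               expression_score = es$es, propensity_score = ps,
               n_genes_scored = es$n_scored, n_genes_total = es$n_total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cluster TF expression profiles across diseases
#'
#' Agglomerative hierarchical clustering (Euclidean distance, average
#' linkage) of a TF x disease z-score matrix, cut at `k` groups — the
#' grouping used to contrast proliferation- versus differentiation-type
#' regulators. Only TFs with complete profiles are clustered.
#'
#' @param profiles numeric matrix, rows = TFs, columns = diseases.
#' @param k number of clusters (>= 1).
#' @return list of class `tf_clusters`: `assignment` (named integer
#'   vector), `tree` (`hclust`), `profiles` (complete rows),
#'   `n_incomplete`.
#' @export
cluster_tf_profiles <- function(profiles, k = 3) {
  stopifnot(is.matrix(profiles), k >= 1)
  complete <- complete.cases(profiles)
  m <- profiles[complete, , drop = FALSE]
  if (nrow(m) < k)
    stop_cohortnet(sprintf(
      "only %d complete TF profiles for k = %d clusters", nrow(m), k),
      "cohortnet_insufficient_data")
  tree <- hclust(dist(m, method = "euclidean"), method = "average")
  assignment <- cutree(tree, k = k)
  structure(list(assignment = assignment, tree = tree, profiles = m,
                 n_incomplete = sum(!complete), k = k),
            class = "tf_clusters")
}

#' @export
print.tf_clusters <- function(x, ...) {
  cat(sprintf("TF profile clustering: %d TFs in %d groups",
              nrow(x$profiles), x$k))
  if (x$n_incomplete > 0)
    cat(sprintf(" (%d incomplete profiles excluded)", x$n_incomplete))
  cat("\n  cluster sizes:", paste(table(x$assignment), collapse = ", "),
      "\n")
  invisible(x)
}

#' Heatmap of clustered TF profiles
#' @param x a `tf_clusters` object.
#' @param ... passed to [stats::heatmap()].
#' @export
plot.tf_clusters <- function(x, ...) {
  ord <- order(x$assignment)
  stats::heatmap(x$profiles[ord, , drop = FALSE], Rowv = NA, Colv = NA,
                 scale = "none",
                 RowSideColors = grDevices::hcl.colors(
                   max(x$assignment), "Dark 3")[x$assignment[ord]], ...)
  invisible(x)
}

#' Select TFs differentially expressed against a reference disease
#'
#' A TF qualifies when its z-score in the reference disease differs from
#' its z-score in at least one other disease by `delta` or more (both
#' values measured). This captures regulators whose activity separates the
#' reference condition from the comparison set.
#'
#' @param profiles numeric matrix, rows = TFs, columns = diseases.
#' @param reference_disease column name of the reference condition.
#' @param delta minimum absolute z difference (default 1).
#' @return character vector of TF names.
#' @export
select_differential_tfs <- function(profiles, reference_disease,
                                    delta = 1.0) {
  stopifnot(is.matrix(profiles))
  if (!reference_disease %in% colnames(profiles))
    stop_cohortnet(paste0("reference disease '", reference_disease,
                          "' not in profile columns"),
                   "cohortnet_config_error")
  ref <- profiles[, reference_disease]
  others <- profiles[, setdiff(colnames(profiles), reference_disease),
                     drop = FALSE]
  diffs <- abs(others - ref)
  hit <- apply(diffs, 1, function(d) any(!is.na(d) & d >= delta))
  hit <- hit & !is.na(ref)
  rownames(profiles)[hit]
}
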