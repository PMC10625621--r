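# TF/target annotation of disease networks and hypergeometric
# overrepresentation analysis.

#' Identify specific transcription factors (STFs) of a network
#'
#' STFs are the regulatory-map TFs that appear as nodes of a
#' disease-specific network; their regulated genes are the union of their
#' targets in the map (targets need not be network nodes). Node roles are
#' updated in place: STFs become `"tf"`, network nodes that are targets of
#' an STF become `"target"` (seeds keep the `"seed"` role).
#'
#' @param network a `disease_network`.
#' @param reg a `regulatory_map`.
#' @return list with `stfs`, `targets` (character vectors) and `network`
#'   (role-annotated copy).
#' @export
identify_stfs <- function(network, reg) {
  nodes <- network$nodes$gene
  stfs <- sort(intersect(nodes, reg$tf_set))
  if (length(stfs) == 0) {
    warning("network contains no regulatory-map TF")
    targets <- character(0)
  } else {
    targets <- sort(unique(reg$pairs$target[reg$pairs$tf %in% stfs]))
  }
  role <- network$nodes$role
  role[nodes %in% stfs & role != "seed"] <- "tf"
  role[nodes %in% targets & !(nodes %in% stfs) & role != "seed"] <- "target"
  network$nodes$role <- role
  igraph::V(network$graph)$role <-
    role[match(igraph::V(network$graph)$name, nodes)]
  list(stfs = stfs, targets = targets, network = network)
}

#' Common TFs and commonly regulated targets of two disease networks
#'
#' Common TFs are the STFs shared by both networks. Common targets are, by
#' default, the intersection of the two networks' full STF-target unions
#' (so a gene regulated by different TFs in the two diseases still counts);
#' `targets_of_common_only = TRUE` restricts to targets of the shared TFs.
#'
#' @param net_a,net_b `disease_network` objects.
#' @param reg a `regulatory_map`.
#' @param targets_of_common_only alternative target semantics (see above).
#' @return list with `common_tfs`, `common_targets`, and the per-network
#'   annotations `a`, `b` (as returned by [identify_stfs()]).
#' @export
common_regulation <- function(net_a, net_b, reg,
                              targets_of_common_only = FALSE) {
  ra <- identify_stfs(net_a, reg)
  rb <- identify_stfs(net_b, reg)
  common_tfs <- intersect(ra$stfs, rb$stfs)
  common_targets <- if (targets_of_common_only) {
    sort(unique(reg$pairs$target[reg$pairs$tf %in% common_tfs]))
  } else {
    sort(intersect(ra$targets, rb$targets))
  }
  list(common_tfs = sort(common_tfs), common_targets = common_targets,
       a = ra, b = rb)
}

#' Hypergeometric overrepresentation analysis
#'
#' Tests a query gene list against each pathway gene set with the
#' hypergeometric upper tail `P(X >= k)`, where `k` is the query/set
#' overlap, `K` the set size within the universe, `n` the query size and
#' `N` the universe size, followed by Benjamini-Hochberg adjustment across
#' all tested sets. Query genes outside the universe are dropped (and
#' counted); a significant view applies `p < p_cut` and `FDR < fdr_cut`.
#'
#' @param query character vector of gene symbols.
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param universe background gene set; defaults to the union of the
#'   collection's genes and the query.
#' @param p_cut,fdr_cut significance cuts for the filtered view.
#' @return object of class `ora_result`: data frame `table` (pathway_id,
#'   overlap_count, set_size, query_size, universe_size, p_value, fdr,
#'   significant), sorted by p then pathway_id, plus `n_query_dropped`.
#' @export
ora_enrich <- function(query, collection, universe = NULL,
                       p_cut = 0.05, fdr_cut = 0.05) {
  if (length(query) == 0)
    stop_cohortnet("empty query gene list", "cohortnet_config_error")
  if (length(collection) == 0)
    stop_cohortnet("empty gene-set collection", "cohortnet_config_error")
  query <- unique(toupper(query))
  if (is.null(universe))
    universe <- unique(c(unlist(collection, use.names = FALSE), query))
  universe <- unique(toupper(universe))
  if (length(universe) == 0)
    stop_cohortnet("empty universe", "cohortnet_config_error")
  n_dropped <- sum(!query %in% universe)
  query <- intersect(query, universe)
  if (length(query) == 0)
    stop_cohortnet("no query gene lies in the universe",
                   "cohortnet_config_error")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection), function(id) {
    set <- intersect(collection[[id]], universe)
    K <- length(set)
    k <- length(intersect(query, set))
    # upper tail P(X >= k)
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = id, overlap_count = k, set_size = K,
               query_size = n, universe_size = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- p.adjust(tab$p_value, method = "BH")
  tab <- tab[order(tab$p_value, tab$pathway_id), , drop = FALSE]
  tab$significant <- tab$p_value < p_cut & tab$fdr < fdr_cut
  rownames(tab) <- NULL
  structure(list(table = tab, n_query_dropped = n_dropped,
                 p_cut = p_cut, fdr_cut = fdr_cut),
            class = "ora_result")
}

#' @export
print.ora_result <- function(x, ...) {
  sig <- x$table[x$table$significant, , drop = FALSE]
  cat(sprintf("ORA: %d sets tested, %d significant (p < %g and FDR < %g)\n",
              nrow(x$table), nrow(sig), x$p_cut, x$fdr_cut))
  if (x$n_query_dropped > 0)
    cat("  query genes outside universe (dropped):", x$n_query_dropped, "\n")
  print(head(sig[, c("pathway_id", "overlap_count", "set_size", "p_value",
                     "fdr")], 10), row.names = FALSE)
  invisible(x)
}

#' Significant rows of an ORA result
#' @param x an `ora_result`.
#' @return data frame of rows passing both cuts.
#' @export
significant_pathways <- function(x) {
  stopifnot(inherits(x, "ora_result"))
  x$table[x$table$significant, , drop = FALSE]
}
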