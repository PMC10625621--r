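# Seeded graphlet enumeration, degree-preserving null model, and the
# graphlet-guided network (GGN).

GRAPHLET_TYPES <- c("edge", "path3", "triangle", "path4", "star4",
                    "cycle4", "tailed_triangle", "diamond", "clique4")

# igraph -> (0-based integer edge matrix, node names); single internal shape
# shared by the enumeration and rewiring code
graph_as_edges <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  list(edges = el - 1L,
       nodes = igraph::V(g)$name,
       weight = igraph::E(g)$weight %||% rep(1, igraph::ecount(g)))
}

#' Enumerate seed-anchored graphlet instances
#'
#' Enumerates every connected induced subgraph on 2-4 nodes that contains at
#' least one seed, classified into the nine connected non-isomorphic
#' graphlet types (edge; 3-path; triangle; 4-path; 3-star; 4-cycle; tailed
#' triangle; diamond; 4-clique). Each distinct node set is returned once per
#' type. When the number of instances anchored at one seed exceeds
#' `max_per_seed`, that seed's instances are uniformly subsampled (reservoir
#' sampling under the session RNG), so set a seed for reproducibility.
#'
#' @param g undirected `igraph` graph.
#' @param seeds character vector of seed node names; seeds absent from `g`
#'   are dropped with a message.
#' @param max_per_seed cap on instances anchored at a single seed.
#' @param collect return the instance table (`TRUE`) or only type counts.
#' @return list with `counts` (named by graphlet type), `instances`
#'   (data frame: type + node columns, when `collect`), `n_enumerated`, and
#'   `dropped_seeds`.
#' @export
enumerate_seeded_graphlets <- function(g, seeds, max_per_seed = 50000,
                                       collect = TRUE) {
  stopifnot(max_per_seed >= 1)
  ge <- graph_as_edges(g)
  present <- seeds %in% ge$nodes
  dropped <- seeds[!present]
  if (length(dropped) > 0)
    message("dropping ", length(dropped), " seed(s) absent from the graph")
  seeds <- unique(seeds[present])
  if (length(seeds) == 0)
    stop_cohortnet("no seed gene is present in the graph",
                   "cohortnet_missing_seeds")
  sidx <- match(seeds, ge$nodes) - 1L
  res <- .cpp_seeded_graphlets(ge$edges, length(ge$nodes), as.integer(sidx),
                               as.integer(max_per_seed), collect)
  counts <- setNames(as.integer(res$counts), GRAPHLET_TYPES)
  inst <- NULL
  if (collect) {
    m <- res$instances
    inst <- data.frame(type = GRAPHLET_TYPES[m[, 1]],
                       stringsAsFactors = FALSE)
    for (j in 2:5)
      inst[[paste0("n", j - 1)]] <- ifelse(is.na(m[, j]), NA_character_,
                                           ge$nodes[m[, j] + 1L])
  }
  list(counts = counts, instances = inst,
       n_enumerated = res$n_enumerated, dropped_seeds = dropped)
}

#' Degree-preserving rewiring of a weighted graph
#'
#' Randomizes a graph by repeated double-edge swaps that keep every node's
#' degree, rejecting swaps that would create self-loops or duplicate edges.
#' Edge weights travel with the rewired edge slots, so the weight multiset
#' is preserved. This is the null model used to call graphlet types
#' significant.
#'
#' @param g undirected weighted `igraph` graph with >= 2 edges.
#' @param n_swaps number of attempted swaps (default `10 * ecount(g)`).
#' @return a rewired `igraph` graph with the same degree sequence.
#' @export
degree_preserving_rewire <- function(g, n_swaps = 10 * igraph::ecount(g)) {
  if (igraph::ecount(g) < 2)
    stop_cohortnet("need at least 2 edges to rewire",
                   "cohortnet_config_error")
  ge <- graph_as_edges(g)
  new_edges <- .cpp_rewire(ge$edges, as.integer(n_swaps))
  df <- data.frame(from = ge$nodes[new_edges[, 1] + 1L],
                   to = ge$nodes[new_edges[, 2] + 1L],
                   weight = ge$weight, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    df, directed = FALSE,
    vertices = data.frame(name = ge$nodes, stringsAsFactors = FALSE))
}

#' Build the graphlet-guided network (GGN) around a seed set
#'
#' Counts seed-anchored instances of each graphlet type in the observed
#' graph and in `n_rewires` degree-preserving rewirings, computes an
#' empirical z-score per type, and takes the union of all seeded instances
#' of the significant types (`z >= z_threshold`) as the GGN — the candidate
#' region of the interactome for disease-network selection. If no type
#' reaches significance the GGN falls back to the seeds' incident edges,
#' with a warning.
#'
#' @param g undirected weighted `igraph` interactome.
#' @param seeds seed gene symbols.
#' @param params an [inference_params()] list (uses `n_rewires`,
#'   `z_threshold`, `max_per_seed`, `n_swap_factor`).
#' @return list of class `ggn`: `graph` (igraph subgraph of `g`),
#'   `significant_types`, `type_stats` (data frame: type, observed, null
#'   mean/sd, z), `instances`, `seeds`, `dropped_seeds`, `fallback`.
#' @export
build_ggn <- function(g, seeds, params = inference_params()) {
  obs <- enumerate_seeded_graphlets(g, seeds,
                                    max_per_seed = params$max_per_seed,
                                    collect = TRUE)
  kept_seeds <- intersect(seeds, igraph::V(g)$name)
  ge <- graph_as_edges(g)
  null_counts <- .cpp_null_graphlet_counts(
    ge$edges, length(ge$nodes),
    as.integer(match(kept_seeds, ge$nodes) - 1L),
    as.integer(params$n_rewires),
    as.integer(params$n_swap_factor * igraph::ecount(g)),
    as.integer(params$max_per_seed))
  colnames(null_counts) <- GRAPHLET_TYPES
  mu <- colMeans(null_counts)
  sdev <- apply(null_counts, 2, stats::sd)
  z <- ifelse(sdev > 0, (obs$counts - mu) / sdev,
              ifelse(obs$counts > mu, Inf, ifelse(obs$counts < mu, -Inf, 0)))
  stats_df <- data.frame(type = GRAPHLET_TYPES, observed = obs$counts,
                         null_mean = mu, null_sd = sdev, z = z,
                         row.names = NULL, stringsAsFactors = FALSE)
  sig <- GRAPHLET_TYPES[z >= params$z_threshold & obs$counts > 0]
  fallback <- FALSE
  if (length(sig) == 0) {
    warning("no graphlet type significant; falling back to seed-incident edges")
    fallback <- TRUE
    keep <- obs$instances[obs$instances$type == "edge", , drop = FALSE]
  } else {
    keep <- obs$instances[obs$instances$type %in% sig, , drop = FALSE]
  }
  sub <- induced_union_subgraph(g, keep)
  structure(list(graph = sub, significant_types = sig,
                 type_stats = stats_df, instances = keep,
                 seeds = kept_seeds, dropped_seeds = obs$dropped_seeds,
                 fallback = fallback),
            class = "ggn")
}

# union of the induced edges of every instance's node set
induced_union_subgraph <- function(g, instances) {
  if (nrow(instances) == 0)
    return(igraph::induced_subgraph(g, character(0)))
  nm <- as.matrix(instances[, -1, drop = FALSE])
  combos <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  pairs <- do.call(rbind, lapply(combos, function(cb)
    cbind(nm[, cb[1]], nm[, cb[2]])))
  pairs <- pairs[!is.na(pairs[, 1]) & !is.na(pairs[, 2]), , drop = FALSE]
  swap <- pairs[, 1] > pairs[, 2]
  pairs[swap, ] <- pairs[swap, c(2, 1)]
  pairs <- unique(pairs)
  eids <- igraph::get_edge_ids(g, as.vector(t(pairs)))
  eids <- eids[eids > 0]
  igraph::subgraph_from_edges(g, igraph::E(g)[eids], delete.vertices = TRUE)
}

#' @export
print.ggn <- function(x, ...) {
  cat("Graphlet-guided network:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges\n")
  cat("  significant types:",
      if (length(x$significant_types)) paste(x$significant_types,
                                             collapse = ", ") else
        "(none; seed-edge fallback)", "\n")
  cat("  seeds in graph:", length(x$seeds), "\n")
  invisible(x)
}
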