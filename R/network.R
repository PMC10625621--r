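# Personalized PageRank, flux edge scoring, top-edge selection, and the
# disease_network model object tying the three together.

#' Inference parameters for disease-network reconstruction
#'
#' Defaults reproduce the reference settings: walk probability
#' `alpha = 0.5` (so the restart probability is `1 - alpha`), edge-selection
#' quantile `tau = 0.8` (keep the top 20 percent of GGN edges by flux), and
#' a hard stop at `edge_cap = 2000` interactions. Graphlet significance is
#' judged against `n_rewires` degree-preserving rewirings at one-sided
#' empirical z >= `z_threshold`.
#'
#' @param alpha probability of walking to a neighbor at each step, in (0,1).
#' @param tau flux quantile below which GGN edges are discarded, in `[0,1)`.
#' @param edge_cap maximum number of edges in the inferred network.
#' @param n_rewires number of null rewirings for graphlet significance.
#' @param z_threshold one-sided empirical z cut for significant graphlets.
#' @param max_per_seed cap on graphlet instances anchored per seed.
#' @param n_swap_factor attempted swaps per edge in each rewiring.
#' @param tol L1 convergence tolerance of the PageRank iteration.
#' @param flux_mode `"min"` scores an edge by the smaller of its two
#'   directed fluxes (bottleneck convention); `"sum"` adds them.
#' @param pagerank_scope `"reference"` runs PageRank on the full reference
#'   graph before restricting fluxes to GGN edges; `"ggn"` runs it on the
#'   GGN only.
#' @return a list of class `inference_params`.
#' @export
inference_params <- function(alpha = 0.5, tau = 0.8, edge_cap = 2000,
                             n_rewires = 100, z_threshold = 1.65,
                             max_per_seed = 50000, n_swap_factor = 10,
                             tol = 1e-12, flux_mode = c("min", "sum"),
                             pagerank_scope = c("reference", "ggn")) {
  stopifnot(alpha > 0, alpha < 1, tau >= 0, tau < 1, edge_cap >= 1,
            n_rewires >= 1, max_per_seed >= 1)
  structure(list(alpha = alpha, tau = tau, edge_cap = as.integer(edge_cap),
                 n_rewires = as.integer(n_rewires),
                 z_threshold = z_threshold,
                 max_per_seed = as.integer(max_per_seed),
                 n_swap_factor = n_swap_factor, tol = tol,
                 flux_mode = match.arg(flux_mode),
                 pagerank_scope = match.arg(pagerank_scope)),
            class = "inference_params")
}

#' Personalized PageRank with restart on a seed set
#'
#' Solves `pr = (1 - alpha) r + alpha t(M) pr` by power iteration, where `r`
#' is uniform over the seeds, `alpha` is the probability of walking to a
#' neighbor, and `M` is the weight-normalized transition matrix of the
#' undirected graph (each edge walkable in both directions). Zero-strength
#' (isolated) nodes are given an implicit self-loop so they retain exactly
#' their restart mass and total mass stays 1.
#'
#' @param g undirected weighted `igraph` graph.
#' @param seeds character vector of seed node names present in `g`.
#' @param alpha walk probability in (0,1).
#' @param tol stop when the L1 change falls below `tol`.
#' @param max_iter iteration cap.
#' @return named numeric vector of scores summing to 1.
#' @export
personalized_pagerank <- function(g, seeds, alpha = 0.5, tol = 1e-12,
                                  max_iter = 10000) {
  nodes <- igraph::V(g)$name
  seeds <- intersect(unique(seeds), nodes)
  if (length(seeds) == 0)
    stop_cohortnet("empty seed set for PageRank", "cohortnet_missing_seeds")
  stopifnot(alpha > 0, alpha < 1)
  n <- length(nodes)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight %||% rep(1, nrow(el))
  # symmetric weighted adjacency; implicit self-loop on isolated nodes
  A <- Matrix::sparseMatrix(i = c(el[, 1], el[, 2]),
                            j = c(el[, 2], el[, 1]),
                            x = c(w, w), dims = c(n, n))
  s <- Matrix::rowSums(A)
  iso <- which(s == 0)
  if (length(iso) > 0) {
    A <- A + Matrix::sparseMatrix(i = iso, j = iso, x = rep(1, length(iso)),
                                  dims = c(n, n))
    s[iso] <- 1
  }
  # transposed row-normalized transition matrix t(M), M = D^-1 A
  Wt <- methods::as(Matrix::t(Matrix::Diagonal(x = 1 / s) %*% A),
                    "CsparseMatrix")
  r <- numeric(n)
  r[match(seeds, nodes)] <- 1 / length(seeds)
  pr <- r
  for (it in seq_len(max_iter)) {
    nxt <- (1 - alpha) * r + alpha * as.numeric(Wt %*% pr)
    if (sum(abs(nxt - pr)) < tol) { pr <- nxt; break }
    pr <- nxt
  }
  setNames(pr, nodes)
}

#' Flux scores of edges under a PageRank solution
#'
#' The directed flux across `(u, v)` is the PageRank mass `u` pushes through
#' the edge in one step: `f(u -> v) = pr(u) w(u,v) / s(u)` with `s(u)` the
#' weighted strength of `u`. The undirected edge score is the smaller of the
#' two directed fluxes (default bottleneck convention) or their sum. Fluxes
#' are invariant to rescaling all weights by a constant.
#'
#' @param g undirected weighted `igraph` graph.
#' @param pr named PageRank vector covering all nodes of `g`.
#' @param mode `"min"` or `"sum"`.
#' @return data frame with columns `from`, `to`, `weight`, `flux`.
#' @export
edge_flux <- function(g, pr, mode = c("min", "sum")) {
  mode <- match.arg(mode)
  nodes <- igraph::V(g)$name
  if (!all(nodes %in% names(pr)))
    stop_cohortnet("PageRank vector does not cover all nodes",
                   "cohortnet_config_error")
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- igraph::E(g)$weight %||% rep(1, nrow(el))
  s <- setNames(as.numeric(igraph::strength(g, weights = w)), nodes)
  fu <- ifelse(s[el[, 1]] > 0, pr[el[, 1]] * w / s[el[, 1]], 0)
  fv <- ifelse(s[el[, 2]] > 0, pr[el[, 2]] * w / s[el[, 2]], 0)
  flux <- if (mode == "min") pmin(fu, fv) else fu + fv
  data.frame(from = el[, 1], to = el[, 2], weight = w,
             flux = as.numeric(flux), stringsAsFactors = FALSE)
}

#' Select the top-flux subnetwork from a GGN
#'
#' Ranks GGN edges by flux (descending; ties broken by the higher
#' min-endpoint PageRank, then by lexicographic edge key) and keeps edges
#' whose flux reaches the `tau` quantile of the GGN flux distribution,
#' stopping once `edge_cap` edges are selected.
#'
#' @param ggn a [build_ggn()] result.
#' @param flux edge-flux data frame over the GGN edges (see [edge_flux()]).
#' @param pr named PageRank vector.
#' @param params an [inference_params()] list.
#' @return list: `edges` (selected, ranked), `threshold`, `nodes`.
#' @export
select_network <- function(ggn, flux, pr, params = inference_params()) {
  if (igraph::ecount(ggn$graph) == 0)
    stop_cohortnet("empty GGN: nothing to select", "cohortnet_empty_ggn")
  fl <- flux
  a <- pmin(fl$from, fl$to); b <- pmax(fl$from, fl$to)
  fl$from <- a; fl$to <- b
  fl$min_pr <- pmin(pr[fl$from], pr[fl$to])
  thr <- as.numeric(quantile(fl$flux, probs = params$tau, type = 7))
  ord <- order(-fl$flux, -fl$min_pr, fl$from, fl$to)
  fl <- fl[ord, , drop = FALSE]
  keep <- fl$flux >= thr
  keep[-seq_len(min(params$edge_cap, nrow(fl)))] <- FALSE
  sel <- fl[keep, , drop = FALSE]
  sel$rank <- seq_len(nrow(sel))
  rownames(sel) <- NULL
  list(edges = sel, threshold = thr,
       nodes = sort(unique(c(sel$from, sel$to))))
}

#' Infer a disease-specific network from seed genes
#'
#' Fits the three-step seeded network model on a reference interactome:
#' (1) a graphlet-guided network (GGN) is grown from the seeds as the union
#' of significant 2-4-node graphlet instances ([build_ggn()]); (2) nodes are
#' weighted by personalized PageRank restarted on the seeds and edges by the
#' PageRank flux they carry; (3) the top-flux GGN edges are kept, up to the
#' `tau` quantile and the 2000-edge cap ([select_network()]).
#'
#' @param g undirected weighted `igraph` reference interactome.
#' @param seeds character vector of seed gene symbols.
#' @param params an [inference_params()] list.
#' @param rng_seed integer seed controlling rewiring and subsampling.
#' @return an object of class `disease_network` with components `nodes`
#'   (data frame: gene, pagerank, is_seed, role), `edges` (data frame:
#'   from, to, weight, flux, rank), `graph` (igraph), `ggn`, `params`,
#'   `seeds`, `flux_threshold`.
#' @export
infer_disease_network <- function(g, seeds, params = inference_params(),
                                  rng_seed = 1) {
  set.seed(rng_seed)
  ggn <- build_ggn(g, seeds, params)
  pr_graph <- if (params$pagerank_scope == "reference") g else ggn$graph
  pr <- personalized_pagerank(pr_graph, ggn$seeds, alpha = params$alpha,
                              tol = params$tol)
  fl <- edge_flux(ggn$graph, pr, mode = params$flux_mode)
  sel <- select_network(ggn, fl, pr, params)
  missing_seeds <- setdiff(ggn$seeds, sel$nodes)
  if (length(missing_seeds) > 0)
    message(length(missing_seeds), " seed(s) not in the selected network")
  nodes <- data.frame(gene = sel$nodes,
                      pagerank = as.numeric(pr[sel$nodes]),
                      is_seed = sel$nodes %in% ggn$seeds,
                      role = ifelse(sel$nodes %in% ggn$seeds, "seed",
                                    "other"),
                      stringsAsFactors = FALSE)
  net <- igraph::graph_from_data_frame(sel$edges, directed = FALSE,
                                       vertices = nodes)
  structure(list(nodes = nodes, edges = sel$edges, graph = net, ggn = ggn,
                 params = params, seeds = ggn$seeds,
                 dropped_seeds = ggn$dropped_seeds,
                 unselected_seeds = missing_seeds,
                 flux_threshold = sel$threshold, rng_seed = rng_seed),
            class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat("Disease-specific network\n")
  cat(sprintf("  %d nodes, %d edges (cap %d, tau = %.2f, alpha = %.2f)\n",
              nrow(x$nodes), nrow(x$edges), x$params$edge_cap,
              x$params$tau, x$params$alpha))
  cat(sprintf("  seeds used: %d (%d in final network)\n", length(x$seeds),
              sum(x$nodes$is_seed)))
  cat("  significant graphlets:",
      if (length(x$ggn$significant_types))
        paste(x$ggn$significant_types, collapse = ", ") else
          "(fallback)", "\n")
  invisible(x)
}

#' @export
summary.disease_network <- function(object, ...) {
  top <- head(object$nodes[order(-object$nodes$pagerank), ], 10)
  out <- list(n_nodes = nrow(object$nodes), n_edges = nrow(object$edges),
              n_seeds = sum(object$nodes$is_seed),
              roles = table(object$nodes$role),
              flux_threshold = object$flux_threshold,
              top_nodes = top)
  class(out) <- "summary.disease_network"
  out
}

#' @export
print.summary.disease_network <- function(x, ...) {
  cat(sprintf("Disease network: %d nodes / %d edges (%d seeds)\n",
              x$n_nodes, x$n_edges, x$n_seeds))
  cat("  node roles:\n"); print(x$roles)
  cat(sprintf("  flux threshold: %.3g\n", x$flux_threshold))
  cat("  top nodes by PageRank:\n")
  print(x$top_nodes, row.names = FALSE)
  invisible(x)
}

#' Plot a disease network
#'
#' Seeds are drawn as filled squares, TFs as triangles, targets as
#' diamonds, remaining nodes as circles; edge width scales with flux.
#'
#' @param x a `disease_network`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.disease_network <- function(x, ...) {
  g <- x$graph
  role <- igraph::V(g)$role
  shape <- c(seed = "square", tf = "csquare", target = "circle",
             other = "circle")[role]
  col <- c(seed = "tomato", tf = "gold", target = "lightskyblue",
           other = "grey80")[role]
  ew <- igraph::E(g)$flux
  ew <- 0.5 + 3 * ew / max(ew)
  igraph::plot.igraph(g, vertex.shape = shape, vertex.color = col,
                      vertex.size = 6, vertex.label.cex = 0.5,
                      edge.width = ew, ...)
  invisible(x)
}

#' Export a disease network's node and edge tables
#'
#' Writes `<prefix>_nodes.tsv`, `<prefix>_edges.tsv` and
#' `<prefix>.graphml`.
#'
#' @param net a `disease_network`.
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_disease_network <- function(net, prefix) {
  p1 <- paste0(prefix, "_nodes.tsv")
  p2 <- paste0(prefix, "_edges.tsv")
  p3 <- paste0(prefix, ".graphml")
  write_tsv(net$nodes, p1)
  write_tsv(net$edges[, c("from", "to", "weight", "flux", "rank")], p2)
  igraph::write_graph(net$graph, p3, format = "graphml")
  invisible(c(p1, p2, p3))
}
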