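# Independent oracles and small fixtures shared across tests. Each oracle
# re-derives the quantity from first principles (brute force, closed form,
# dense linear algebra) without touching the package's own code paths.

# ---- fixtures ---------------------------------------------------------

toy_catalog <- function(rows, name = "toy") {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(sample_id = r[1], gene = r[2], protein_change = r[3],
               stringsAsFactors = FALSE)))
  mutation_catalog(df, name)
}

random_weighted_graph <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  while (igraph::ecount(g) < 1) g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  igraph::E(g)$weight <- runif(igraph::ecount(g), 0.1, 1)
  g
}

# ---- Welch t closed form ---------------------------------------------

welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}

# ---- hypergeometric tail and BH step-up ------------------------------

hyper_tail_oracle <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  adj[ord] <- pmin(1, rev(cummin(rev(m * p[ord] / seq_len(m)))))
  adj
}

# ---- personalized PageRank as a dense linear system ------------------

pagerank_oracle <- function(g, seeds, alpha) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  for (e in seq_len(nrow(el))) {
    A[el[e, 1], el[e, 2]] <- A[el[e, 1], el[e, 2]] + w[e]
    A[el[e, 2], el[e, 1]] <- A[el[e, 2], el[e, 1]] + w[e]
  }
  s <- rowSums(A)
  iso <- s == 0
  diag(A)[iso] <- 1
  s[iso] <- 1
  M <- A / s
  r <- numeric(n)
  r[match(seeds, nodes)] <- 1 / length(seeds)
  solve(diag(n) - alpha * t(M), (1 - alpha) * r)
}

# ---- brute-force seeded graphlet enumeration -------------------------

# classify a node set by its induced subgraph; NA when disconnected
brute_classify <- function(adj, idx) {
  k <- length(idx)
  sub <- adj[idx, idx, drop = FALSE]
  reach <- (diag(k) + sub) %*% (diag(k) + sub) %*% (diag(k) + sub)
  if (any(reach[1, ] == 0)) return(NA_character_)
  m <- sum(sub) / 2
  maxd <- max(rowSums(sub))
  if (k == 2) return("edge")
  if (k == 3) return(if (m == 3) "triangle" else "path3")
  if (m == 3) return(if (maxd == 3) "star4" else "path4")
  if (m == 4) return(if (maxd == 3) "tailed_triangle" else "cycle4")
  if (m == 5) return("diamond")
  "clique4"
}

# every connected induced subgraph of size 2-4 containing >= 1 seed,
# as sorted "type|node,node,..." keys
brute_seeded_graphlets <- function(g, seeds) {
  nodes <- igraph::V(g)$name
  adj <- (igraph::as_adjacency_matrix(g, sparse = FALSE) > 0) * 1
  keys <- character(0)
  for (k in 2:4) {
    if (length(nodes) < k) next
    cmb <- combn(seq_along(nodes), k)
    for (j in seq_len(ncol(cmb))) {
      idx <- cmb[, j]
      if (!any(nodes[idx] %in% seeds)) next
      type <- brute_classify(adj, idx)
      if (!is.na(type))
        keys <- c(keys, paste0(type, "|",
                               paste(sort(nodes[idx]), collapse = ",")))
    }
  }
  sort(keys)
}

instance_keys <- function(instances) {
  sort(vapply(seq_len(nrow(instances)), function(i) {
    ns <- unlist(instances[i, -1], use.names = FALSE)
    paste0(instances$type[i], "|",
           paste(sort(ns[!is.na(ns)]), collapse = ","))
  }, character(1)))
}

# ---- naive average-linkage agglomeration -----------------------------

naive_average_linkage <- function(m, k) {
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      lnk <- mean(d[clusters[[i]], clusters[[j]]])
      if (lnk < best[1]) best <- c(lnk, i, j)
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  assign <- integer(nrow(m))
  for (ci in seq_along(clusters)) assign[clusters[[ci]]] <- ci
  setNames(assign, rownames(m))
}

# canonical partition labels so assignments compare up to renaming
canonical_partition <- function(assign) {
  match(assign, unique(assign))
}
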