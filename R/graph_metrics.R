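# Four nodal metrics on thresholded weighted graphs, degree-preserving null
# ensembles, and null-normalization. Path lengths use reciprocal weights;
# weighted clustering uses the geometric-mean (Onnela) formulation on
# max-rescaled weights, the weighted-undirected convention of the standard
# brain-connectivity toolboxes.

graph_weights <- function(G) {
  W <- if (inherits(G, "weighted_graph")) G$weights else as.matrix(G)
  if (any(W < 0)) stop("weights must be nonnegative")
  if (any(diag(W) != 0)) stop("diagonal must be zero")
  W
}

as_igraph <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

#' Eigenvector centrality of a weighted graph
#'
#' Leading eigenvector of the weight matrix (largest eigenvalue), entries
#' nonnegative, scaled to unit Euclidean norm. Computed on the largest
#' connected component; nodes outside it get 0 and the result carries a
#' `disconnected` attribute.
#'
#' @param G A [proportional_threshold()] weighted graph (or nonnegative
#'   symmetric matrix with zero diagonal).
#' @return Numeric per-node vector with unit 2-norm over the giant component.
#' @export
eigenvector_centrality <- function(G) {
  W <- graph_weights(G)
  n <- nrow(W)
  if (all(W == 0)) stop("empty graph")
  g <- as_igraph(W)
  comp <- igraph::components(g)
  giant <- which.max(comp$csize)
  idx <- which(comp$membership == giant)
  sub <- igraph::induced_subgraph(g, idx)
  ec <- igraph::eigen_centrality(sub, weights = igraph::E(sub)$weight)$vector
  ec <- abs(ec)
  ec <- ec / sqrt(sum(ec^2))
  out <- numeric(n)
  out[idx] <- ec
  names(out) <- rownames(W)
  attr(out, "disconnected") <- comp$no > 1
  out
}

#' Weighted clustering coefficient (geometric-mean formulation)
#'
#' `C_i = sum_{j,h} (w_ij' w_ih' w_jh')^(1/3) / (k_i (k_i - 1))` with weights
#' rescaled by the graph maximum and `k_i` the binary degree; nodes with
#' fewer than two neighbours get 0. Values lie in `[0, 1]`.
#'
#' @inheritParams eigenvector_centrality
#' @return Numeric per-node vector.
#' @export
clustering_coefficient <- function(G) {
  W <- graph_weights(G)
  if (all(W == 0)) return(setNames(numeric(nrow(W)), rownames(W)))
  Wh <- (W / max(W))^(1 / 3)
  num <- diag(Wh %*% Wh %*% Wh)
  k <- rowSums(W > 0)
  C <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  setNames(C, rownames(W))
}

#' Closeness centrality with reciprocal-weight path lengths
#'
#' Edge lengths are `1 / weight`; for node `i`,
#' `closeness_i = (1 / sum_j d(i, j)) * (r_i - 1) / (n - 1)` where the sum
#' and the reachable count `r_i` run over nodes reachable from `i`
#' (disconnection penalty). Isolated nodes get 0.
#'
#' @inheritParams eigenvector_centrality
#' @return Numeric per-node vector.
#' @export
closeness_centrality <- function(G) {
  W <- graph_weights(G)
  n <- nrow(W)
  g <- as_igraph(W)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  out <- numeric(n)
  for (i in seq_len(n)) {
    reach <- which(is.finite(d[i, ]) & seq_len(n) != i)
    if (length(reach) == 0) next
    out[i] <- (1 / sum(d[i, reach])) * length(reach) / (n - 1)
  }
  setNames(out, rownames(W))
}

#' Louvain community partition (best of seeded restarts)
#'
#' Runs Louvain modularity maximization `n_runs` times from seeded starts
#' and returns the partition with the highest weighted modularity `Q`
#' (reported as an attribute). Deterministic given `seed`.
#'
#' @inheritParams eigenvector_centrality
#' @param resolution Modularity resolution parameter (default 1).
#' @param n_runs Number of restarts (default 100).
#' @param seed Integer RNG seed.
#' @return Integer per-node community labels with attribute `modularity`.
#' @export
louvain_partition <- function(G, resolution = 1.0, n_runs = 100, seed = 1) {
  W <- graph_weights(G)
  if (all(W == 0)) stop("empty graph")
  g <- as_igraph(W)
  best <- NULL
  best_q <- -Inf
  for (run in seq_len(n_runs)) {
    set.seed(seed + run - 1L)
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    q <- igraph::modularity(g, igraph::membership(cl),
                            weights = igraph::E(g)$weight,
                            resolution = resolution)
    if (q > best_q) {
      best_q <- q
      best <- as.integer(igraph::membership(cl))
    }
  }
  names(best) <- rownames(W)
  attr(best, "modularity") <- best_q
  best
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_m (s_im / s_i)^2` where `s_im` is node `i`'s summed weight
#' to module `m` and `s_i` its strength; isolated nodes get 0. Captures the
#' diversity of a node's intermodular connections.
#'
#' @inheritParams eigenvector_centrality
#' @param labels Integer community labels covering all nodes (e.g. from
#'   [louvain_partition()]).
#' @return Numeric per-node vector in `[0, 1]`.
#' @export
participation_coefficient <- function(G, labels) {
  W <- graph_weights(G)
  n <- nrow(W)
  if (length(labels) != n) stop("labels must cover all nodes")
  s <- rowSums(W)
  P <- numeric(n)
  mods <- unique(labels)
  frac2 <- matrix(0, n, length(mods))
  for (m in seq_along(mods)) {
    frac2[, m] <- rowSums(W[, labels == mods[m], drop = FALSE])
  }
  ok <- s > 0
  P[ok] <- 1 - rowSums((frac2[ok, , drop = FALSE] / s[ok])^2)
  setNames(P, rownames(W))
}

#' Degree-preserving null ensemble
#'
#' Each null graph is built by degree-sequence-preserving edge-swap rewiring
#' of the binary topology (`swaps_per_edge` attempted swaps per edge),
#' followed by random reassignment of the original weight multiset to the
#' rewired edges. Graphs with no valid swap (complete graphs) keep their
#' topology and only permute weights, with a warning.
#'
#' @inheritParams eigenvector_centrality
#' @param n_nulls Ensemble size (default 500).
#' @param swaps_per_edge Attempted swaps per edge (default 10).
#' @param seed Integer RNG seed.
#' @return An object of class `null_ensemble`: list of weight matrices plus
#'   the generation parameters.
#' @export
degree_preserving_nulls <- function(G, n_nulls = 500, swaps_per_edge = 10, seed = 1) {
  W <- graph_weights(G)
  n <- nrow(W)
  ut <- upper.tri(W)
  wts <- W[ut][W[ut] > 0]
  m <- length(wts)
  if (m < 2) stop("need at least 2 edges")
  complete <- m == n * (n - 1) / 2
  if (complete) warning("complete graph: nulls keep the topology and permute weights only")
  g0 <- as_igraph((W > 0) * 1)
  graphs <- vector("list", n_nulls)
  for (k in seq_len(n_nulls)) {
    set.seed(seed + k - 1L)
    gk <- if (complete) g0 else igraph::rewire(g0, igraph::keeping_degseq(niter = swaps_per_edge * m))
    el <- igraph::as_edgelist(gk, names = FALSE)
    Wk <- matrix(0, n, n, dimnames = dimnames(W))
    Wk[el] <- sample(wts)
    Wk <- Wk + t(Wk)
    graphs[[k]] <- Wk
  }
  structure(list(graphs = graphs, n_nulls = n_nulls,
                 rewire_swaps_per_edge = swaps_per_edge, seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d degree-preserving nulls (%d swaps/edge, seed %d)\n",
              x$n_nulls, x$rewire_swaps_per_edge, x$seed))
  invisible(x)
}

#' Normalize a nodal metric against a null ensemble
#'
#' Primary normalization is the ratio `raw / null_mean` (the convention for
#' small-world-type indices); the z-score `(raw - null_mean) / null_sd` is
#' returned alongside. Nodes whose null mean is at or below `eps` get `NA`.
#'
#' @param raw Numeric per-node metric vector.
#' @param null_values `n_nulls` x n matrix of the same metric on each null
#'   graph.
#' @param eps Floor below which the null mean is treated as zero.
#' @return Tibble `(raw, null_mean, null_sd, ratio, zscore)` per node.
#' @export
normalize_metric <- function(raw, null_values, eps = 1e-12) {
  if (ncol(null_values) != length(raw)) stop("metric/ensemble size mismatch")
  mu <- colMeans(null_values)
  sdv <- apply(null_values, 2, sd)
  tibble::tibble(
    raw = as.numeric(raw),
    null_mean = mu,
    null_sd = sdv,
    ratio = ifelse(mu > eps, raw / mu, NA_real_),
    zscore = ifelse(sdv > eps, (raw - mu) / sdv, NA_real_)
  )
}

metric_vector <- function(W, metric, louvain_runs, seed) {
  switch(metric,
    eigenvector_centrality = eigenvector_centrality(W),
    clustering_coefficient = clustering_coefficient(W),
    closeness_centrality = closeness_centrality(W),
    participation_coefficient = {
      lab <- louvain_partition(W, n_runs = louvain_runs, seed = seed)
      participation_coefficient(W, lab)
    },
    stop("unknown metric: ", metric)
  )
}

GRAPH_METRICS <- c("eigenvector_centrality", "clustering_coefficient",
                   "closeness_centrality", "participation_coefficient")

#' All four nodal metrics, raw and null-normalized
#'
#' Computes eigenvector centrality, weighted clustering, closeness and
#' participation (via Louvain) for every node, builds a degree-preserving
#' null ensemble and returns ratio- and z-normalized values in long format.
#'
#' @inheritParams degree_preserving_nulls
#' @param louvain_runs Louvain restarts for the observed graph (default 100).
#' @param null_louvain_runs Louvain restarts per null graph (default 1; null
#'   partitions are recomputed per null).
#' @return Tibble with columns `node` (0-based), `metric`, `raw`,
#'   `null_mean`, `null_sd`, `ratio`, `zscore`.
#' @export
compute_all_metrics <- function(G, n_nulls = 500, swaps_per_edge = 10,
                                louvain_runs = 100, null_louvain_runs = 1,
                                seed = 1) {
  W <- graph_weights(G)
  n <- nrow(W)
  ens <- degree_preserving_nulls(G, n_nulls = n_nulls,
                                 swaps_per_edge = swaps_per_edge, seed = seed)
  out <- vector("list", length(GRAPH_METRICS))
  for (mi in seq_along(GRAPH_METRICS)) {
    metric <- GRAPH_METRICS[mi]
    raw <- metric_vector(W, metric, louvain_runs, seed)
    nulls <- matrix(0, n_nulls, n)
    for (k in seq_len(n_nulls)) {
      nulls[k, ] <- metric_vector(ens$graphs[[k]], metric, null_louvain_runs,
                                  seed + 7919L * k)
    }
    out[[mi]] <- dplyr::bind_cols(
      tibble::tibble(node = seq_len(n) - 1L, metric = metric),
      normalize_metric(raw, nulls)
    )
  }
  dplyr::bind_rows(out)
}
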