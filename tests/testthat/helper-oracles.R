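# Brute-force oracles for the graph metrics, written independently of the
# package implementations (dense eigen-decomposition, Floyd-Warshall,
# explicit triple loops), plus a random weighted-graph battery.

random_connected_graph <- function(n, seed, p_edge = 0.7) {
  set.seed(seed)
  repeat {
    W <- matrix(0, n, n)
    ut <- which(upper.tri(W))
    on <- runif(length(ut)) < p_edge
    W[ut[on]] <- runif(sum(on), 0.1, 1)
    W <- W + t(W)
    if (sum(W > 0) == 0) next
    # connectivity via boolean reachability
    A <- W > 0
    R <- diag(n) > 0
    for (k in seq_len(n)) R <- R | (R %*% A) > 0
    if (all(R)) return(W)
  }
}

oracle_evcent <- function(W) {
  e <- eigen(W, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  v / sqrt(sum(v^2))
}

oracle_closeness <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    reach <- which(is.finite(D[i, ]) & seq_len(n) != i)
    if (length(reach)) out[i] <- (1 / sum(D[i, reach])) * length(reach) / (n - 1)
  }
  out
}

oracle_clustering <- function(W) {
  n <- nrow(W)
  Wh <- (W / max(W))^(1 / 3)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) s <- s + Wh[i, j] * Wh[i, h] * Wh[j, h]
      }
    }
    out[i] <- s / (k * (k - 1))
  }
  out
}

oracle_participation <- function(W, labels) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- sum(W[i, ])
    if (s == 0) next
    acc <- 0
    for (m in unique(labels)) acc <- acc + (sum(W[i, labels == m]) / s)^2
    out[i] <- 1 - acc
  }
  out
}

# A tiny 10-parcel parcellation (5 lobes x 1 bilateral region) for fast
# end-to-end tests.
tiny_parcellation <- function() {
  lobes <- c("frontal", "temporal", "parietal", "occipital", "limbic")
  load_parcellation(data.frame(
    name = rep(paste0(lobes, " region"), each = 2),
    hemisphere = rep(c("L", "R"), 5),
    lobe = rep(lobes, each = 2),
    region_id = rep(0:4, each = 2)
  ))
}

toy_parcellation <- function() {
  load_parcellation(taugraph_example("atlas_toy24.tsv"))
}

atlas98 <- function() load_parcellation(taugraph_example("atlas98.tsv"))
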