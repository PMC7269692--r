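# Nodal metrics against closed forms and brute-force oracles; null
# ensembles and normalization.

test_that("eigenvector centrality matches closed forms", {
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- 1
  star <- star + t(star)
  ec <- eigenvector_centrality(star)
  expect_equal(unname(ec[1]), sqrt(1 / 2), tolerance = 1e-6)
  expect_equal(unname(ec[2:4]), rep(sqrt(1 / 6), 3), tolerance = 1e-6)
  c4 <- matrix(0, 4, 4)
  c4[cbind(1:4, c(2, 3, 4, 1))] <- 1
  c4 <- pmax(c4, t(c4))
  expect_equal(as.numeric(eigenvector_centrality(c4)), rep(0.5, 4), tolerance = 1e-6)
  # support only on the heavier of two disconnected dyads
  dyads <- matrix(0, 4, 4)
  dyads[1, 2] <- 2; dyads[3, 4] <- 1
  dyads <- dyads + t(dyads)
  ec2 <- eigenvector_centrality(dyads)
  expect_true(attr(ec2, "disconnected"))
  expect_equal(unname(ec2[3:4]), c(0, 0))
  expect_equal(unname(ec2[1:2]), oracle_evcent(matrix(c(0, 2, 2, 0), 2))[1:2],
               tolerance = 1e-8)
  expect_error(eigenvector_centrality(matrix(0, 3, 3)), "empty")
})

test_that("clustering matches hand-computed triangles", {
  tri <- matrix(0, 3, 3)
  tri[upper.tri(tri)] <- 1
  tri <- tri + t(tri)
  expect_equal(unname(clustering_coefficient(tri)), rep(1, 3))
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 3] <- 1
  path <- path + t(path)
  expect_equal(unname(clustering_coefficient(path)), rep(0, 3))
  wtri <- matrix(0, 3, 3)
  wtri[1, 2] <- 1; wtri[1, 3] <- 0.5; wtri[2, 3] <- 0.5
  wtri <- wtri + t(wtri)
  expect_equal(unname(clustering_coefficient(wtri)),
               rep((1 * 0.5 * 0.5)^(1 / 3), 3), tolerance = 1e-12)
})

test_that("closeness uses reciprocal lengths and the reachability penalty", {
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 3] <- 1
  path <- path + t(path)
  cc <- closeness_centrality(path)
  expect_equal(unname(cc), c(1 / 3, 1 / 2, 1 / 3))
  dyad <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(unname(closeness_centrality(dyad)), c(2, 2))
  iso <- matrix(0, 3, 3)
  iso[1, 2] <- 1
  iso <- iso + t(iso)
  cc2 <- closeness_centrality(iso)
  expect_equal(unname(cc2[3]), 0)
  expect_equal(unname(cc2[1]), (1 / 1) * (1 / 2))  # one reachable of n-1 = 2
})

test_that("participation matches the strength-fraction formula", {
  split2 <- matrix(0, 3, 3)
  split2[1, 2] <- split2[1, 3] <- 1
  split2 <- split2 + t(split2)
  expect_equal(unname(participation_coefficient(split2, c(1, 2, 3))[1]), 0.5)
  star4 <- matrix(0, 5, 5)
  star4[1, 2:5] <- 1
  star4 <- star4 + t(star4)
  expect_equal(unname(participation_coefficient(star4, c(1, 2, 3, 4, 5))[1]), 0.75)
  within <- matrix(0, 3, 3)
  within[1, 2] <- 1
  within <- within + t(within)
  expect_equal(unname(participation_coefficient(within, c(1, 1, 2))[1]), 0)
})

test_that("louvain separates weakly joined cliques and is deterministic", {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1
  W[5:8, 5:8] <- 1
  diag(W) <- 0
  W[4, 5] <- W[5, 4] <- 0.1
  lab <- louvain_partition(W, seed = 5, n_runs = 20)
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:4])), 1)
  expect_equal(length(unique(lab[5:8])), 1)
  expect_gt(attr(lab, "modularity"), 0.4)
  lab2 <- louvain_partition(W, seed = 5, n_runs = 20)
  expect_identical(unclass(lab), unclass(lab2))
  # complete graph: no structure, single community accepted
  K <- matrix(1, 6, 6)
  diag(K) <- 0
  labk <- louvain_partition(K, seed = 1, n_runs = 5)
  expect_lte(attr(labk, "modularity"), 1e-9)
})

test_that("metrics agree with brute-force oracles on random graphs", {
  for (i in 1:40) {
    n <- 4 + (i %% 5)
    W <- random_connected_graph(n, seed = 100 + i)
    expect_equal(as.numeric(eigenvector_centrality(W)), oracle_evcent(W),
                 tolerance = 1e-10)
    expect_equal(unname(closeness_centrality(W)), oracle_closeness(W),
                 tolerance = 1e-12)
    expect_equal(unname(clustering_coefficient(W)), oracle_clustering(W),
                 tolerance = 1e-12)
    lab <- louvain_partition(W, seed = i, n_runs = 5)
    expect_equal(unname(participation_coefficient(W, lab)),
                 oracle_participation(W, lab), tolerance = 1e-12)
  }
})

test_that("metrics are permutation-equivariant and scale as documented", {
  W <- random_connected_graph(7, seed = 42)
  perm <- c(3, 7, 1, 5, 2, 6, 4)
  Wp <- W[perm, perm]
  expect_equal(as.numeric(eigenvector_centrality(Wp)),
               as.numeric(eigenvector_centrality(W))[perm], tolerance = 1e-9)
  expect_equal(unname(closeness_centrality(Wp)),
               unname(closeness_centrality(W))[perm], tolerance = 1e-12)
  expect_equal(unname(clustering_coefficient(Wp)),
               unname(clustering_coefficient(W))[perm], tolerance = 1e-12)
  # scale behaviour: clustering / participation / evcent invariant,
  # closeness scales linearly with the weights
  c_scale <- 3.7
  expect_equal(unname(clustering_coefficient(c_scale * W)),
               unname(clustering_coefficient(W)), tolerance = 1e-12)
  expect_equal(as.numeric(eigenvector_centrality(c_scale * W)),
               as.numeric(eigenvector_centrality(W)), tolerance = 1e-9)
  lab <- louvain_partition(W, seed = 1, n_runs = 5)
  expect_equal(unname(participation_coefficient(c_scale * W, lab)),
               unname(participation_coefficient(W, lab)), tolerance = 1e-12)
  expect_equal(unname(closeness_centrality(c_scale * W)),
               c_scale * unname(closeness_centrality(W)), tolerance = 1e-12)
})

test_that("null ensembles preserve degrees and the weight multiset", {
  set.seed(31)
  A <- matrix(runif(144), 12)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  G <- proportional_threshold(A, 0.3)
  ens <- degree_preserving_nulls(G, n_nulls = 50, seed = 7)
  deg0 <- rowSums(G$weights > 0)
  w0 <- sort(G$weights[upper.tri(G$weights)][G$weights[upper.tri(G$weights)] > 0])
  for (Wk in ens$graphs) {
    expect_equal(rowSums(Wk > 0), deg0)
    expect_equal(sort(Wk[upper.tri(Wk)][Wk[upper.tri(Wk)] > 0]), w0)
  }
  # seeded reproducibility
  ens2 <- degree_preserving_nulls(G, n_nulls = 5, seed = 7)
  expect_identical(ens$graphs[1:5], ens2$graphs)
  K <- matrix(1, 5, 5)
  diag(K) <- 0
  expect_warning(degree_preserving_nulls(K, n_nulls = 2, seed = 1), "complete")
})

test_that("rewiring destroys lattice triangles; normalization reads as > 1", {
  n <- 12
  W <- matrix(0, n, n)
  for (i in 1:n) for (k in 1:2) {
    j <- ((i + k - 1) %% n) + 1
    W[i, j] <- W[j, i] <- 1 - 0.01 * k
  }
  ens <- degree_preserving_nulls(W, n_nulls = 100, seed = 3)
  null_cc <- sapply(ens$graphs, function(Wk) mean(clustering_coefficient(Wk)))
  expect_lt(mean(null_cc), mean(clustering_coefficient(W)))
  nulls <- t(sapply(ens$graphs, clustering_coefficient))
  norm <- normalize_metric(clustering_coefficient(W), nulls)
  expect_gt(mean(norm$ratio), 1)
  # raw equal to the null mean gives a ratio of exactly 1
  self <- normalize_metric(colMeans(nulls), nulls)
  expect_equal(self$ratio, rep(1, n), tolerance = 1e-12)
})

test_that("compute_all_metrics returns a complete, reproducible table", {
  W <- random_connected_graph(8, seed = 9)
  tbl <- compute_all_metrics(W, n_nulls = 20, louvain_runs = 5, seed = 2)
  expect_equal(nrow(tbl), 8 * 4)
  expect_true(all(is.finite(tbl$raw)))
  expect_true(all(tbl$metric %in% c("eigenvector_centrality", "clustering_coefficient",
                                    "closeness_centrality", "participation_coefficient")))
  expect_true(all(tbl$raw[tbl$metric == "participation_coefficient"] <= 1))
  expect_true(all(tbl$raw[tbl$metric == "clustering_coefficient"] >= 0))
  tbl2 <- compute_all_metrics(W, n_nulls = 20, louvain_runs = 5, seed = 2)
  expect_identical(tbl, tbl2)
})
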