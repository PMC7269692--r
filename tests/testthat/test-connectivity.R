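# AEC matrices, proportional thresholding, lobar summaries.

test_that("AEC reproduces exact correlations and flags degenerate rows", {
  set.seed(21)
  e1 <- abs(rnorm(100)) + 0.1
  dup <- aec(rbind(e1, e1, abs(rnorm(100))))
  expect_equal(dup$values[1, 2], 1.0)
  expect_equal(unname(diag(dup$values)), rep(0, 3))
  anti <- aec(rbind(e1, max(e1) + 0.5 - e1))
  expect_equal(anti$values[1, 2], -1.0)
  expect_warning(cst <- aec(rbind(e1, rep(1, 100))), "constant")
  expect_equal(cst$values[1, 2], 0)
  long <- matrix(abs(rnorm(4 * 5000)), 4)
  A <- aec(long)
  expect_lt(max(abs(A$values)), 0.1)
  expect_error(aec(rbind(e1, e1)[, 1:10]), "30")
})

test_that("AEC is invariant to positive affine rescaling of an envelope", {
  set.seed(22)
  E <- matrix(abs(rnorm(3 * 500)), 3)
  A1 <- aec(E)
  E2 <- E
  E2[2, ] <- 3 * E[2, ] + 1
  A2 <- aec(E2)
  expect_equal(A1$values, A2$values, tolerance = 1e-12)
})

test_that("AEC respects the envelope validity mask", {
  set.seed(23)
  E <- matrix(abs(rnorm(2 * 200)), 2)
  valid <- rep(c(FALSE, TRUE), each = 100)
  # corrupt the invalid samples; the correlation must ignore them
  E2 <- E
  E2[, !valid] <- rep(E2[1, !valid], each = 2)
  es <- envelope_series(E2, 200, canonical_bands()$alpha, valid = valid)
  ref <- cor(E2[1, valid], E2[2, valid])
  expect_equal(aec(es)$values[1, 2], ref, tolerance = 1e-12)
})

test_that("proportional threshold retains exactly the requested edge count", {
  set.seed(24)
  A <- matrix(runif(98 * 98), 98)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  G <- proportional_threshold(A, 0.25)
  expect_equal(G$n_edges, 1188)  # floor(0.25 * 98 * 97 / 2)
  expect_equal(sum(G$weights[upper.tri(G$weights)] > 0), 1188)
  expect_equal(G$weights, t(G$weights))
  # 4-node, density 0.5 keeps the 3 strongest
  B <- matrix(0, 4, 4)
  B[upper.tri(B)] <- c(0.9, 0.1, 0.8, 0.2, 0.7, 0.3)
  B <- B + t(B)
  G2 <- proportional_threshold(B, 0.5)
  expect_equal(sort(G2$weights[upper.tri(G2$weights)][G2$weights[upper.tri(G2$weights)] > 0]),
               c(0.7, 0.8, 0.9))
  expect_error(proportional_threshold(B, 0), "density")
  expect_error(proportional_threshold(B, 0.01), "retains no edges")
})

test_that("ties break lexicographically and edge sets nest across densities", {
  n <- 8
  A <- matrix(1, n, n)
  diag(A) <- 0
  G <- proportional_threshold(A, 0.25)  # floor(0.25*28) = 7 edges
  el <- which(G$weights > 0 & upper.tri(G$weights), arr.ind = TRUE)
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  ut <- which(upper.tri(A), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), ][1:7, ]
  expect_equal(unname(el), unname(ut))
  set.seed(25)
  B <- matrix(runif(100), 10)
  B <- (B + t(B)) / 2
  diag(B) <- 0
  e1 <- proportional_threshold(B, 0.2)$weights > 0
  e2 <- proportional_threshold(B, 0.4)$weights > 0
  expect_true(all(e2[e1]))
})

test_that("negative correlations are never retained", {
  A <- matrix(0, 4, 4)
  A[upper.tri(A)] <- c(0.5, -0.9, 0.4, -0.8, 0.3, -0.7)
  A <- A + t(A)
  expect_warning(G <- proportional_threshold(A, 0.9), "positive")
  expect_true(all(G$weights >= 0))
  expect_equal(G$n_edges, 3)
})

test_that("lobar connectivity averages the right blocks", {
  parc <- toy_parcellation()
  n <- parc$n_parcels
  A <- matrix(0.3, n, n)
  diag(A) <- 0
  L <- lobar_connectivity(A, parc)
  expect_true(all(abs(L - 0.3) < 1e-12))
  # block construction: limbic-occipital pairs 0.5, everything else 0
  B <- matrix(0, n, n)
  li <- which(parc$parcels$lobe == "limbic")
  oc <- which(parc$parcels$lobe == "occipital")
  B[li, oc] <- 0.5
  B[oc, li] <- 0.5
  L2 <- lobar_connectivity(B, parc)
  expect_equal(L2["limbic", "occipital"], 0.5)
  expect_equal(L2["frontal", "parietal"], 0)
  expect_equal(L2["limbic", "limbic"], 0)
  # hand-computable 6-parcel case
  small <- load_parcellation(data.frame(
    name = c("f", "f", "t", "t", "p", "p"),
    hemisphere = rep(c("L", "R"), 3),
    lobe = c("frontal", "frontal", "temporal", "temporal", "parietal", "parietal"),
    region_id = rep(0:2, each = 2)
  ))
  C <- matrix(0, 6, 6)
  C[1, 2] <- 0.4            # within frontal
  C[1, 3] <- 0.2; C[2, 4] <- 0.6  # frontal-temporal block (4 pairs)
  C <- C + t(C)
  Ls <- lobar_connectivity(C, small)
  expect_equal(Ls["frontal", "frontal"], 0.4)
  expect_equal(Ls["frontal", "temporal"], (0.2 + 0.6) / 4)
})
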