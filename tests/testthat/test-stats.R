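# Partial correlations, GLM contrasts, permutation correction and the
# three statistical suites.

test_that("partial correlation handles exact and null relationships", {
  set.seed(51)
  z <- rnorm(10)
  x <- rnorm(10)
  r1 <- partial_correlation(x, x, z)
  expect_equal(r1$r, 1)
  expect_lt(r1$p, 1e-10)
  n <- 2000
  r0 <- partial_correlation(rnorm(n), rnorm(n), rnorm(n))
  expect_lt(abs(r0$r), 0.1)
  expect_equal(r0$dof, n - 3)
  expect_error(partial_correlation(z, rep(1, 10), x), "zero residual")
  expect_error(partial_correlation(rnorm(4), rnorm(4), cbind(rnorm(4), rnorm(4))),
               "n >=")
})

test_that("the printed patient table gives a negative MMSE-Tau partial r", {
  t1 <- read.csv(taugraph_example("table1_patients.csv"))
  res <- partial_correlation(t1$global_uptake, t1$mmse, t1$age,
                             alternative = "less")
  expect_lt(res$r, 0)
  expect_equal(res$dof, 9)
})

test_that("glm_contrast equals the closed-form OLS solution", {
  # 6-observation design solved symbolically via solve()
  d <- data.frame(y = c(1.2, 2.1, 2.9, 4.2, 4.8, 6.3),
                  x = c(1, 2, 3, 4, 5, 6),
                  z = c(0.1, -0.2, 0.3, 0, -0.1, 0.2))
  X <- cbind(1, d$x, d$z)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  res <- d$y - X %*% beta
  se <- sqrt(drop(crossprod(res)) / 3 * solve(t(X) %*% X)[2, 2])
  fit <- glm_contrast(d, "y", "x", "z")
  expect_equal(fit$estimate, beta[2], tolerance = 1e-12)
  expect_equal(fit$t, beta[2] / se, tolerance = 1e-12)
  expect_equal(fit$dof, 3)
  # noiseless recovery
  d2 <- data.frame(y = 2 * (1:10) + rnorm(10, 0, 1e-10), x = 1:10)
  fit2 <- glm_contrast(d2, "y", "x")
  expect_equal(fit2$estimate, 2, tolerance = 1e-6)
  expect_gt(abs(fit2$t), 1e6)
  # orthogonal predictor: t near zero at large n
  set.seed(52)
  d3 <- data.frame(y = rnorm(2000), x = rnorm(2000))
  expect_lt(abs(glm_contrast(d3, "y", "x")$t), 3)
})

test_that("GLM t equals the partial-correlation t for a shared design", {
  set.seed(53)
  d <- data.frame(y = rnorm(15), x = rnorm(15), a = rnorm(15), b = rnorm(15))
  g <- glm_contrast(d, "y", "x", c("a", "b"))
  p <- partial_correlation(d$x, d$y, d[, c("a", "b")])
  expect_equal(g$t, p$t, tolerance = 1e-10)
  expect_equal(g$dof, p$dof)
})

test_that("permutation p values respect their bounds and conventions", {
  set.seed(54)
  n <- 16
  X <- cbind(1, rnorm(n))
  tests <- lapply(1:6, function(k) list(y = rnorm(n), X = X, j = 2L,
                                        id = paste0("t", k)))
  res <- permutation_correct(tests, n_perm = 199, seed = 1)
  expect_true(all(res$p_uncorrected > 0))
  expect_true(all(res$p_corrected <= 1))
  expect_true(all(res$p_corrected >= res$p_uncorrected - 1e-12))
  # corrected p is monotone nonincreasing in |t| (max-statistic property)
  ord <- order(abs(res$t), decreasing = TRUE)
  expect_true(all(diff(res$p_corrected[ord]) >= -1e-12))
  # single-test family: corrected equals uncorrected
  solo <- permutation_correct(tests[1], n_perm = 199, seed = 1)
  expect_equal(solo$p_corrected, solo$p_uncorrected)
  expect_error(permutation_correct(list(), 100, 1), "empty")
  expect_warning(permutation_correct(tests[1], n_perm = 50, seed = 1), "coarse")
})

make_unit_metrics <- function(sim) sim$metrics

test_that("group contrasts are exactly null for mirrored groups", {
  # controls are a relabeled copy of the patients with identical covariates
  units <- c("parietal", "occipital")
  set.seed(55)
  vals <- tidyr::expand_grid(subject_id = sprintf("P%02d", 1:6),
                             visit = "baseline", band = "beta",
                             unit = units, metric = "closeness_centrality")
  vals$value <- rnorm(nrow(vals))
  mirrored <- vals
  mirrored$subject_id <- sub("P", "C", mirrored$subject_id)
  um <- rbind(vals, mirrored)
  covs <- data.frame(subject_id = c(sprintf("P%02d", 1:6), sprintf("C%02d", 1:6)),
                     group = rep(c("patient", "control"), each = 6),
                     age = rep(60 + 1:6, 2), site = "A")
  res <- suppressWarnings(group_contrast_suite(um, covs, n_perm = 100, seed = 1))
  expect_true(all(abs(res$t) < 1e-10))
})

test_that("the tau suite flags degenerate tau and recovers injected slopes", {
  units <- paste0("u", 1:6)
  cells <- data.frame(unit = "u2", band = "beta", metric = "closeness_centrality")
  sim <- simulate_metric_study(units, bands = c("alpha", "beta"),
                               metrics = "closeness_centrality",
                               effect_cells = cells, seed = 77)
  res <- tau_association_suite(sim$metrics, sim$tau, sim$covariates,
                               sim$atrophy, n_perm = 500, seed = 2)
  hit <- res[res$unit == "u2" & res$band == "beta", ]
  expect_lt(hit$estimate, 0)
  expect_lt(hit$p_corrected, 0.05)
  # constant tau across subjects for every unit is untestable
  tau_const <- sim$tau
  tau_const$tau <- 0.2
  expect_error(suppressWarnings(
    tau_association_suite(sim$metrics, tau_const, sim$covariates,
                          sim$atrophy, n_perm = 100, seed = 2)
  ), "constant")
})

test_that("longitudinal contrasts are zero for identical visits", {
  units <- c("frontal", "occipital")
  sim <- simulate_metric_study(units, bands = "delta",
                               metrics = "eigenvector_centrality",
                               visit_effect = 0, seed = 78)
  um <- sim$metrics
  # force identical visits
  base <- um[um$visit == "baseline", ]
  m6 <- um[um$visit == "month6", ]
  m6$value <- base$value[match(paste(m6$subject_id, m6$unit),
                               paste(base$subject_id, base$unit))]
  res <- longitudinal_contrast(rbind(base, m6), sim$covariates,
                               n_perm = 100, seed = 3)
  expect_true(all(res$t == 0))
  # injected decline is detected with a negative t
  simd <- simulate_metric_study(units, bands = "delta",
                                metrics = "eigenvector_centrality",
                                tau_effect_beta = 0, visit_effect = -0.4,
                                seed = 79)
  resd <- longitudinal_contrast(simd$metrics, simd$covariates,
                                n_perm = 500, seed = 3)
  expect_true(all(resd$t < 0))
  expect_true(any(resd$p_corrected < 0.05))
  expect_error(longitudinal_contrast(base, sim$covariates, 100, 1),
               "paired")
})
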