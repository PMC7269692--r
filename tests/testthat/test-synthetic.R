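# Synthetic cohort generator: Tau maps, coupling targets, band series with
# known envelope correlations, cohort assembly.

test_that("tau maps hit the requested global level and stay nonnegative", {
  parc <- toy_parcellation()
  flat <- generate_tau_map(parc, 0.215, gradient = 0, seed = 1)
  expect_equal(unname(flat), rep(0.215, parc$n_parcels))
  m1 <- generate_tau_map(parc, 0.2, gradient = 0.8, seed = 5)
  expect_equal(mean(m1), 0.2, tolerance = 1e-9)
  expect_true(all(m1 >= 0))
  expect_gt(sd(m1), 0)
  # posterior loading: parietal/occipital above frontal on average
  post <- parc$parcels$lobe %in% c("parietal", "occipital")
  expect_gt(mean(m1[post]), mean(m1[parc$parcels$lobe == "frontal"]))
  expect_identical(m1, generate_tau_map(parc, 0.2, gradient = 0.8, seed = 5))
  expect_error(generate_tau_map(parc, -1), "positive")
})

test_that("coupling targets are block-structured, PSD and tau-monotone", {
  modules <- rep(1:3, each = 4)
  C0 <- generate_envelope_coupling(modules, within_r = 0.4, between_r = 0.1)
  expect_equal(C0[1, 2], 0.4)
  expect_equal(C0[1, 5], 0.1)
  expect_equal(diag(C0), rep(1, 12))
  expect_false(attr(C0, "projected"))
  # degenerate single-module case
  C1 <- generate_envelope_coupling(modules, within_r = 0.3, between_r = 0.3)
  expect_true(all(abs(C1[upper.tri(C1)] - 0.3) < 1e-12))
  # tau decoupling: high-tau node has weaker mean coupling than tau-free node
  tau <- rep(0, 12)
  tau[1] <- 0.3
  Cb <- generate_envelope_coupling(modules, 0.4, 0.1, tau = tau, beta = -1)
  mean_off <- function(C, i) mean(C[i, -i])
  expect_lt(mean_off(Cb, 1), mean_off(Cb, 2))
  ev <- eigen(Cb, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_error(generate_envelope_coupling(modules, 0.1, 0.4), "between_r")
})

test_that("band series recover prescribed envelope correlations", {
  band <- canonical_bands()$alpha
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- 0.8
  s <- generate_band_series(C, band, fs = 200, duration = 300, seed = 3)
  expect_equal(dim(s$data), c(4, 60000))
  A <- aec(hilbert_envelope(epoch(s, 4)))
  expect_lt(abs(A$values[1, 2] - 0.8), 0.15)
  expect_lt(abs(A$values[3, 4]), 0.1)
  expect_lt(abs(A$values[1, 3]), 0.1)
  # determinism
  s2 <- generate_band_series(C, band, fs = 200, duration = 300, seed = 3)
  expect_identical(s$data, s2$data)
  expect_error(generate_band_series(C, canonical_bands()$delta, duration = 50),
               "10 cycles")
  expect_error(generate_band_series(C, band, leakage_strength = 1), "leakage")
})

test_that("estimation error shrinks as the recording doubles", {
  band <- canonical_bands()$alpha
  C <- generate_envelope_coupling(rep(1:2, each = 3), 0.4, 0.1)
  mae <- function(duration) {
    errs <- sapply(1:3, function(k) {
      s <- generate_band_series(C, band, duration = duration, seed = 40 + k)
      A <- aec(hilbert_envelope(epoch(s, 4)))
      target <- s$calibration$achievable
      mean(abs(A$values[upper.tri(C)] - target[upper.tri(C)]))
    })
    mean(errs)
  }
  expect_lt(mae(240), mae(60))
})

test_that("leakage inflates naive AEC and orthogonalization removes it", {
  band <- canonical_bands()$alpha
  C0 <- diag(6)
  s <- generate_band_series(C0, band, duration = 60, leakage_strength = 0.4,
                            seed = 8)
  naive <- aec(hilbert_envelope(epoch(s, 4)))
  corrected <- aec(hilbert_envelope(epoch(symmetric_orthogonalize(s), 4)))
  m <- function(A) mean(abs(A$values[upper.tri(A$values)]))
  expect_gt(m(naive), m(corrected))
})

test_that("cohorts have the designed sizes, visits and covariate ranges", {
  parc <- toy_parcellation()
  spec <- cohort_spec(parc, duration = 60, bands = canonical_bands()["alpha"],
                      seed = 4)
  cohort <- generate_cohort(spec)
  base <- subset(cohort$subjects, visit == "baseline")
  expect_equal(nrow(base), 24)
  expect_equal(sum(cohort$subjects$visit == "month6"), 9)
  pat <- subset(base, group == "patient")
  con <- subset(base, group == "control")
  expect_true(all(pat$mmse >= 20))
  expect_true(all(con$mmse >= 28))
  expect_true(all(cohort$tau >= 0))
  pg <- rowMeans(cohort$tau[pat$subject_id, ])
  expect_true(all(pg >= 0.12 - 1e-9 & pg <= 0.31 + 1e-9))
  # same seed twice: identical covariate tables
  cohort2 <- generate_cohort(spec)
  expect_identical(cohort$subjects, cohort2$subjects)
  expect_identical(cohort$tau, cohort2$tau)
  # follow-up restriction
  spec9 <- cohort_spec(parc, n_followup = 3, duration = 60,
                       bands = canonical_bands()["alpha"], seed = 4)
  expect_equal(sum(generate_cohort(spec9)$subjects$visit == "month6"), 3)
  expect_error(cohort_spec(parc, duration = 0.2, fs = 200), "infeasible")
})

test_that("cohort series are reproducible and tau-decoupled for patients", {
  parc <- tiny_parcellation()
  spec <- cohort_spec(parc, n_patients = 2, n_controls = 2, n_followup = 2,
                      duration = 30, bands = canonical_bands()["alpha"],
                      leakage_strength = 0, seed = 11)
  cohort <- generate_cohort(spec)
  s1 <- cohort_band_series(cohort, "P01", "baseline", "alpha")
  s2 <- cohort_band_series(cohort, "P01", "baseline", "alpha")
  expect_identical(s1$data, s2$data)
  expect_error(cohort_band_series(cohort, "C01", "month6", "alpha"), "no record")
  # patient coupling is weakened relative to control coupling
  Cp <- cohort$coupling[["P01.baseline"]]
  Cc <- cohort$coupling[["C01.baseline"]]
  expect_lt(mean(Cp[upper.tri(Cp)]), mean(Cc[upper.tri(Cc)]))
})

test_that("the metric-level simulator is deterministic and injects effects", {
  units <- paste0("u", 1:4)
  sim <- simulate_metric_study(units, bands = "beta", metrics = "closeness_centrality",
                               seed = 6)
  sim2 <- simulate_metric_study(units, bands = "beta", metrics = "closeness_centrality",
                                seed = 6)
  expect_identical(sim$metrics, sim2$metrics)
  expect_equal(nrow(sim$covariates), 24)
  # null generator: no group, tau or visit effect
  null <- simulate_metric_study(units, bands = "beta", tau_effect_beta = 0,
                                metrics = "closeness_centrality", seed = 6)
  expect_equal(length(unique(null$metrics$visit)), 2)
  # injected cell effect increases the spread of patient values in that cell
  cells <- data.frame(unit = "u1", band = "beta", metric = "closeness_centrality")
  eff <- simulate_metric_study(units, bands = "beta", metrics = "closeness_centrality",
                               tau_effect_beta = -8, effect_cells = cells, seed = 6)
  m_eff <- subset(merge(eff$metrics, eff$covariates), group == "patient" & unit == "u1")
  m_oth <- subset(merge(eff$metrics, eff$covariates), group == "patient" & unit == "u2")
  expect_gt(sd(m_eff$value), sd(m_oth$value))
})
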