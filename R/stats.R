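# Association statistics: partial correlations, GLM contrasts, and
# permutation-based familywise correction (max-|t| across each metric's
# family of units x bands). Permutation schemes: Freedman-Lane residual
# permutation for continuous predictors, group-label permutation within
# site strata for group contrasts, and sign-flipping for paired contrasts.

ols_t <- function(y, X, j) {
  n <- length(y)
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) stop("design matrix is rank deficient after dummy coding")
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  dof <- n - p
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sum(res^2) / dof * XtXinv[j, j])
  t <- if (se == 0) {
    if (beta[j] == 0) 0 else sign(beta[j]) * Inf  # exact fit
  } else beta[j] / se
  list(estimate = unname(beta[j]), se = unname(se), t = unname(t), dof = dof)
}

#' Pearson partial correlation
#'
#' Correlation of the residuals of `x` and `y` after regressing out the
#' covariates from both; `dof = n - 2 - k` and the p value comes from the
#' t transform `t = r * sqrt(dof) / sqrt(1 - r^2)`.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric vector, matrix or data frame of covariates
#'   (or `NULL` for a plain correlation).
#' @param alternative `"two.sided"`, `"less"` (one-tailed negative) or
#'   `"greater"` (one-tailed positive).
#' @return Tibble `(r, t, dof, p, alternative)`.
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates)) {
    Z <- matrix(1, n, 1)
  } else {
    Z <- cbind(1, as.matrix(as.data.frame(covariates)))
  }
  k <- ncol(Z) - 1
  if (n < k + 3) stop("need n >= covariate count + 3")
  rx <- resid(lm.fit(Z, x))
  ry <- resid(lm.fit(Z, y))
  if (sd(rx) <= 1e-12 * max(abs(x), 1) || sd(ry) <= 1e-12 * max(abs(y), 1)) {
    stop("zero residual variance")
  }
  r <- cor(rx, ry)
  dof <- n - 2 - k
  t <- r * sqrt(dof) / sqrt(1 - r^2)
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(t), dof),
              less = pt(t, dof),
              greater = pt(t, dof, lower.tail = FALSE))
  tibble::tibble(r = r, t = t, dof = dof, p = p, alternative = alternative)
}

#' @importFrom stats lm.fit qr.coef
NULL

#' GLM contrast for one predictor of interest
#'
#' Ordinary least squares of `response` on the predictor of interest plus
#' covariates (factors dummy-coded); returns the predictor's estimate and
#' t statistic with `dof = n - p`.
#'
#' @param data Data frame holding all variables.
#' @param response,predictor Column names.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return Tibble `(estimate, se, t, dof, p)` (two-sided p).
#' @export
glm_contrast <- function(data, response, predictor, covariates = character()) {
  data <- as.data.frame(data)
  f <- stats::reformulate(c(predictor, covariates))
  X <- model.matrix(f, data)
  y <- data[[response]]
  j <- grep(paste0("^", predictor), colnames(X))[1]
  if (is.na(j)) stop("predictor column not found in design")
  fit <- ols_t(y, X, j)
  tibble::tibble(estimate = fit$estimate, se = fit$se, t = fit$t,
                 dof = fit$dof, p = 2 * pt(-abs(fit$t), fit$dof))
}

# Observed and permuted t statistics for one test under Freedman-Lane or
# sign-flip permutation of the reduced-model residuals. `perm` is either an
# index matrix (n_perm x n) or a sign matrix (n_perm x n of +/-1).
perm_t_matrix <- function(y, X, j, perm, flip = FALSE) {
  n <- length(y)
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) stop("design matrix is rank deficient after dummy coding")
  Q <- qr.Q(qx)
  XtXinv <- chol2inv(qr.R(qx))
  w <- (XtXinv %*% t(X))[j, ]
  g <- XtXinv[j, j]
  Z <- X[, -j, drop = FALSE]
  qz <- qr(Z)
  fitz <- drop(Z %*% qr.coef(qz, y))
  resz <- y - fitz
  t_of <- function(Y) {
    est <- drop(crossprod(w, Y))
    rss <- colSums(Y^2) - colSums(crossprod(Q, Y)^2)
    rss <- pmax(rss, 0)
    tt <- est / sqrt(rss / (n - p) * g)
    ifelse(rss == 0, ifelse(est == 0, 0, sign(est) * Inf), tt)
  }
  obs <- t_of(matrix(y, n, 1))
  Ystar <- if (flip) {
    matrix(fitz, n, nrow(perm)) + resz * t(perm)
  } else {
    matrix(fitz, n, nrow(perm)) + matrix(resz[t(perm)], n, nrow(perm))
  }
  list(obs = obs, perm = t_of(Ystar),
       estimate = drop(crossprod(w, y)), dof = n - p)
}

#' Permutation-based familywise correction over a family of GLM tests
#'
#' Runs the requested permutation scheme with shared permutations across the
#' family and corrects by the max-|t| distribution:
#' `p_corrected = (1 + #\{max-|t*| >= |t|\}) / (n_perm + 1)`. Per-test
#' uncorrected p values come from each test's own permutation distribution
#' with the same +1 convention (so no p is ever 0).
#'
#' @param tests List of tests, each `list(y, X, j, id)` with `j` the column
#'   index of the predictor of interest; all tests must share the subject
#'   count.
#' @param n_perm Number of permutations (default 500; < 100 warns).
#' @param seed Integer RNG seed.
#' @param scheme `"freedman_lane"` (permute reduced-model residuals),
#'   `"group_within_site"` (permute the predictor column within `strata`) or
#'   `"sign_flip"` (flip reduced-model residual signs; for paired
#'   contrasts).
#' @param strata Stratum labels for `"group_within_site"`.
#' @return Tibble `(id, estimate, t, dof, p_uncorrected, p_corrected,
#'   n_permutations)`.
#' @export
permutation_correct <- function(tests, n_perm = 500, seed = 1,
                                scheme = c("freedman_lane", "group_within_site",
                                           "sign_flip"),
                                strata = NULL) {
  scheme <- match.arg(scheme)
  if (length(tests) == 0) stop("empty test family")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse permutation p")
  n <- length(tests[[1]]$y)
  K <- length(tests)
  set.seed(seed)
  if (scheme == "sign_flip") {
    perm <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  } else if (scheme == "freedman_lane") {
    perm <- t(replicate(n_perm, sample.int(n)))
  } else {
    if (is.null(strata)) stop("group_within_site needs strata")
    perm <- t(replicate(n_perm, {
      idx <- seq_len(n)
      for (s in unique(strata)) {
        sel <- which(strata == s)
        idx[sel] <- sel[sample.int(length(sel))]
      }
      idx
    }))
  }
  obs <- numeric(K); est <- numeric(K); dof <- numeric(K)
  Tperm <- matrix(0, n_perm, K)
  if (scheme == "group_within_site") {
    for (k in seq_len(K)) {
      tk <- tests[[k]]
      fit <- ols_t(tk$y, tk$X, tk$j)
      obs[k] <- fit$t; est[k] <- fit$estimate; dof[k] <- fit$dof
    }
    shared <- all(vapply(tests, function(t) identical(t$X, tests[[1]]$X) &&
                           t$j == tests[[1]]$j, logical(1)))
    if (shared) {
      # one design per permutation, all responses at once
      X0 <- tests[[1]]$X; j0 <- tests[[1]]$j; p <- ncol(X0)
      Y <- vapply(tests, function(t) t$y, numeric(n))
      for (b in seq_len(n_perm)) {
        Xs <- X0
        Xs[, j0] <- Xs[perm[b, ], j0]
        qx <- qr(Xs)
        Q <- qr.Q(qx)
        XtXinv <- chol2inv(qr.R(qx))
        w <- (XtXinv %*% t(Xs))[j0, ]
        estb <- drop(crossprod(w, Y))
        rss <- pmax(colSums(Y^2) - colSums(crossprod(Q, Y)^2), 0)
        Tperm[b, ] <- estb / sqrt(rss / (n - p) * XtXinv[j0, j0])
      }
    } else {
      for (b in seq_len(n_perm)) {
        for (k in seq_len(K)) {
          tk <- tests[[k]]
          Xs <- tk$X
          Xs[, tk$j] <- Xs[perm[b, ], tk$j]
          Tperm[b, k] <- ols_t(tk$y, Xs, tk$j)$t
        }
      }
    }
  } else {
    for (k in seq_len(K)) {
      tk <- tests[[k]]
      r <- perm_t_matrix(tk$y, tk$X, tk$j, perm, flip = scheme == "sign_flip")
      obs[k] <- r$obs; est[k] <- r$estimate; dof[k] <- r$dof
      Tperm[, k] <- r$perm
    }
  }
  maxT <- apply(abs(Tperm), 1, max)
  p_unc <- vapply(seq_len(K), function(k) {
    (1 + sum(abs(Tperm[, k]) >= abs(obs[k]))) / (n_perm + 1)
  }, numeric(1))
  p_cor <- vapply(seq_len(K), function(k) {
    (1 + sum(maxT >= abs(obs[k]))) / (n_perm + 1)
  }, numeric(1))
  tibble::tibble(
    id = vapply(tests, function(t) t$id, character(1)),
    estimate = est, t = obs, dof = dof,
    p_uncorrected = p_unc, p_corrected = p_cor,
    n_permutations = n_perm
  )
}

#' Aggregate nodal metrics to analysis units
#'
#' Aggregates a nodal metric table (one value per parcel) to whole-brain,
#' lobar or ROI units for the statistical suites. ROI units are bilateral
#' regions (hemisphere-averaged) restricted to an [select_rois()] set.
#'
#' @param metric_tbl Tibble with columns `subject_id, visit, band, node,
#'   metric` and a value column (default `ratio`, the null-normalized
#'   metric).
#' @param parc A [load_parcellation()] object; `node` is the 0-based
#'   `parcel_id`.
#' @param level `"whole_brain"`, `"lobe"` or `"roi"`.
#' @param rois An [select_rois()] set (required for `level = "roi"`).
#' @param value_col Which column of `metric_tbl` to aggregate.
#' @return Tibble `(subject_id, visit, band, unit, metric, value)`.
#' @export
aggregate_metrics <- function(metric_tbl, parc, level = c("lobe", "roi", "whole_brain"),
                              rois = NULL, value_col = "ratio") {
  level <- match.arg(level)
  metric_tbl <- dplyr::rename(metric_tbl, value = dplyr::all_of(value_col))
  key <- parc$parcels[, c("parcel_id", "lobe", "region_id")]
  df <- dplyr::left_join(metric_tbl, key, by = c(node = "parcel_id"))
  if (level == "whole_brain") {
    df |>
      dplyr::group_by(.data$subject_id, .data$visit, .data$band, .data$metric) |>
      dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
      dplyr::mutate(unit = "whole_brain") |>
      dplyr::select("subject_id", "visit", "band", "unit", "metric", "value")
  } else if (level == "lobe") {
    df |>
      dplyr::group_by(.data$subject_id, .data$visit, .data$band, .data$metric,
                      unit = .data$lobe) |>
      dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
      dplyr::select("subject_id", "visit", "band", "unit", "metric", "value")
  } else {
    if (is.null(rois)) stop("level = 'roi' needs a roi_set")
    reg <- regions(parc)
    df |>
      dplyr::group_by(.data$subject_id, .data$visit, .data$band, .data$metric,
                      region_id = .data$region_id) |>
      dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
      dplyr::filter(.data$region_id %in% rois$region_ids) |>
      dplyr::mutate(unit = reg$region[match(.data$region_id, reg$region_id)]) |>
      dplyr::select("subject_id", "visit", "band", "unit", "metric", "value")
  }
}

# Build the shared covariate design for a set of subjects: intercept, age,
# site dummies (plus optional extra numeric columns bound by the caller).
covariate_design <- function(cov_df) {
  cov_df$site <- factor(cov_df$site)
  if (nlevels(cov_df$site) > 1) {
    model.matrix(~ age + site, cov_df)
  } else {
    model.matrix(~ age, cov_df)
  }
}

# Family-wise listwise deletion: drop tests that are missing for everyone
# (e.g. a band that failed upstream), then drop subjects missing any
# remaining value, so every test in the family shares the same subjects
# (required for shared permutations). Deletions are logged as warnings.
family_response_matrix <- function(dm, subject_ids) {
  keys <- unique(paste(dm$unit, dm$band, sep = "\r"))
  Y <- matrix(NA_real_, length(subject_ids), length(keys),
              dimnames = list(subject_ids, keys))
  idx <- cbind(match(dm$subject_id, subject_ids),
               match(paste(dm$unit, dm$band, sep = "\r"), keys))
  ok <- !is.na(idx[, 1])
  Y[idx[ok, , drop = FALSE]] <- dm$value[ok]
  all_missing <- colSums(!is.na(Y)) == 0
  if (any(all_missing)) {
    warning("tests with no data dropped: ",
            paste(gsub("\r", "/", colnames(Y)[all_missing]), collapse = ", "))
    Y <- Y[, !all_missing, drop = FALSE]
  }
  incomplete <- rowSums(is.na(Y)) > 0
  if (any(incomplete)) {
    warning("subjects removed by listwise deletion: ",
            paste(rownames(Y)[incomplete], collapse = ", "))
    Y <- Y[!incomplete, , drop = FALSE]
  }
  Y
}

suite_result <- function(perm_tbl, metric, suite) {
  parts <- strsplit(perm_tbl$id, "\r")
  tibble::tibble(
    unit = vapply(parts, `[`, character(1), 1),
    band = vapply(parts, `[`, character(1), 2),
    metric = metric,
    estimate = perm_tbl$estimate,
    t = perm_tbl$t,
    dof = perm_tbl$dof,
    p_uncorrected = perm_tbl$p_uncorrected,
    p_corrected = perm_tbl$p_corrected,
    family_id = paste(suite, metric, sep = ":"),
    n_permutations = perm_tbl$n_permutations
  )
}

#' Patient-control group contrasts over units and bands
#'
#' One GLM per (unit, band, metric) of the unit-level metric on group with
#' age and site covariates; the correction family is all units x bands
#' within a metric, permuting group labels within site strata.
#'
#' @param unit_metrics Tibble from [aggregate_metrics()] (baseline visit is
#'   used).
#' @param covariates Tibble `(subject_id, group, age, site)`.
#' @param n_perm,seed Permutation parameters.
#' @return StatResult tibble `(unit, band, metric, estimate, t, dof,
#'   p_uncorrected, p_corrected, family_id, n_permutations)`.
#' @export
group_contrast_suite <- function(unit_metrics, covariates, n_perm = 500, seed = 1) {
  um <- dplyr::filter(unit_metrics, .data$visit == "baseline")
  cov0 <- dplyr::semi_join(covariates, um, by = "subject_id")
  if (length(unique(cov0$group)) < 2) stop("both groups must be present")
  out <- list()
  for (m in unique(um$metric)) {
    dm <- dplyr::filter(um, .data$metric == m)
    Y <- family_response_matrix(dm, cov0$subject_id)
    cov <- cov0[match(rownames(Y), cov0$subject_id), ]
    Z <- covariate_design(cov)
    X <- cbind(Z[, 1, drop = FALSE], group = as.numeric(cov$group == "patient"),
               Z[, -1, drop = FALSE])
    tests <- lapply(colnames(Y), function(key) {
      list(y = Y[, key], X = X, j = 2L, id = key)
    })
    res <- permutation_correct(tests, n_perm = n_perm, seed = seed,
                               scheme = "group_within_site", strata = cov$site)
    out[[m]] <- suite_result(res, m, "group")
  }
  dplyr::bind_rows(out)
}

#' Tau-metric association suite (patients)
#'
#' One GLM per (unit, band, metric) of the unit-level metric on local Tau
#' (BP_ND) with age, site and (optionally) local gray-matter atrophy as
#' covariates, in the patient group at baseline. Freedman-Lane residual
#' permutation; max-|t| family correction per metric.
#'
#' @param unit_metrics Tibble from [aggregate_metrics()], patients baseline.
#' @param tau Tibble `(subject_id, unit, tau)` at the matching level.
#' @param covariates Tibble `(subject_id, group, age, site)`.
#' @param atrophy Optional tibble `(subject_id, unit, atrophy)`.
#' @param n_perm,seed Permutation parameters.
#' @return StatResult tibble as in [group_contrast_suite()].
#' @export
tau_association_suite <- function(unit_metrics, tau, covariates, atrophy = NULL,
                                  n_perm = 500, seed = 1) {
  um <- dplyr::filter(unit_metrics, .data$visit == "baseline")
  cov0 <- covariates |>
    dplyr::filter(.data$group == "patient") |>
    dplyr::semi_join(um, by = "subject_id")
  if (nrow(cov0) == 0) stop("no patient records")
  out <- list()
  dropped <- character()
  for (m in unique(um$metric)) {
    dm <- dplyr::filter(um, .data$metric == m,
                        .data$subject_id %in% cov0$subject_id)
    Y <- family_response_matrix(dm, cov0$subject_id)
    cov <- cov0[match(rownames(Y), cov0$subject_id), ]
    Z <- covariate_design(cov)
    tests <- list()
    for (key in colnames(Y)) {
      unit <- strsplit(key, "\r")[[1]][1]
      tu <- tau$tau[match(paste(cov$subject_id, unit),
                          paste(tau$subject_id, tau$unit))]
      if (anyNA(tu)) stop("missing Tau for unit ", unit)
      if (sd(tu) == 0) {
        dropped <- c(dropped, unit)
        next
      }
      X <- cbind(Z[, 1, drop = FALSE], tau = tu, Z[, -1, drop = FALSE])
      if (!is.null(atrophy)) {
        au <- atrophy$atrophy[match(paste(cov$subject_id, unit),
                                    paste(atrophy$subject_id, atrophy$unit))]
        if (anyNA(au)) stop("missing atrophy for unit ", unit)
        X <- cbind(X, atrophy = au)
      }
      tests[[length(tests) + 1]] <- list(y = Y[, key], X = X, j = 2L, id = key)
    }
    if (length(tests) == 0) stop("no testable units: Tau constant everywhere")
    res <- permutation_correct(tests, n_perm = n_perm, seed = seed,
                               scheme = "freedman_lane")
    out[[m]] <- suite_result(res, m, "tau")
  }
  if (length(dropped)) {
    warning("units with constant Tau dropped: ",
            paste(unique(dropped), collapse = ", "))
  }
  dplyr::bind_rows(out)
}

#' Longitudinal (month-6 minus baseline) contrasts
#'
#' Within-subject metric change tested against zero with age and site
#' covariates; permutation by random sign-flipping of the reduced-model
#' residuals of the subject differences.
#'
#' @param unit_metrics Tibble from [aggregate_metrics()] containing both
#'   visits for at least 2 subjects.
#' @param covariates Tibble `(subject_id, group, age, site)`.
#' @param n_perm,seed Permutation parameters.
#' @return StatResult tibble as in [group_contrast_suite()].
#' @export
longitudinal_contrast <- function(unit_metrics, covariates, n_perm = 500, seed = 1) {
  wide <- unit_metrics |>
    tidyr::pivot_wider(names_from = "visit", values_from = "value")
  if (!all(c("baseline", "month6") %in% names(wide))) stop("no paired subjects")
  wide <- dplyr::filter(wide, !is.na(.data$baseline), !is.na(.data$month6)) |>
    dplyr::mutate(diff = .data$month6 - .data$baseline)
  ids <- sort(unique(wide$subject_id))
  if (length(ids) < 2) stop("need >= 2 subjects with both visits")
  out <- list()
  for (m in unique(wide$metric)) {
    dm <- dplyr::filter(wide, .data$metric == m) |>
      dplyr::mutate(value = .data$diff)
    Y <- family_response_matrix(dm, ids)
    if (nrow(Y) < 2) stop("need >= 2 subjects with both visits")
    cov <- covariates[match(rownames(Y), covariates$subject_id), ]
    Z <- covariate_design(cov)
    # centre the covariates so the intercept is the covariate-adjusted mean
    # change (an uncentred age column would absorb the mean shift)
    X <- cbind(Z[, 1, drop = FALSE],
               scale(Z[, -1, drop = FALSE], center = TRUE, scale = FALSE))
    tests <- lapply(colnames(Y), function(key) {
      list(y = Y[, key], X = X, j = 1L, id = key)
    })
    res <- permutation_correct(tests, n_perm = n_perm, seed = seed,
                               scheme = "sign_flip")
    out[[m]] <- suite_result(res, m, "longitudinal")
  }
  dplyr::bind_rows(out)
}
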