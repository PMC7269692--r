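# End-to-end orchestration: simulate -> preprocess -> orthogonalize ->
# connect -> metrics -> stats -> report, with a run manifest for
# reproducibility. Processing streams one subject-band series at a time.

#' Pipeline configuration
#'
#' Defaults are the canonical analysis parameters: 4 s epochs, 200 Hz
#' analysis rate, 25% graph density, 500 null graphs, 500 permutations,
#' alpha 0.01, and the five canonical bands. Any argument supplied
#' explicitly is recorded as an override in the run manifest.
#'
#' @param parc A [load_parcellation()] object (default: the packaged
#'   98-parcel atlas).
#' @param n_patients,n_controls,n_followup Cohort sizes.
#' @param duration Recording seconds per subject.
#' @param epoch_seconds Epoch length (default 4).
#' @param target_fs Analysis sampling rate (default 200).
#' @param density Proportional threshold (default 0.25).
#' @param n_nulls Null graphs per subject-band (default 500).
#' @param n_permutations Permutations per statistical family (default 500).
#' @param alpha Significance level for reporting (default 0.01).
#' @param bands Which canonical bands to run (names).
#' @param levels Analysis levels for the statistical suites.
#' @param louvain_runs,null_louvain_runs Louvain restarts (observed / null).
#' @param tau_effect_beta,group_effect,visit_effect,leakage_strength
#'   Generator ground-truth parameters (see [cohort_spec()]).
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(parc = NULL, n_patients = 12, n_controls = 12,
                            n_followup = 9, duration = 300,
                            epoch_seconds = 4, target_fs = 200,
                            density = 0.25, n_nulls = 500,
                            n_permutations = 500, alpha = 0.01,
                            bands = c("delta", "theta", "alpha", "beta", "gamma"),
                            levels = c("whole_brain", "lobe", "roi"),
                            louvain_runs = 100, null_louvain_runs = 1,
                            tau_effect_beta = -1.0, group_effect = 0,
                            visit_effect = 0, leakage_strength = 0.3,
                            seed = 1) {
  supplied <- names(as.list(match.call()))[-1]
  if (is.null(parc)) parc <- load_parcellation(taugraph_example("atlas98.tsv"))
  if (density <= 0 || density >= 1) stop("density must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (epoch_seconds <= 0 || duration < epoch_seconds) {
    stop("duration must cover at least one epoch")
  }
  band_defs <- canonical_bands(target_fs)
  if (!all(bands %in% names(band_defs))) {
    stop("unknown bands: ", paste(setdiff(bands, names(band_defs)), collapse = ", "))
  }
  structure(
    list(parc = parc, n_patients = n_patients, n_controls = n_controls,
         n_followup = n_followup, duration = duration,
         epoch_seconds = epoch_seconds, target_fs = target_fs,
         density = density, n_nulls = n_nulls,
         n_permutations = n_permutations, alpha = alpha,
         bands = bands, band_defs = band_defs[bands], levels = levels,
         louvain_runs = louvain_runs, null_louvain_runs = null_louvain_runs,
         tau_effect_beta = tau_effect_beta, group_effect = group_effect,
         visit_effect = visit_effect, leakage_strength = leakage_strength,
         seed = as.integer(seed),
         overrides = setdiff(supplied, "parc")),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_config> %d+%d subjects, %d parcels, %g s, ",
                     "density %.2f, %d nulls, %d perms, alpha %.2g, bands: %s\n"),
              x$n_patients, x$n_controls, x$parc$n_parcels, x$duration,
              x$density, x$n_nulls, x$n_permutations, x$alpha,
              paste(x$bands, collapse = ",")))
  if (length(x$overrides)) cat("  overrides:", paste(x$overrides, collapse = ", "), "\n")
  invisible(x)
}

process_record <- function(cohort, config, subject_id, visit, band_name) {
  series <- cohort_band_series(cohort, subject_id, visit, band_name)
  band <- config$band_defs[[band_name]]
  if (length(band$notch)) series <- notch(series, band$notch)
  series <- epoch(series, config$epoch_seconds)
  if (series$fs > config$target_fs) series <- downsample(series, config$target_fs)
  series <- symmetric_orthogonalize(series)
  env <- hilbert_envelope(series)
  A <- aec(env)
  G <- proportional_threshold(A, config$density)
  sidx <- match(subject_id, rownames(cohort$tau))
  bidx <- match(band_name, config$bands)
  mseed <- (config$seed + 7717L * sidx + 13L * bidx +
              3L * match(visit, c("baseline", "month6"))) %% 2147483647L
  metrics <- compute_all_metrics(G, n_nulls = config$n_nulls,
                                 louvain_runs = config$louvain_runs,
                                 null_louvain_runs = config$null_louvain_runs,
                                 seed = mseed)
  list(
    metrics = dplyr::mutate(metrics, subject_id = subject_id, visit = visit,
                            band = band_name, .before = 1),
    lobar = lobar_connectivity(A, cohort$parc)
  )
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates the cohort, processes every subject-visit-band record through
#' the signal chain (notch, epoching, leakage correction, envelopes, AEC,
#' thresholding, null-normalized metrics), selects ROIs from the patient
#' group-mean Tau map, and runs the three statistical suites at the
#' configured levels. Failures are isolated per (subject, band) and
#' reported; the remaining records complete.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, [report()] is
#'   called and a run manifest (JSON) is written.
#' @return An object of class `taugraph_results`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  spec <- cohort_spec(
    parc = config$parc, n_patients = config$n_patients,
    n_controls = config$n_controls, n_followup = config$n_followup,
    duration = config$duration, fs = config$target_fs,
    bands = config$band_defs, leakage_strength = config$leakage_strength,
    tau_effect_beta = config$tau_effect_beta,
    group_effect = config$group_effect, visit_effect = config$visit_effect,
    seed = config$seed
  )
  cohort <- generate_cohort(spec)
  records <- tidyr::expand_grid(
    cohort$subjects[, c("subject_id", "visit")],
    band = config$bands
  )
  metric_rows <- list()
  lobar_sums <- NULL
  failures <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    res <- tryCatch(
      process_record(cohort, config, r$subject_id, r$visit, r$band),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        list(subject_id = r$subject_id, visit = r$visit, band = r$band,
             message = conditionMessage(res))
      next
    }
    metric_rows[[length(metric_rows) + 1]] <- res$metrics
    key <- paste(unique(cohort$subjects$group[cohort$subjects$subject_id == r$subject_id]),
                 r$band, sep = ".")
    if (is.null(lobar_sums)) lobar_sums <- list()
    if (is.null(lobar_sums[[key]])) {
      lobar_sums[[key]] <- list(sum = res$lobar, n = 1)
    } else {
      lobar_sums[[key]] <- list(sum = lobar_sums[[key]]$sum + res$lobar,
                                n = lobar_sums[[key]]$n + 1)
    }
  }
  if (length(metric_rows) == 0) stop("all records failed; nothing to analyse")
  nodal <- dplyr::bind_rows(metric_rows)
  # ROI selection from the patient group-mean regional Tau
  pat_ids <- cohort$subjects$subject_id[cohort$subjects$group == "patient" &
                                          cohort$subjects$visit == "baseline"]
  tau_parcel_mean <- colMeans(cohort$tau[unique(pat_ids), , drop = FALSE])
  tau_region <- bilateral_average(tau_parcel_mean, cohort$parc)
  rois <- select_rois(setNames(tau_region$value, tau_region$region_id), cohort$parc)
  reg <- regions(cohort$parc)
  # unit-level tau/atrophy tables for the association suite
  lobe_of_region <- setNames(reg$lobe, reg$region)
  tau_units <- list(); atrophy_units <- list()
  for (sid in rownames(cohort$tau)) {
    breg <- bilateral_average(cohort$tau[sid, ], cohort$parc)
    tau_units[[sid]] <- dplyr::bind_rows(
      tibble::tibble(subject_id = sid, unit = "whole_brain",
                     tau = mean(cohort$tau[sid, ])),
      lobe_aggregate(cohort$tau[sid, ], cohort$parc) |>
        dplyr::transmute(subject_id = sid, unit = .data$lobe, tau = .data$value),
      breg |>
        dplyr::filter(.data$region_id %in% rois$region_ids) |>
        dplyr::transmute(subject_id = sid, unit = .data$region, tau = .data$value)
    )
    areg <- cohort$atrophy[sid, ]
    atrophy_units[[sid]] <- dplyr::bind_rows(
      tibble::tibble(subject_id = sid, unit = "whole_brain", atrophy = mean(areg)),
      tibble::tibble(subject_id = sid, unit = unname(lobe_of_region[names(areg)]),
                     atrophy = unname(areg)) |>
        dplyr::group_by(.data$unit) |>
        dplyr::summarise(subject_id = sid, atrophy = mean(.data$atrophy),
                         .groups = "drop") |>
        dplyr::select("subject_id", "unit", "atrophy"),
      tibble::tibble(subject_id = sid, unit = names(areg), atrophy = unname(areg)) |>
        dplyr::filter(.data$unit %in% rois$regions)
    )
  }
  tau_units <- dplyr::bind_rows(tau_units)
  atrophy_units <- dplyr::bind_rows(atrophy_units)
  unit_metrics <- dplyr::bind_rows(lapply(config$levels, function(lv) {
    aggregate_metrics(nodal, cohort$parc, level = lv, rois = rois)
  }))
  covariates <- dplyr::distinct(cohort$subjects[, c("subject_id", "group", "age", "site")])
  stats <- list()
  stats$group <- group_contrast_suite(unit_metrics, covariates,
                                      n_perm = config$n_permutations,
                                      seed = config$seed + 1L)
  stats$tau <- tau_association_suite(
    dplyr::semi_join(unit_metrics,
                     tibble::tibble(subject_id = unique(pat_ids)),
                     by = "subject_id"),
    tau_units, covariates, atrophy = atrophy_units,
    n_perm = config$n_permutations, seed = config$seed + 2L
  )
  stats$longitudinal <- if (config$n_followup >= 2) {
    longitudinal_contrast(unit_metrics, covariates,
                          n_perm = config$n_permutations,
                          seed = config$seed + 3L)
  } else NULL
  lobar <- lapply(lobar_sums, function(x) x$sum / x$n)
  manifest <- list(
    package_version = as.character(utils::packageVersion("taugraph")),
    seed = config$seed,
    parameters = list(
      epoch_seconds = config$epoch_seconds, target_fs = config$target_fs,
      density = config$density, n_nulls = config$n_nulls,
      n_permutations = config$n_permutations, alpha = config$alpha,
      bands = lapply(config$band_defs, function(b) c(low = b$low, high = b$high))
    ),
    overrides = config$overrides,
    n_records = nrow(records), n_failed = length(failures),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  results <- structure(
    list(config = config, covariates = cohort$subjects, nodal_metrics = nodal,
         unit_metrics = unit_metrics, stats = stats, rois = rois,
         lobar_connectivity = lobar, tau_units = tau_units,
         failures = failures, manifest = manifest),
    class = "taugraph_results"
  )
  if (!is.null(out_dir)) results <- report(results, out_dir)
  results
}

#' @export
print.taugraph_results <- function(x, ...) {
  cat(sprintf("<taugraph_results> %d nodal metric rows, %d unit tests, %d failures\n",
              nrow(x$nodal_metrics),
              sum(vapply(x$stats, function(s) if (is.null(s)) 0L else nrow(s), integer(1))),
              length(x$failures)))
  invisible(x)
}

#' Write result tables, figures and the run manifest
#'
#' Exports the covariate, nodal-metric and statistical tables as CSV,
#' renders unit x band t-value grids per suite (significant cells at the
#' configured alpha outlined), writes the ROI set as JSON and the manifest
#' with per-file MD5 checksums.
#'
#' @param results A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return The results object with `manifest$checksums` filled, invisibly.
#' @export
report <- function(results, out_dir) {
  stopifnot(inherits(results, "taugraph_results"))
  if (nrow(results$unit_metrics) == 0) stop("empty results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  wr(results$covariates, "covariates.csv")
  wr(results$nodal_metrics, "nodal_metrics.csv")
  wr(results$unit_metrics, "unit_metrics.csv")
  for (s in names(results$stats)) {
    if (!is.null(results$stats[[s]])) wr(results$stats[[s]], paste0("stats_", s, ".csv"))
  }
  write_roi_set(results$rois, file.path(out_dir, "rois.json"))
  paths[["rois.json"]] <- file.path(out_dir, "rois.json")
  for (s in names(results$stats)) {
    if (is.null(results$stats[[s]])) next
    fig <- plot_stat_grid(results$stats[[s]], alpha = results$config$alpha)
    ggplot2::ggsave(file.path(out_dir, paste0("tmap_", s, ".png")), fig,
                    width = 9, height = 6, dpi = 120)
  }
  results$manifest$checksums <- as.list(tools::md5sum(unlist(paths)))
  names(results$manifest$checksums) <- names(paths)
  jsonlite::write_json(results$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
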