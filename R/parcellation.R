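# Node space: parcels, hemispheres, lobes, bilateral regions, ROI subset.

LOBES <- c("frontal", "temporal", "parietal", "occipital", "limbic")

#' Load and validate a parcellation table
#'
#' A parcellation assigns every parcel a name, hemisphere, lobe and a
#' bilateral region index shared by left/right homologues. Row order defines
#' the 0-based `parcel_id`. The packaged 98-parcel cortical atlas table
#' (49 bilateral regions including the hippocampi) is available via
#' `taugraph_example("atlas98.tsv")`.
#'
#' @param table Path to a TSV with columns `name`, `hemisphere` (`L`/`R`,
#'   `left`/`right`), `lobe` (frontal/temporal/parietal/occipital/limbic) and
#'   `region_id`, or a data frame with those columns.
#' @return An object of class `parcellation` with elements `parcels`
#'   (a tibble, one row per parcel) and `n_parcels`.
#' @export
load_parcellation <- function(table) {
  df <- if (is.character(table)) read.delim(table, stringsAsFactors = FALSE) else as.data.frame(table)
  required <- c("name", "hemisphere", "lobe", "region_id")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("parcellation table lacks columns: ", paste(missing, collapse = ", "))
  hemi <- tolower(df$hemisphere)
  hemi[hemi == "l"] <- "left"
  hemi[hemi == "r"] <- "right"
  if (!all(hemi %in% c("left", "right"))) {
    stop("unknown hemisphere labels: ", paste(unique(df$hemisphere[!hemi %in% c("left", "right")]), collapse = ", "))
  }
  lobe <- tolower(df$lobe)
  if (!all(lobe %in% LOBES)) {
    stop("unknown lobe labels: ", paste(unique(df$lobe[!lobe %in% LOBES]), collapse = ", "))
  }
  key <- paste(df$name, hemi)
  if (anyDuplicated(key)) {
    stop("duplicate (name, hemisphere) rows: ", paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  counts <- table(df$region_id)
  if (any(counts > 2)) {
    stop("region_id mapped to more than 2 parcels: ", paste(names(counts)[counts > 2], collapse = ", "))
  }
  parcels <- tibble::tibble(
    parcel_id = seq_len(nrow(df)) - 1L,
    name = as.character(df$name),
    hemisphere = hemi,
    lobe = lobe,
    region_id = as.integer(df$region_id)
  )
  structure(list(parcels = parcels, n_parcels = nrow(parcels)), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d parcels, %d bilateral regions, lobes: %s\n",
              x$n_parcels, length(unique(x$parcels$region_id)),
              paste(sort(unique(x$parcels$lobe)), collapse = ", ")))
  invisible(x)
}

#' Region lookup for a parcellation
#'
#' @param parc A [load_parcellation()] object.
#' @return Tibble with one row per bilateral region: `region_id`, `region`
#'   (the shared name), `lobe`, `n_parcels`, ordered by `region_id`.
#' @export
regions <- function(parc) {
  stopifnot(inherits(parc, "parcellation"))
  parc$parcels |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(region = .data$name[1], lobe = .data$lobe[1],
                     n_parcels = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$region_id)
}

check_parcel_values <- function(values, parc) {
  if (length(values) != parc$n_parcels) {
    stop("values length (", length(values), ") != n_parcels (", parc$n_parcels, ")")
  }
  as.numeric(values)
}

#' Average per-parcel values across hemispheres
#'
#' Each bilateral region's value is the arithmetic mean of its one or two
#' parcels.
#'
#' @param values Numeric vector over parcels (in `parcel_id` order).
#' @param parc A [load_parcellation()] object.
#' @return Tibble `(region_id, region, value)` ordered by `region_id`.
#' @export
bilateral_average <- function(values, parc) {
  values <- check_parcel_values(values, parc)
  parc$parcels |>
    dplyr::mutate(value = values) |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(region = .data$name[1], value = mean(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$region_id)
}

#' Select regions with Tau burden above the cortical mean
#'
#' Implements the ROI rule: keep the bilateral regions whose group-mean Tau
#' (BP_ND) exceeds (strictly) the mean over all regions. On the packaged
#' group-average Tau table this yields the 21-region temporo-parietal ROI
#' set.
#'
#' @param group_mean_tau Numeric vector of group-mean BP_ND per region
#'   (ordered by `region_id`), or a data frame with columns `region_id` and
#'   `tau`.
#' @param parc A [load_parcellation()] object.
#' @return An object of class `roi_set`: `region_ids`, `regions` (names) and
#'   `selection_threshold` (the cortical mean used).
#' @export
select_rois <- function(group_mean_tau, parc) {
  reg <- regions(parc)
  if (is.data.frame(group_mean_tau)) {
    stopifnot(all(c("region_id", "tau") %in% names(group_mean_tau)))
    tau <- group_mean_tau$tau[match(reg$region_id, group_mean_tau$region_id)]
  } else {
    if (length(group_mean_tau) != nrow(reg)) {
      stop("tau vector length (", length(group_mean_tau), ") != region count (", nrow(reg), ")")
    }
    tau <- as.numeric(group_mean_tau)
  }
  if (anyNA(tau)) stop("missing tau for some regions")
  threshold <- mean(tau)
  keep <- tau > threshold
  if (!any(keep)) warning("no region exceeds the cortical mean; empty ROI set")
  structure(
    list(region_ids = reg$region_id[keep], regions = reg$region[keep],
         selection_threshold = threshold),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d regions above mean Tau %.4g\n",
              length(x$region_ids), x$selection_threshold))
  invisible(x)
}

#' Serialize / read an ROI set as JSON
#' @param rois An [select_rois()] object.
#' @param path File path.
#' @return `write_roi_set` returns `path` invisibly; `read_roi_set` the
#'   `roi_set`.
#' @export
write_roi_set <- function(rois, path) {
  jsonlite::write_json(
    list(regions = rois$regions, region_ids = rois$region_ids,
         selection_threshold = rois$selection_threshold),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(region_ids = as.integer(x$region_ids), regions = x$regions,
                 selection_threshold = x$selection_threshold), class = "roi_set")
}

#' Average per-parcel values within functional lobes
#'
#' @param values Numeric vector over parcels.
#' @param parc A [load_parcellation()] object.
#' @return Tibble `(lobe, value)` with one row per represented lobe; lobes
#'   with no parcels are dropped with a warning.
#' @export
lobe_aggregate <- function(values, parc) {
  values <- check_parcel_values(values, parc)
  present <- unique(parc$parcels$lobe)
  absent <- setdiff(LOBES, present)
  if (length(absent)) warning("lobes with no parcels excluded: ", paste(absent, collapse = ", "))
  parc$parcels |>
    dplyr::mutate(value = values) |>
    dplyr::group_by(.data$lobe) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::arrange(match(.data$lobe, LOBES))
}

#' Path to a packaged example/fixture file
#' @param file File name under the package's `extdata/`, or `NULL` to list.
#' @return Full path (or file listing).
#' @export
taugraph_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "taugraph"))
  } else {
    system.file("extdata", file, package = "taugraph", mustWork = TRUE)
  }
}
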