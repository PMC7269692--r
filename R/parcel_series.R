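#' Parcel time-series container
#'
#' Multichannel parcel (or vertex) time series: a parcels x samples matrix
#' with its sampling rate, optional band label and optional epoch structure.
#'
#' @param data Numeric matrix, parcels in rows, samples in columns. Row names
#'   (parcel names) are kept if present.
#' @param fs Sampling rate in Hz.
#' @param band Optional [band_spec()] describing the band limits of `data`.
#' @param epoch_length Samples per epoch if the series is epoched, else `NULL`.
#' @param subject_id,visit Optional provenance labels.
#' @return An object of class `parcel_series`.
#' @export
parcel_series <- function(data, fs, band = NULL, epoch_length = NULL,
                          subject_id = NA_character_, visit = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  if (anyNA(data) || any(!is.finite(data))) stop("data contains NaN/Inf values")
  if (!is.null(epoch_length) && ncol(data) %% epoch_length != 0) {
    stop("samples (", ncol(data), ") not divisible by epoch_length (", epoch_length, ")")
  }
  if (!is.null(band) && !inherits(band, "band_spec")) stop("band must be a band_spec")
  structure(
    list(data = data, fs = fs, band = band, epoch_length = epoch_length,
         subject_id = subject_id, visit = visit),
    class = "parcel_series"
  )
}

#' @export
print.parcel_series <- function(x, ...) {
  cat(sprintf(
    "<parcel_series> %d parcels x %d samples @ %g Hz (%s%s)\n",
    nrow(x$data), ncol(x$data), x$fs,
    if (is.null(x$band)) "broadband" else x$band$name,
    if (is.null(x$epoch_length)) "" else sprintf(", %d epochs of %d samples",
                                                 ncol(x$data) %/% x$epoch_length,
                                                 x$epoch_length)
  ))
  invisible(x)
}

#' @export
dim.parcel_series <- function(x) dim(x$data)

is_epoched <- function(series) !is.null(series$epoch_length)

#' Write / read a parcel series as a CSV array with a JSON sidecar
#'
#' The data matrix is stored as plain CSV (one row per parcel) and the
#' metadata (sampling rate, band, epoch structure, provenance) as a JSON
#' sidecar next to it, so series survive round-trips through text-only
#' storage.
#'
#' @param series A [parcel_series()].
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @return `write_parcel_series` returns `path` invisibly;
#'   `read_parcel_series` the reconstructed `parcel_series`.
#' @export
write_parcel_series <- function(series, path) {
  stopifnot(inherits(series, "parcel_series"))
  utils::write.table(series$data, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(
    fs = series$fs,
    band = if (is.null(series$band)) NULL else {
      list(name = series$band$name, low = series$band$low,
           high = series$band$high, order = series$band$order,
           notch = series$band$notch)
    },
    epoch_length = series$epoch_length,
    subject_id = series$subject_id, visit = series$visit,
    parcel_names = rownames(series$data)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_parcel_series
#' @export
read_parcel_series <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(data) <- NULL
  if (!is.null(meta$parcel_names) && length(meta$parcel_names)) {
    rownames(data) <- meta$parcel_names
  }
  band <- if (!is.null(meta$band)) {
    band_spec(meta$band$name, meta$band$low, meta$band$high,
              order = meta$band$order, notch = meta$band$notch)
  }
  parcel_series(data, meta$fs, band = band, epoch_length = meta$epoch_length,
                subject_id = meta$subject_id %||% NA_character_,
                visit = meta$visit %||% NA_character_)
}

#' Amplitude envelope container
#'
#' Nonnegative envelope samples per parcel with a validity mask marking
#' samples retained for connectivity estimation (epoch-edge samples are
#' flagged invalid by [hilbert_envelope()]).
#'
#' @param data Nonnegative parcels x samples matrix.
#' @param fs Sampling rate (Hz).
#' @param band The [band_spec()] the envelopes were derived from.
#' @param valid Logical vector, one flag per sample column.
#' @param subject_id,visit Optional provenance labels.
#' @return An object of class `envelope_series`.
#' @export
envelope_series <- function(data, fs, band, valid = rep(TRUE, ncol(data)),
                            subject_id = NA_character_, visit = NA_character_) {
  data <- as.matrix(data)
  if (any(data < 0)) stop("envelope values must be nonnegative")
  if (length(valid) != ncol(data)) stop("valid mask length must equal sample count")
  structure(
    list(data = data, fs = fs, band = band, valid = as.logical(valid),
         subject_id = subject_id, visit = visit),
    class = "envelope_series"
  )
}

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("<envelope_series> %d parcels x %d samples @ %g Hz (%s), %d valid\n",
              nrow(x$data), ncol(x$data), x$fs,
              if (is.null(x$band)) "broadband" else x$band$name, sum(x$valid)))
  invisible(x)
}
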