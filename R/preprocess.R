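# Signal chain: bandpass -> (notch) -> epoch -> downsample -> envelope.
# All filtering is zero-phase (forward-backward second-order sections).

#' Band-pass filter a parcel series
#'
#' Fifth-order (by default) Butterworth band-pass applied forward-backward,
#' so the output has zero net phase shift. Must be applied to continuous
#' (non-epoched) input; epoch afterwards.
#'
#' @param series A [parcel_series()] (continuous, broadband).
#' @param band A [band_spec()].
#' @return A band-limited `parcel_series`.
#' @export
bandpass <- function(series, band) {
  stopifnot(inherits(series, "parcel_series"), inherits(band, "band_spec"))
  if (is_epoched(series)) {
    stop("bandpass must run before epoching; got an epoched series")
  }
  if (band$low >= series$fs / 2) {
    stop("band ", band$name, " lies entirely above Nyquist at fs = ", series$fs)
  }
  sos <- butter_bandpass_sos(band$order, band$low, band$high, series$fs)
  padlen <- ceiling(2 * series$fs / max(band$low, 0.05))
  out <- filter_rows(sos, series$data, padlen = padlen)
  parcel_series(out, series$fs, band = band, subject_id = series$subject_id,
                visit = series$visit)
}

#' Notch-filter line noise
#'
#' Narrow zero-phase IIR notches at each listed mains frequency (applied to
#' the gamma band in the canonical chain). Frequencies at or above Nyquist
#' are skipped with a warning.
#'
#' @param series A [parcel_series()].
#' @param line_freqs Numeric vector of line frequencies in Hz (possibly empty).
#' @param q Notch quality factor (centre frequency / -3 dB bandwidth).
#' @return The filtered `parcel_series`.
#' @export
notch <- function(series, line_freqs, q = 35) {
  stopifnot(inherits(series, "parcel_series"))
  if (length(line_freqs) == 0) return(series)
  keep <- line_freqs < series$fs / 2
  if (any(!keep)) {
    warning("skipping notch frequencies at/above Nyquist: ",
            paste(line_freqs[!keep], collapse = ", "))
  }
  data <- series$data
  for (f0 in line_freqs[keep]) {
    sos <- notch_sos(f0, series$fs, q)
    data <- filter_rows(sos, data, padlen = ceiling(series$fs))
  }
  out <- series
  out$data <- data
  out
}

#' Cut a continuous series into consecutive fixed-length epochs
#'
#' Trailing samples that do not fill a whole epoch are discarded, so a 300 s
#' recording at 4 s epochs yields 75 epochs.
#'
#' @param series A continuous [parcel_series()].
#' @param epoch_seconds Epoch length in seconds (default 4).
#' @return An epoched `parcel_series`.
#' @export
epoch <- function(series, epoch_seconds = 4) {
  stopifnot(inherits(series, "parcel_series"))
  if (is_epoched(series)) stop("series is already epoched")
  len <- round(epoch_seconds * series$fs)
  n <- ncol(series$data)
  if (n < len) stop("recording shorter than one epoch (", epoch_seconds, " s)")
  n_epochs <- n %/% len
  out <- series
  out$data <- series$data[, seq_len(n_epochs * len), drop = FALSE]
  out$epoch_length <- len
  out
}

#' Number of epochs in an epoched series
#' @param series An epoched [parcel_series()].
#' @return Integer epoch count.
#' @export
n_epochs <- function(series) {
  if (!is_epoched(series)) stop("series is not epoched")
  ncol(series$data) %/% series$epoch_length
}

#' Downsample to a target rate with anti-alias filtering
#'
#' Integer-factor decimation: an 8th-order Butterworth low-pass at 80% of the
#' target Nyquist is applied zero-phase, then every k-th sample is kept.
#' Upsampling and non-integer factors are refused.
#'
#' @param series A [parcel_series()] (epoched series are supported; epochs are
#'   contiguous in time so filtering the concatenation is exact).
#' @param target_fs Target sampling rate (Hz), default 200.
#' @return A `parcel_series` at `target_fs`.
#' @export
downsample <- function(series, target_fs = 200) {
  stopifnot(inherits(series, "parcel_series"))
  if (target_fs > series$fs) stop("upsampling refused (", series$fs, " -> ", target_fs, " Hz)")
  if (target_fs == series$fs) return(series)
  factor <- series$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stop("fs/target_fs must be an integer (got ", series$fs, "/", target_fs, ")")
  }
  factor <- as.integer(round(factor))
  if (is_epoched(series) && series$epoch_length %% factor != 0) {
    stop("epoch_length not divisible by the decimation factor")
  }
  sos <- butter_lowpass_sos(8, 0.8 * target_fs / 2, series$fs)
  data <- filter_rows(sos, series$data)
  idx <- seq(1, ncol(data), by = factor)
  out <- series
  out$data <- data[, idx, drop = FALSE]
  out$fs <- target_fs
  if (is_epoched(series)) out$epoch_length <- series$epoch_length %/% factor
  out
}

#' First eigenvariate of a vertex-by-time matrix
#'
#' Variance-optimal one-dimensional summary of a parcel: the leading right
#' singular vector scaled by its singular value. The sign is fixed so the
#' time course correlates nonnegatively with the vertex mean.
#'
#' @param vertex_data Numeric vertices x samples matrix (>= 1 vertex,
#'   >= 2 samples).
#' @return Numeric vector of length `ncol(vertex_data)`.
#' @export
first_eigenvariate <- function(vertex_data) {
  vertex_data <- as.matrix(vertex_data)
  if (ncol(vertex_data) < 2) stop("need at least 2 samples")
  if (all(vertex_data == 0)) {
    warning("all-zero vertex data; returning zero eigenvariate")
    return(numeric(ncol(vertex_data)))
  }
  sv <- svd(vertex_data, nu = 0, nv = 1)
  tc <- sv$v[, 1] * sv$d[1]
  m <- colMeans(vertex_data)
  if (sum(tc * m) < 0) tc <- -tc
  tc
}

# Analytic signal of one real vector via the frequency-domain Hilbert mask.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Hilbert amplitude envelope of an epoched band-limited series
#'
#' The analytic signal is computed per epoch and per parcel, magnitudes are
#' taken, and epochs are concatenated. Because the Hilbert transform is
#' circular within an epoch, the first and last `edge_frac` of each epoch's
#' samples are flagged invalid and excluded from downstream correlation
#' (switchable via `edge_frac = 0`).
#'
#' @param series An epoched, band-limited [parcel_series()].
#' @param edge_frac Fraction of samples flagged at each epoch edge
#'   (default 0.1).
#' @return An [envelope_series()].
#' @export
hilbert_envelope <- function(series, edge_frac = 0.1) {
  stopifnot(inherits(series, "parcel_series"))
  if (!is_epoched(series)) stop("hilbert_envelope requires an epoched series")
  if (is.null(series$band)) stop("hilbert_envelope requires band-limited input")
  len <- series$epoch_length
  ne <- n_epochs(series)
  env <- matrix(0, nrow(series$data), ncol(series$data),
                dimnames = dimnames(series$data))
  for (e in seq_len(ne)) {
    cols <- ((e - 1) * len + 1):(e * len)
    for (p in seq_len(nrow(series$data))) {
      env[p, cols] <- Mod(analytic_signal(series$data[p, cols]))
    }
  }
  edge <- floor(edge_frac * len)
  epoch_valid <- rep(TRUE, len)
  if (edge > 0) epoch_valid[c(seq_len(edge), (len - edge + 1):len)] <- FALSE
  envelope_series(env, series$fs, series$band, valid = rep(epoch_valid, ne),
                  subject_id = series$subject_id, visit = series$visit)
}
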