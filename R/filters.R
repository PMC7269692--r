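# Butterworth designs realised as cascaded second-order sections (biquads).
# Transfer-function (b, a) forms of a 10th-order bandpass are numerically
# singular at the 0.1 Hz delta edge; the SOS cascade stays stable there.

#' Frequency band specification
#'
#' Defines an analysis band for band-pass filtering and envelope extraction.
#' The five canonical E/MEG bands are provided by [canonical_bands()].
#'
#' @param name Band label, e.g. `"alpha"`.
#' @param low,high Band edges in Hz; `0 <= low < high`.
#' @param order Butterworth filter order (default 5).
#' @param notch Optional numeric vector of line frequencies (Hz) to notch out
#'   after band-passing (used for the gamma band).
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(name, low, high, order = 5, notch = NULL) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1, length(high) == 1)
  if (low < 0 || low >= high) {
    stop("band edges must satisfy 0 <= low < high (got ", low, ", ", high, ")")
  }
  structure(
    list(name = as.character(name), low = low, high = high,
         order = as.integer(order), notch = notch),
    class = "band_spec"
  )
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz (order %d%s)\n", x$name, x$low, x$high,
              x$order,
              if (length(x$notch)) paste0(", notch ", paste(x$notch, collapse = "/"), " Hz") else ""))
  invisible(x)
}

#' Canonical E/MEG frequency bands
#'
#' The five analysis bands: delta 0.1-4, theta 4-8, alpha 8-12, beta 12-30 and
#' gamma 30-100 Hz. When the analysis sampling rate puts the nominal gamma
#' upper edge at or above Nyquist, the gamma band is truncated to
#' `0.475 * fs` (95 Hz at 200 Hz) and this is recorded in the returned spec.
#' Gamma carries a mains notch (default 50 Hz).
#'
#' @param fs Sampling rate (Hz) the bands will be applied at.
#' @param line_freq Mains frequency for the gamma notch (Hz).
#' @return Named list of five [band_spec()] objects.
#' @export
canonical_bands <- function(fs = 200, line_freq = 50) {
  gamma_high <- min(100, 0.475 * fs)
  list(
    delta = band_spec("delta", 0.1, 4),
    theta = band_spec("theta", 4, 8),
    alpha = band_spec("alpha", 8, 12),
    beta  = band_spec("beta", 12, 30),
    gamma = band_spec("gamma", 30, gamma_high, notch = line_freq)
  )
}

# Analog Butterworth prototype poles (unit cutoff), left half plane.
butter_prototype_poles <- function(n) {
  exp(1i * pi * (2 * seq_len(n) + n - 1) / (2 * n))
}

bilinear_pole <- function(s, fs) (2 * fs + s) / (2 * fs - s)

# One biquad (b0 b1 b2 a1 a2) from a conjugate (or real) pole pair and two zeros.
biquad_from_pair <- function(p1, p2, z1, z2) {
  c(1, -Re(z1 + z2), Re(z1 * z2), -Re(p1 + p2), Re(p1 * p2))
}

sos_response <- function(sos, f, fs) {
  z <- exp(1i * 2 * pi * f / fs)
  H <- 1 + 0i
  for (i in seq_len(nrow(sos))) {
    s <- sos[i, ]
    H <- H * (s[1] + s[2] / z + s[3] / z^2) / (1 + s[4] / z + s[5] / z^2)
  }
  H
}

normalize_sos_gain <- function(sos, f_ref, fs) {
  g <- (1 / Mod(sos_response(sos, f_ref, fs)))^(1 / nrow(sos))
  sos[, 1:3] <- sos[, 1:3] * g
  sos
}

#' Butterworth band-pass design as second-order sections
#'
#' @param order Prototype (lowpass) order; the band-pass is order `2 * order`.
#' @param low,high Band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @return Matrix with one row per biquad: `(b0, b1, b2, a1, a2)`.
#' @export
butter_bandpass_sos <- function(order, low, high, fs) {
  nyq <- fs / 2
  if (low >= nyq) stop("band (", low, "-", high, " Hz) lies at or above Nyquist (", nyq, " Hz)")
  high <- min(high, 0.499 * fs)
  p <- butter_prototype_poles(order)
  W1 <- 2 * fs * tan(pi * low / fs)
  W2 <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(W1 * W2)
  B <- W2 - W1
  secs <- list()
  for (pk in p[Im(p) > 1e-9]) {
    d <- sqrt((B * pk)^2 - 4 * w0^2 + 0i)
    for (s in c((B * pk + d) / 2, (B * pk - d) / 2)) {
      z <- bilinear_pole(s, fs)
      secs[[length(secs) + 1]] <- biquad_from_pair(z, Conj(z), 1 + 0i, -1 + 0i)
    }
  }
  for (pk in Re(p[abs(Im(p)) <= 1e-9])) {
    d <- sqrt((B * pk)^2 - 4 * w0^2 + 0i)
    z1 <- bilinear_pole((B * pk + d) / 2, fs)
    z2 <- bilinear_pole((B * pk - d) / 2, fs)
    secs[[length(secs) + 1]] <- biquad_from_pair(z1, z2, 1 + 0i, -1 + 0i)
  }
  sos <- do.call(rbind, secs)
  f0 <- fs / pi * atan(w0 / (2 * fs))  # bilinear-warped centre frequency
  normalize_sos_gain(sos, f0, fs)
}

#' Butterworth low-pass design as second-order sections
#'
#' @inheritParams butter_bandpass_sos
#' @param cutoff Cutoff frequency in Hz.
#' @return Biquad matrix as in [butter_bandpass_sos()]; odd orders contribute a
#'   degenerate first-order section.
#' @export
butter_lowpass_sos <- function(order, cutoff, fs) {
  if (cutoff >= fs / 2) stop("cutoff must be below Nyquist")
  p <- butter_prototype_poles(order)
  wc <- 2 * fs * tan(pi * cutoff / fs)
  secs <- list()
  for (pk in p[Im(p) > 1e-9]) {
    z <- bilinear_pole(wc * pk, fs)
    secs[[length(secs) + 1]] <- biquad_from_pair(z, Conj(z), -1 + 0i, -1 + 0i)
  }
  for (pk in Re(p[abs(Im(p)) <= 1e-9])) {
    z <- bilinear_pole(wc * pk, fs)
    # first-order section: one pole, one zero at z = -1
    secs[[length(secs) + 1]] <- c(1, 1, 0, -Re(z), 0)
  }
  sos <- do.call(rbind, secs)
  normalize_sos_gain(sos, 0, fs)
}

# Narrow IIR notch biquad at f0 with quality factor q.
notch_sos <- function(f0, fs, q = 35) {
  w0 <- 2 * pi * f0 / fs
  r <- 1 - pi * f0 / (q * fs)  # pole radius from -3 dB bandwidth f0/q
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  g <- sum(a) / sum(b)  # unit DC gain
  matrix(c(b * g, a[2:3]), nrow = 1)
}

# Steady-state initial conditions per section for a unit-amplitude step,
# propagating each section's DC gain down the cascade (zero for band-pass
# sections, where the steady state dies out anyway).
sos_step_zi <- function(sos) {
  nsec <- nrow(sos)
  zi <- matrix(0, nsec, 2)
  scale <- 1
  for (i in seq_len(nsec)) {
    b <- sos[i, 1:3]; a1 <- sos[i, 4]; a2 <- sos[i, 5]
    den <- 1 + a1 + a2
    g <- if (abs(den) > 1e-14) sum(b) / den else 0
    zi[i, 1] <- scale * (g - b[1])
    zi[i, 2] <- scale * (b[3] - a2 * g)
    scale <- scale * g
  }
  zi
}

#' Zero-phase filtering through a second-order-section cascade
#'
#' Applies the cascade forward and backward (zero net phase) with odd
#' reflection padding and step-matched initial conditions, so in-band
#' components keep their timing and edge transients are suppressed.
#'
#' @param sos Biquad matrix from one of the `*_sos` designers.
#' @param x Numeric vector to filter.
#' @param padlen Reflection pad length in samples; capped at `length(x) - 2`.
#' @return Filtered vector, same length as `x`.
#' @export
sosfiltfilt <- function(sos, x, padlen = NULL) {
  n <- length(x)
  if (n < 4) stop("signal too short to filter")
  if (is.null(padlen)) padlen <- 3 * 6 * nrow(sos)
  padlen <- min(padlen, n - 2)
  zi <- sos_step_zi(sos)
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  y <- sosfilt_cpp(sos, ext, zi * ext[1])
  y <- rev(y)
  y <- sosfilt_cpp(sos, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

# Zero-phase filter every row of a matrix.
filter_rows <- function(sos, mat, padlen = NULL) {
  t(apply(mat, 1, function(r) sosfiltfilt(sos, r, padlen)))
}
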