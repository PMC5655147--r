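#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass filter forward and backward
#' (via [signal::filtfilt()]) so the output has zero group delay. Zero-phase
#' filtering is essential here because event timing feeds the downstream lag
#' statistics: any phase delay in the detection band would bias every
#' cross-correlogram peak lag.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param low_hz,high_hz Pass-band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @return Filtered signal, same length as `x`.
#' @examples
#' fs <- 2000
#' t <- seq(0, 1, by = 1 / fs)
#' y <- bandpass_filter(sin(2 * pi * 150 * t), fs, 100, 250)
#' @export
bandpass_filter <- function(x, fs, low_hz, high_hz) {
  stopifnot(is.numeric(x), length(x) > 0, is.finite(fs), fs > 0)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("band [", low_hz, ", ", high_hz, "] Hz must satisfy 0 < low < high < fs/2 (fs = ",
         fs, ")", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  # butter(2, ...) with type = "pass" yields a 4th-order band-pass
  bf <- signal::butter(2, c(low_hz, high_hz) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Analytic signal of a real vector
#'
#' FFT construction: double the positive-frequency coefficients, zero the
#' negative ones (Nyquist and DC kept once), and invert.
#'
#' @param x Numeric vector with no non-finite values.
#' @return Complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous amplitude via the Hilbert transform
#'
#' Returns the modulus of the analytic signal, i.e. the instantaneous
#' amplitude (envelope) of a band-limited trace. This is the quantity
#' thresholded by all three oscillatory event detectors and correlated by
#' the amplitude cross-correlogram.
#'
#' @param x Numeric signal vector, typically band-pass filtered first.
#' @return Non-negative envelope, same length as `x`.
#' @examples
#' fs <- 2000
#' t <- seq(0, 2, by = 1 / fs)
#' env <- hilbert_envelope(2 * sin(2 * pi * 150 * t))
#' @export
hilbert_envelope <- function(x) {
  stopifnot(is.numeric(x), length(x) > 0)
  if (anyNA(x) || any(!is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  Mod(analytic_signal(x))
}

#' Welch power spectral density
#'
#' Segment-averaged periodogram: the signal is cut into `window_s`-second
#' segments with 50% overlap, each segment is Hann-tapered and its
#' periodogram computed, and the periodograms are averaged. Density scaling
#' (power per Hz) is used, so integrating over frequency recovers variance.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param window_s Segment length in seconds (default 2).
#' @param overlap Fractional overlap between consecutive segments (default 0.5).
#' @return An object of class `"psd"`: list with `freqs_hz`, `power`,
#'   `window_s`, `n_segments`.
#' @export
welch_psd <- function(x, fs, window_s = 2, overlap = 0.5) {
  stopifnot(is.numeric(x), fs > 0, window_s > 0, overlap >= 0, overlap < 1)
  nper <- round(window_s * fs)
  if (length(x) < 2 * nper) {
    stop("signal too short for Welch PSD: need at least ", 2 * nper,
         " samples (2 x window), got ", length(x), call. = FALSE)
  }
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann taper
  u <- sum(w^2)                                              # taper power norm
  nfreq <- floor(nper / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nfreq)]
    p <- (Mod(X)^2) / (fs * u)
    # one-sided density: double everything except DC (and Nyquist when even)
    if (nper %% 2 == 0) p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]
    else p[2:nfreq] <- 2 * p[2:nfreq]
    acc <- acc + p
  }
  structure(list(freqs_hz = (seq_len(nfreq) - 1L) * fs / nper,
                 power = acc / length(starts),
                 window_s = window_s,
                 n_segments = length(starts)),
            class = "psd")
}

#' Canonical frequency bands
#'
#' The five bands used for band-power summaries: delta 1-4, theta 4-12,
#' alpha 12-20, beta 20-40, gamma 40-100 Hz.
#' @return Named list of `c(low, high)` pairs in Hz.
#' @export
canonical_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 12), alpha = c(12, 20),
       beta = c(20, 40), gamma = c(40, 100))
}

#' Fraction of total 1-100 Hz power per canonical band
#'
#' Each grid frequency is assigned to exactly one band by half-open binning
#' `[low, high)`, so shared band edges (e.g. 4 Hz between delta and theta)
#' are not double counted and the five fractions sum to 1. The denominator
#' is the total power over 1-100 Hz.
#'
#' @param psd A `"psd"` object covering at least 1-100 Hz.
#' @return Named numeric vector of fractions over the five canonical bands.
#' @export
band_power_fractions <- function(psd) {
  stopifnot(inherits(psd, "psd"))
  f <- psd$freqs_hz
  if (max(f) < 100 || min(f) > 1) {
    stop("PSD grid must cover 1-100 Hz", call. = FALSE)
  }
  bands <- canonical_bands()
  in_total <- f >= 1 & f < 100
  total <- sum(psd$power[in_total])
  if (total <= 0) stop("total 1-100 Hz power is zero; band fractions undefined", call. = FALSE)
  vapply(bands, function(b) {
    sum(psd$power[f >= b[1] & f < b[2]]) / total
  }, numeric(1))
}

#' Band power (absolute) over an arbitrary band
#'
#' Integrates PSD density over `[low, high)` using the grid spacing.
#' @param psd A `"psd"` object.
#' @param low_hz,high_hz Band edges in Hz.
#' @return Scalar power.
#' @keywords internal
band_power <- function(psd, low_hz, high_hz) {
  sel <- psd$freqs_hz >= low_hz & psd$freqs_hz < high_hz
  df <- if (length(psd$freqs_hz) > 1) psd$freqs_hz[2] - psd$freqs_hz[1] else 1
  sum(psd$power[sel]) * df
}
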