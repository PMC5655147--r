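#' Histogram-mode estimate of a continuous sample
#'
#' The mode of a continuous quantity (EMG envelope level, theta/delta
#' ratio) is estimated as the centre of the maximal-count histogram bin
#' under Freedman-Diaconis binning; ties break toward the lower bin. The
#' mode, rather than the mean, is used for adaptive thresholds because it
#' tracks the dominant (baseline) level and is insensitive to the heavy
#' right tail that movement artifacts and oscillatory events produce.
#'
#' @param values Numeric vector with at least 100 finite values.
#' @return Scalar mode estimate.
#' @export
estimate_mode <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 100) {
    stop("need >= 100 finite values to estimate a mode, got ", length(values),
         call. = FALSE)
  }
  rng <- range(values)
  if (rng[1] == rng[2]) return(rng[1])
  iqr <- stats::IQR(values)
  bw <- 2 * iqr * length(values)^(-1 / 3)          # Freedman-Diaconis
  if (bw <= 0) bw <- diff(rng) / ceiling(sqrt(length(values)))
  breaks <- seq(rng[1], rng[2] + bw, by = bw)
  counts <- tabulate(findInterval(values, breaks, rightmost.closed = FALSE),
                     nbins = length(breaks) - 1L)
  k <- which.max(counts)                           # which.max takes the first = lower bin
  (breaks[k] + breaks[k + 1L]) / 2
}

#' Detect immobility from the EMG channel
#'
#' The EMG Hilbert envelope is smoothed with a 0.5 s moving average;
#' immobile periods are maximal runs where the smoothed envelope stays
#' below `3 x mode` of the envelope, lasting at least `min_dur_s`
#' (default 10 s). Because both the envelope and its mode scale with any
#' gain applied to the EMG, the intervals are invariant to channel
#' scaling.
#'
#' @param emg EMG signal.
#' @param fs Sampling rate (Hz).
#' @param threshold_mult Threshold as a multiple of the envelope mode
#'   (default 3).
#' @param min_dur_s Minimum immobile duration in seconds (default 10).
#' @return `data.frame` of immobile intervals (`start_s`, `end_s`).
#' @export
detect_immobility <- function(emg, fs, threshold_mult = 3, min_dur_s = 10) {
  stopifnot(is.numeric(emg), fs > 0)
  if (length(emg) < 60 * fs) stop("EMG must be at least 60 s long", call. = FALSE)
  env <- hilbert_envelope(emg)
  env <- running_mean(env, max(1L, round(0.5 * fs)))
  m <- estimate_mode(env)
  if (m <= 0) stop("degenerate EMG: envelope mode is zero", call. = FALSE)
  runs <- logical_runs(env < threshold_mult * m)
  if (nrow(runs) == 0) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  keep <- (runs$last - runs$first + 1L) / fs >= min_dur_s
  runs <- runs[keep, , drop = FALSE]
  data.frame(start_s = (runs$first - 1L) / fs, end_s = runs$last / fs)
}

#' Centered running mean with edge shrinkage
#' @keywords internal
running_mean <- function(x, k) {
  if (k <= 1) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Score sleep states from EMG immobility and the theta/delta ratio
#'
#' Two-stage adaptive staging:
#'
#' 1. Non-immobile time (EMG envelope >= 3 x mode, see
#'    [detect_immobility()]) is WAKE.
#' 2. Immobile time is tiled into `epoch_s` (default 2 s) epochs. For each
#'    epoch the theta (4-12 Hz) to delta (1-4 Hz) power ratio is computed
#'    from a Welch PSD of the chosen LFP within the epoch. Epochs whose
#'    ratio falls below `3.5 x mode` of the ratio over all immobile epochs
#'    are NREM; epochs above it are REM.
#'
#' The threshold is re-estimated per session from that session's immobile
#' epochs (adaptive). Epochs truncated at immobility edges shorter than
#' 1 s are dropped (the sliver is labelled WAKE). If there are no
#' immobile epochs at all, a pure-WAKE hypnogram is returned with a
#' `warning` attribute.
#'
#' @param rec An `"lfp_recording"` with an `EMG` channel and `lfp_role`.
#' @param lfp_role LFP channel driving the ratio (default `"CA1_LFP"`).
#' @param epoch_s Staging epoch length in seconds (default 2).
#' @param ratio_threshold_mult REM threshold as a multiple of the ratio
#'   mode (default 3.5).
#' @return A `"hypnogram"` covering the whole recording.
#' @export
score_sleep <- function(rec, lfp_role = "CA1_LFP", epoch_s = 2,
                        ratio_threshold_mult = 3.5) {
  stopifnot(inherits(rec, "lfp_recording"))
  emg <- get_channel(rec, "EMG")
  lfp <- get_channel(rec, lfp_role)
  fs <- rec$fs
  dur <- recording_duration(rec)
  imm <- detect_immobility(emg, fs)
  if (nrow(imm) == 0) {
    h <- hypnogram(data.frame(start_s = 0, end_s = dur, state = "WAKE"), dur)
    attr(h, "warning") <- "no immobile epochs; scored as pure WAKE"
    return(h)
  }
  # tile immobile intervals into epochs (boundary epochs truncated; < 1 s dropped)
  epochs <- NULL
  for (k in seq_len(nrow(imm))) {
    s <- seq(imm$start_s[k], imm$end_s[k], by = epoch_s)
    if (s[length(s)] < imm$end_s[k]) s <- c(s, imm$end_s[k])
    e <- data.frame(start_s = s[-length(s)], end_s = s[-1])
    epochs <- rbind(epochs, e[e$end_s - e$start_s >= 1, , drop = FALSE])
  }
  if (is.null(epochs) || nrow(epochs) == 0) {
    h <- hypnogram(data.frame(start_s = 0, end_s = dur, state = "WAKE"), dur)
    attr(h, "warning") <- "immobile time too fragmented to stage; scored as pure WAKE"
    return(h)
  }
  ratio <- vapply(seq_len(nrow(epochs)), function(i) {
    i1 <- floor(epochs$start_s[i] * fs) + 1L
    i2 <- min(length(lfp), ceiling(epochs$end_s[i] * fs))
    seg <- lfp[i1:i2]
    win <- min(1, (length(seg) / fs) / 2)   # >= 2 segments within the epoch
    psd <- welch_psd(seg, fs, window_s = win)
    th <- band_power(psd, 4, 12)
    dl <- band_power(psd, 1, 4)
    if (dl <= 0) Inf else th / dl
  }, numeric(1))
  # the ratio mode needs a large sample; short immobile stretches fall back
  # to the median, which for a unimodal ratio distribution sits close by
  centre <- if (sum(is.finite(ratio)) >= 100) estimate_mode(ratio)
            else stats::median(ratio[is.finite(ratio)])
  thr <- ratio_threshold_mult * centre
  epochs$state <- ifelse(ratio < thr, "NREM", "REM")
  # assemble full coverage: everything outside scored epochs is WAKE
  iv <- epochs[order(epochs$start_s), ]
  out <- data.frame(start_s = numeric(0), end_s = numeric(0), state = character(0))
  t <- 0
  for (i in seq_len(nrow(iv))) {
    if (iv$start_s[i] > t) {
      out[nrow(out) + 1L, ] <- list(t, iv$start_s[i], "WAKE")
    }
    out[nrow(out) + 1L, ] <- list(iv$start_s[i], iv$end_s[i], iv$state[i])
    t <- iv$end_s[i]
  }
  if (t < dur) out[nrow(out) + 1L, ] <- list(t, dur, "WAKE")
  hypnogram(out, dur)
}

#' Sleep-architecture summary
#'
#' Totals per state plus NREM bout statistics (a bout is one maximal
#' contiguous NREM interval of the canonicalized hypnogram).
#'
#' @param h A `"hypnogram"`.
#' @return List with `total_nrem_s`, `mean_nrem_epoch_s`, `n_nrem_epochs`,
#'   `total_rem_s`, `total_wake_s`.
#' @export
sleep_architecture <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  nrem <- state_intervals(h, "NREM")
  list(
    total_nrem_s = state_total_s(h, "NREM"),
    mean_nrem_epoch_s = if (nrow(nrem) > 0) mean(nrem$end_s - nrem$start_s) else 0,
    n_nrem_epochs = nrow(nrem),
    total_rem_s = state_total_s(h, "REM"),
    total_wake_s = state_total_s(h, "WAKE")
  )
}
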