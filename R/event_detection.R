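#' Detection parameter sets
#'
#' Bundles the band, threshold multiplier, merge gap and duration bounds of
#' an envelope-threshold detector. The presets reproduce the standard
#' criteria for the three NREM oscillations:
#'
#' * ripple: CA1 LFP, 100-250 Hz, threshold 3 SD, merge gap 50 ms, no
#'   duration bounds;
#' * spindle: ACC LFP, 12-15 Hz, threshold 2 SD, duration 200-2000 ms,
#'   merge gap 100 ms;
#' * delta: ACC LFP, 1-4 Hz, threshold 1.5 SD, duration 150-500 ms,
#'   merge gap 100 ms.
#'
#' `threshold_rule` selects how the multiplier `k` is applied to the
#' envelope baseline: `"mean_plus_k_sd"` (default; the envelope of noise is
#' strictly positive, so a bare `k * SD` cut can sit below the mean) or
#' `"k_sd"`. `baseline_scope` selects whether the baseline mean/SD come
#' from NREM samples only (default) or the whole recording.
#'
#' @param kind `"ripple"`, `"spindle"` or `"delta"` for a preset, or
#'   `"custom"`.
#' @param band_low_hz,band_high_hz Detection band (Hz).
#' @param threshold_sd Threshold multiplier `k` (> 0).
#' @param merge_gap_ms Merge events separated by less than this gap.
#' @param min_dur_ms,max_dur_ms Duration bounds (NULL = unbounded).
#' @param baseline_scope `"NREM"` or `"whole_recording"`.
#' @param threshold_rule `"mean_plus_k_sd"` or `"k_sd"`.
#' @return A named list of class `"detection_params"`.
#' @export
detection_params <- function(kind = c("ripple", "spindle", "delta", "custom"),
                             band_low_hz = NULL, band_high_hz = NULL,
                             threshold_sd = NULL, merge_gap_ms = NULL,
                             min_dur_ms = NULL, max_dur_ms = NULL,
                             baseline_scope = "NREM",
                             threshold_rule = "mean_plus_k_sd") {
  kind <- match.arg(kind)
  preset <- switch(kind,
    ripple  = list(band_low_hz = 100, band_high_hz = 250, threshold_sd = 3,
                   merge_gap_ms = 50, min_dur_ms = NULL, max_dur_ms = NULL),
    spindle = list(band_low_hz = 12, band_high_hz = 15, threshold_sd = 2,
                   merge_gap_ms = 100, min_dur_ms = 200, max_dur_ms = 2000),
    delta   = list(band_low_hz = 1, band_high_hz = 4, threshold_sd = 1.5,
                   merge_gap_ms = 100, min_dur_ms = 150, max_dur_ms = 500),
    custom  = list(band_low_hz = NULL, band_high_hz = NULL, threshold_sd = NULL,
                   merge_gap_ms = 0, min_dur_ms = NULL, max_dur_ms = NULL))
  override <- list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                   threshold_sd = threshold_sd, merge_gap_ms = merge_gap_ms,
                   min_dur_ms = min_dur_ms, max_dur_ms = max_dur_ms)
  for (nm in names(override)) if (!is.null(override[[nm]])) preset[[nm]] <- override[[nm]]
  p <- c(list(kind = kind), preset,
         list(baseline_scope = match.arg(baseline_scope, c("NREM", "whole_recording")),
              threshold_rule = match.arg(threshold_rule, c("mean_plus_k_sd", "k_sd"))))
  if (is.null(p$band_low_hz) || is.null(p$band_high_hz) || is.null(p$threshold_sd)) {
    stop("band_low_hz, band_high_hz and threshold_sd are required", call. = FALSE)
  }
  if (p$band_low_hz >= p$band_high_hz) stop("band_low_hz must be < band_high_hz", call. = FALSE)
  if (p$threshold_sd <= 0) stop("threshold_sd must be > 0", call. = FALSE)
  if (!is.null(p$min_dur_ms) && !is.null(p$max_dur_ms) && p$min_dur_ms > p$max_dur_ms) {
    stop("min_dur_ms must be <= max_dur_ms", call. = FALSE)
  }
  structure(p, class = "detection_params")
}

#' Construct an event set
#'
#' @param kind Event kind.
#' @param events `data.frame` with `kind,start_s,end_s,center_s,peak_time_s,
#'   peak_amp,onset_s`, sorted by `start_s`.
#' @param params The `"detection_params"` (or plain list) that produced it.
#' @param source_role Channel role the events were detected on.
#' @param restricted_to NREM intervals the detection was restricted to.
#' @return Object of class `"event_set"`.
#' @export
event_set <- function(kind, events, params = list(), source_role = NA_character_,
                      restricted_to = NULL) {
  stopifnot(is.data.frame(events))
  if (nrow(events) > 1 && any(diff(events$start_s) < 0)) {
    stop("events must be sorted by start_s", call. = FALSE)
  }
  if (nrow(events) > 0 && any(events$end_s <= events$start_s)) {
    stop("events must have start_s < end_s", call. = FALSE)
  }
  structure(list(kind = kind, events = events, params = params,
                 source_role = source_role, restricted_to = restricted_to),
            class = "event_set")
}

#' Number of events in an event set
#' @param es An `"event_set"`.
#' @export
n_events <- function(es) {
  stopifnot(inherits(es, "event_set"))
  nrow(es$events)
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d %s event(s) from %s\n", n_events(x), x$kind, x$source_role))
  invisible(x)
}

#' Envelope-threshold event detection
#'
#' The shared detection rule behind all three oscillation detectors:
#'
#' 1. baseline mean and SD of the envelope are computed over the samples
#'    inside the NREM mask (or the whole trace, per `baseline_scope`);
#' 2. the threshold is `mean + k * SD` (or `k * SD` under the `"k_sd"`
#'    rule);
#' 3. candidate windows are maximal supra-threshold runs restricted to
#'    NREM (candidates straddling an NREM edge are clipped to it);
#' 4. windows separated by less than `merge_gap_ms` are merged;
#' 5. windows outside `[min_dur_ms, max_dur_ms]` are then discarded.
#'
#' Merging happens *before* duration filtering so a brief sub-threshold dip
#' cannot fragment one genuine long event into two short rejected pieces.
#'
#' @param envelope Non-negative instantaneous-amplitude trace.
#' @param fs Sampling rate (Hz).
#' @param params A `"detection_params"`.
#' @param nrem `data.frame` of NREM intervals (`start_s`, `end_s`).
#' @param kind Event kind label stored on the output.
#' @param source_role Channel role label stored on the output.
#' @return An `"event_set"` sorted by onset.
#' @export
detect_threshold_events <- function(envelope, fs, params, nrem,
                                    kind = params$kind, source_role = NA_character_) {
  stopifnot(is.numeric(envelope), fs > 0)
  if (is.null(nrem) || nrow(nrem) == 0) stop("NREM interval set is empty", call. = FALSE)
  if (any(envelope < 0)) stop("envelope must be non-negative", call. = FALSE)
  n <- length(envelope)
  mask <- interval_mask(nrem, n, fs)
  if (!any(mask)) stop("NREM mask covers no samples", call. = FALSE)
  base <- if (params$baseline_scope == "NREM") envelope[mask] else envelope
  mu <- mean(base)
  sigma <- stats::sd(base)
  if (!is.finite(sigma) || sigma == 0) {
    stop("degenerate envelope: baseline SD is zero", call. = FALSE)
  }
  thr <- if (params$threshold_rule == "mean_plus_k_sd") mu + params$threshold_sd * sigma
         else params$threshold_sd * sigma
  supra <- envelope > thr & mask
  runs <- logical_runs(supra)
  if (nrow(runs) > 0 && !is.null(params$merge_gap_ms) && params$merge_gap_ms > 0) {
    gap_samp <- params$merge_gap_ms / 1000 * fs
    merged <- runs[1, , drop = FALSE]
    for (i in seq_len(nrow(runs))[-1]) {
      if (runs$first[i] - merged$last[nrow(merged)] - 1L < gap_samp) {
        merged$last[nrow(merged)] <- runs$last[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  if (nrow(runs) > 0) {
    dur_ms <- (runs$last - runs$first + 1L) / fs * 1000
    keep <- rep(TRUE, nrow(runs))
    if (!is.null(params$min_dur_ms)) keep <- keep & dur_ms >= params$min_dur_ms
    if (!is.null(params$max_dur_ms)) keep <- keep & dur_ms <= params$max_dur_ms
    runs <- runs[keep, , drop = FALSE]
  }
  ev <- data.frame(kind = character(0), start_s = numeric(0), end_s = numeric(0),
                   center_s = numeric(0), peak_time_s = numeric(0),
                   peak_amp = numeric(0), onset_s = numeric(0))
  for (i in seq_len(nrow(runs))) {
    i1 <- runs$first[i]; i2 <- runs$last[i]
    pk <- i1 - 1L + which.max(envelope[i1:i2])
    start_s <- (i1 - 1L) / fs
    end_s <- i2 / fs
    ev[nrow(ev) + 1L, ] <- list(kind, start_s, end_s, (start_s + end_s) / 2,
                                (pk - 1L) / fs, envelope[pk], start_s)
  }
  event_set(kind = kind, events = ev, params = params,
            source_role = source_role, restricted_to = nrem)
}

#' Maximal runs of TRUE in a logical vector
#' @return `data.frame` with `first`, `last` sample indices.
#' @keywords internal
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(first = starts[r$values], last = ends[r$values])
}

#' Detect sharp-wave ripples
#'
#' Band-pass filters the CA1 LFP to 100-250 Hz, takes the Hilbert
#' envelope, and applies the envelope-threshold rule (3 SD, 50 ms merge, no
#' duration bounds) within NREM.
#'
#' @param rec An `"lfp_recording"` containing a `CA1_LFP` channel.
#' @param hyp A `"hypnogram"` with NREM intervals.
#' @param params Optional `"detection_params"` override.
#' @return An `"event_set"` of kind `"ripple"`.
#' @export
detect_ripples <- function(rec, hyp, params = detection_params("ripple")) {
  detect_band_events(rec, hyp, params, role = "CA1_LFP", kind = "ripple")
}

#' Detect sleep spindles
#'
#' ACC LFP, 12-15 Hz, threshold 2 SD, duration 200-2000 ms, merge 100 ms,
#' within NREM.
#' @inheritParams detect_ripples
#' @return An `"event_set"` of kind `"spindle"`.
#' @export
detect_spindles <- function(rec, hyp, params = detection_params("spindle")) {
  detect_band_events(rec, hyp, params, role = "ACC_LFP", kind = "spindle")
}

#' Detect delta waves
#'
#' ACC LFP, 1-4 Hz, threshold 1.5 SD, duration 150-500 ms, merge 100 ms,
#' within NREM. The event onset (`onset_s`) anchors ripple-delta coupling.
#' @inheritParams detect_ripples
#' @return An `"event_set"` of kind `"delta"`.
#' @export
detect_deltas <- function(rec, hyp, params = detection_params("delta")) {
  detect_band_events(rec, hyp, params, role = "ACC_LFP", kind = "delta")
}

detect_band_events <- function(rec, hyp, params, role, kind) {
  stopifnot(inherits(rec, "lfp_recording"), inherits(hyp, "hypnogram"))
  nrem <- state_intervals(hyp, "NREM")
  if (nrow(nrem) == 0) stop("hypnogram contains no NREM sleep", call. = FALSE)
  x <- get_channel(rec, role)
  env <- hilbert_envelope(bandpass_filter(x, rec$fs, params$band_low_hz, params$band_high_hz))
  detect_threshold_events(env, rec$fs, params, nrem, kind = kind, source_role = role)
}

#' Event incidence per minute of NREM
#'
#' @param es An `"event_set"`.
#' @param hyp A `"hypnogram"`.
#' @return Events per minute of NREM sleep.
#' @export
event_incidence <- function(es, hyp) {
  stopifnot(inherits(es, "event_set"), inherits(hyp, "hypnogram"))
  nrem_s <- state_total_s(hyp, "NREM")
  if (nrem_s <= 0) stop("hypnogram has zero NREM time; incidence undefined", call. = FALSE)
  n_events(es) / (nrem_s / 60)
}

#' Mean peak envelope amplitude of an event set
#'
#' @param es A non-empty `"event_set"`.
#' @return Arithmetic mean of per-event peak instantaneous amplitudes.
#' @export
event_amplitude_summary <- function(es) {
  stopifnot(inherits(es, "event_set"))
  if (n_events(es) == 0) stop("event set is empty; amplitude summary undefined", call. = FALSE)
  mean(es$events$peak_amp)
}
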