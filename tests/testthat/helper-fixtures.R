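# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

# A short all-NREM interval table covering [0, dur)
nrem_all <- function(dur) data.frame(start_s = 0, end_s = dur)

# Piecewise-constant "envelope" built from (level, seconds) segments
piecewise_env <- function(fs, ...) {
  segs <- list(...)
  unlist(lapply(segs, function(s) rep(s[1], round(s[2] * fs))))
}

# Small synthetic session shared by several detector/coupling tests.
# Cached per options so repeated calls in one test file are free.
.session_cache <- new.env(parent = emptyenv())
cached_session <- function(seed = 7, p_couple = 0, duration_s = 660, fs = 1000,
                           blocks = c(WAKE = 60, NREM = 600, REM = 0), ...) {
  key <- paste(seed, p_couple, duration_s, fs, paste(blocks, collapse = "-"),
               paste(unlist(list(...)), collapse = "-"), sep = "|")
  if (is.null(.session_cache[[key]])) {
    cfg <- synth_config(duration_s = duration_s, fs = fs, state_block_s = blocks,
                        p_couple = p_couple, seed = seed, ...)
    .session_cache[[key]] <- generate_recording(cfg)
  }
  .session_cache[[key]]
}

# Band envelope of one channel, optionally decimated
channel_env <- function(rec, role, low, high, dec = 1) {
  e <- hilbert_envelope(bandpass_filter(rec$channels[[role]], rec$fs, low, high))
  if (dec > 1) decimate_envelope(e, dec) else e
}

# Fraction of truth events with a detected peak within tol (recall), and
# fraction of detections near a truth event (precision)
match_rates <- function(det_times, truth_times, tol = 0.05) {
  recall <- if (length(truth_times) == 0) NA_real_ else {
    mean(vapply(truth_times, function(t) any(abs(det_times - t) <= tol), logical(1)))
  }
  precision <- if (length(det_times) == 0) NA_real_ else {
    mean(vapply(det_times, function(t) any(abs(truth_times - t) <= tol), logical(1)))
  }
  list(recall = recall, precision = precision)
}

# Naive per-lag Pearson amplitude correlogram (independent oracle for
# amplitude_xcorr): plain loops, no FFT, no running sums.
naive_amplitude_xcorr <- function(ripple_env, anchor_env, anchors_s, fs,
                                  half_window_s, step_s, nrem) {
  nw <- round(half_window_s * fs)
  lag_samp <- seq(-round(half_window_s / step_s), round(half_window_s / step_s)) *
    round(step_s * fs)
  # concatenate NREM segments exactly as the implementation defines them
  i1 <- pmax(1L, floor(nrem$start_s * fs) + 1L)
  i2 <- pmin(length(ripple_env), ceiling(nrem$end_s * fs))
  seg_of <- function(t) which(t >= (i1 - 1) / fs & t < i2 / fs)
  coefs_sum <- numeric(length(lag_samp))
  n_used <- 0
  for (a in anchors_s) {
    k <- seg_of(a)
    if (length(k) != 1) next
    c0 <- round(a * fs) + 1L
    if (c0 - 2 * nw < i1[k] || c0 + 2 * nw > i2[k]) next
    x <- anchor_env[(c0 - nw):(c0 + nw)]
    r <- vapply(lag_samp, function(l) {
      y <- ripple_env[(c0 - nw + l):(c0 + nw + l)]
      stats::cor(x, y)
    }, numeric(1))
    coefs_sum <- coefs_sum + r
    n_used <- n_used + 1
  }
  list(lags_s = lag_samp / fs, coefs = coefs_sum / n_used, n = n_used)
}
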