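#' Concatenate the NREM portions of a trace
#'
#' Coupling statistics are restricted to NREM sleep. NREM segments are
#' extracted and concatenated, with segment boundaries recorded so anchor
#' windows are never allowed to straddle a seam (which would correlate
#' across a gap in real time).
#'
#' @param n_samples Trace length.
#' @param fs Sampling rate (Hz).
#' @param nrem `data.frame` of NREM intervals (`start_s`, `end_s`).
#' @return List: `idx` (original sample indices making up the concatenated
#'   trace), `seg_first`/`seg_last` (concatenated-index bounds per
#'   segment), `seg_start_s` (original start time per segment),
#'   `seg_offset` (concatenated index preceding each segment).
#' @keywords internal
nrem_concat_index <- function(n_samples, fs, nrem) {
  stopifnot(nrow(nrem) > 0)
  i1 <- pmax(1L, floor(nrem$start_s * fs) + 1L)
  i2 <- pmin(n_samples, ceiling(nrem$end_s * fs))
  ok <- i2 >= i1
  i1 <- i1[ok]; i2 <- i2[ok]
  lens <- i2 - i1 + 1L
  seg_last <- cumsum(lens)
  seg_first <- seg_last - lens + 1L
  idx <- unlist(lapply(seq_along(i1), function(k) i1[k]:i2[k]))
  list(idx = idx, seg_first = seg_first, seg_last = seg_last,
       seg_start_idx = i1, seg_end_idx = i2,
       seg_start_s = (i1 - 1L) / fs, seg_end_s = i2 / fs)
}

#' Map anchor times into the concatenated trace
#'
#' @return List: `pos` (concatenated sample index per retained anchor),
#'   `seg` (segment id), `kept` (logical per input anchor).
#' @keywords internal
map_anchors <- function(anchors_s, ci, fs) {
  pos <- integer(0); seg <- integer(0); kept <- logical(length(anchors_s))
  for (a in seq_along(anchors_s)) {
    t0 <- anchors_s[a]
    k <- which(t0 >= ci$seg_start_s & t0 < ci$seg_end_s)
    if (length(k) == 1) {
      samp <- round(t0 * fs) + 1L                 # original sample index
      p <- ci$seg_first[k] + (samp - ci$seg_start_idx[k])
      if (p >= ci$seg_first[k] && p <= ci$seg_last[k]) {
        pos <- c(pos, p); seg <- c(seg, k); kept[a] <- TRUE
      }
    }
  }
  list(pos = pos, seg = seg, kept = kept)
}

#' Precompute sliding window statistics for the correlogram
#'
#' For each retained anchor at concatenated position `p`, the Pearson
#' correlation at displacement `d` (lag plus any shuffle shift) needs the
#' cross-product of the fixed anchor window with the ripple window starting
#' at `p - nw + d`, and that ripple window's sum and sum of squares. All
#' three are precomputed here for every displacement `|d| <= max lag +
#' max shuffle shift` — one FFT cross-correlation and one cumulative sum
#' per anchor — so evaluating the observed correlogram or any shuffle is
#' pure indexing. Ripple reads beyond the concatenated trace wrap
#' circularly.
#'
#' @keywords internal
xcorr_prep <- function(anchor_conc, ripple_conc, pos, seg, ci, fs,
                       half_window_s, step_s, max_off_samp = 0L) {
  nw <- round(half_window_s * fs)
  lag_step <- round(step_s * fs)
  if (abs(lag_step - step_s * fs) > 1e-6) {
    stop("step_s must be an integer number of samples at this rate", call. = FALSE)
  }
  n_half <- round(half_window_s / step_s)
  lag_samp <- seq(-n_half, n_half) * lag_step
  L <- 2L * nw + 1L
  # retention: the most lag-shifted ripple window must stay inside the segment
  keep <- (pos - 2L * nw) >= ci$seg_first[seg] & (pos + 2L * nw) <= ci$seg_last[seg]
  pos <- pos[keep]
  A <- length(pos)
  if (A == 0) {
    stop("no anchors remain after boundary filtering; need NREM segments longer than ",
         4 * half_window_s, " s", call. = FALSE)
  }
  D <- max(abs(lag_samp)) + max_off_samp
  nd <- 2L * D + 1L
  N <- length(ripple_conc)
  m <- stats::nextn(L + nd + L - 1L, c(2, 3, 5))
  # anchor windows (fixed)
  xmat <- matrix(anchor_conc[outer((-nw):nw, pos, "+")], nrow = L)
  sx <- colSums(xmat)
  vx <- colSums(xmat * xmat) - sx^2 / L
  # extended ripple segments around each anchor, circular reads
  rel <- (-(nw + D)):(nw + D)
  yidx <- (outer(rel, pos, "+") - 1L) %% N + 1L
  ymat <- matrix(ripple_conc[yidx], nrow = length(rel))   # (L + 2D) x A
  # FFT cross-correlation of each anchor window over its extended segment
  xpad <- matrix(0, m, A); xpad[seq_len(L), ] <- xmat
  ypad <- matrix(0, m, A); ypad[seq_len(nrow(ymat)), ] <- ymat
  cc <- Re(stats::mvfft(stats::mvfft(ypad) * Conj(stats::mvfft(xpad)),
                        inverse = TRUE))[seq_len(nd), , drop = FALSE] / m
  # sliding window sums over the extended segments
  cy <- apply(ymat, 2, cumsum)
  cyy <- apply(ymat * ymat, 2, cumsum)
  zero <- matrix(0, 1, A)
  cy <- rbind(zero, cy); cyy <- rbind(zero, cyy)
  j <- seq_len(nd)
  sy <- cy[j + L, , drop = FALSE] - cy[j, , drop = FALSE]
  syy <- cyy[j + L, , drop = FALSE] - cyy[j, , drop = FALSE]
  list(nw = nw, L = L, D = D, lag_samp = lag_samp, pos = pos, A = A,
       sx = sx, vx = vx, sxy = cc, sy = sy, syy = syy)
}

#' Evaluate the correlogram for given per-anchor displacements
#'
#' `offsets` is one shuffle shift per anchor (zero for the observed
#' correlogram); all quantities are gathered from the precomputed sliding
#' statistics.
#' @keywords internal
xcorr_core <- function(prep, fs, half_window_s, step_s, offsets = NULL) {
  L <- prep$L
  lag_samp <- prep$lag_samp
  lags_s <- lag_samp / fs
  P <- length(lag_samp)
  A <- prep$A
  if (is.null(offsets)) offsets <- integer(A)
  sum_coef <- numeric(P)
  n_used <- 0L
  eps <- .Machine$double.eps * L
  for (a in seq_len(A)) {
    if (prep$vx[a] <= eps) next
    d <- lag_samp + offsets[a] + prep$D + 1L
    vy <- prep$syy[d, a] - prep$sy[d, a]^2 / L
    if (any(vy <= eps)) next
    sum_coef <- sum_coef +
      (prep$sxy[d, a] - prep$sx[a] * prep$sy[d, a] / L) / sqrt(prep$vx[a] * vy)
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("all anchor windows were degenerate", call. = FALSE)
  coefs <- sum_coef / n_used
  pk <- pick_peak(coefs, lags_s)
  structure(list(lags_s = lags_s, coefs = coefs, n_windows = n_used,
                 n_skipped = A - n_used, peak_coef = pk$coef,
                 peak_lag_s = pk$lag, half_window_s = half_window_s,
                 step_s = step_s),
            class = "xcorr")
}

#' Deterministic peak with ties broken toward the smallest |lag|
#' @keywords internal
pick_peak <- function(coefs, lags_s) {
  finite <- which(is.finite(coefs))
  best <- finite[coefs[finite] == max(coefs[finite])]
  best <- best[order(abs(lags_s[best]), lags_s[best])][1]
  list(coef = coefs[best], lag = lags_s[best])
}

#' @export
print.xcorr <- function(x, ...) {
  cat(sprintf("<xcorr %s> peak %.4f at lag %+.3f s (%d windows, +/-%g s, step %g s)\n",
              if (is.null(x$method)) "amplitude" else x$method,
              x$peak_coef, x$peak_lag_s, x$n_windows, x$half_window_s, x$step_s))
  invisible(x)
}

#' Amplitude cross-correlogram around anchor events
#'
#' For each anchor time (spindle centre or delta onset) the anchor-band
#' envelope over `[c - W, c + W]` is Pearson-correlated with the ripple
#' envelope over `[c - W + tau, c + W + tau]` for every lag `tau` on the
#' grid `[-W, W]` in `step_s` increments, restricted to NREM. The
#' coefficients are averaged across anchors; the peak coefficient and its
#' signed lag are extracted. A negative peak lag means the ripple leads
#' the anchor.
#'
#' Anchors whose maximally shifted window would leave the containing NREM
#' segment are dropped; anchors with a zero-variance window are skipped
#' and counted in `n_skipped`.
#'
#' @param ripple_env Ripple-band envelope (full recording timeline).
#' @param anchor_env Anchor-band envelope, same length and rate.
#' @param anchors_s Anchor event times in seconds.
#' @param fs Sampling rate of the envelopes (Hz).
#' @param half_window_s Half window `W` in seconds (default 4).
#' @param step_s Lag increment in seconds (default 0.01).
#' @param nrem NREM intervals (`start_s`, `end_s`).
#' @return An `"xcorr"` object with `lags_s`, `coefs`, `peak_coef`,
#'   `peak_lag_s`, `n_windows`, `n_skipped`.
#' @export
amplitude_xcorr <- function(ripple_env, anchor_env, anchors_s, fs,
                            half_window_s = 4, step_s = 0.01, nrem) {
  stopifnot(length(ripple_env) == length(anchor_env), fs > 0,
            length(anchors_s) > 0, is.data.frame(nrem), nrow(nrem) > 0)
  ci <- nrem_concat_index(length(ripple_env), fs, nrem)
  am <- map_anchors(anchors_s, ci, fs)
  if (length(am$pos) == 0) stop("no anchors fall inside NREM", call. = FALSE)
  prep <- xcorr_prep(anchor_env[ci$idx], ripple_env[ci$idx], am$pos, am$seg,
                     ci, fs, half_window_s, step_s)
  out <- xcorr_core(prep, fs, half_window_s, step_s)
  out$method <- "amplitude"
  out$anchor <- "anchor_event"
  out
}

#' Circular-shift shuffle null for the amplitude cross-correlogram
#'
#' The chance level of the observed correlogram peak is estimated by
#' recomputing the correlogram `n_shuffles` times with the ripple envelope
#' displaced relative to the anchor envelope by a random 4-10 s shift
#' (sign equiprobable), and collecting the shuffled peak coefficients.
#' The observed peak is significant when it exceeds the nearest-rank 99th
#' percentile of the null peaks (strict inequality).
#'
#' Two shuffle modes are available: `"global"` (default) applies one
#' circular shift to the whole concatenated-NREM ripple envelope per
#' shuffle, preserving the envelope's autocorrelation — the more
#' conservative null; `"per_window"` shifts each anchor's ripple window
#' independently.
#'
#' @inheritParams amplitude_xcorr
#' @param n_shuffles Number of shuffles (default 100).
#' @param shift_range_s Shift magnitude range in seconds (default `c(4, 10)`).
#' @param seed Integer seed; the null is exactly reproducible given it.
#' @param mode `"global"` or `"per_window"`.
#' @return Object of class `"shuffle_null"`: `observed` (the unshuffled
#'   `"xcorr"`), `null_peaks`, `pct99`, `observed_peak`, `is_significant`,
#'   `n_shuffles`, `shift_range_s`, `seed`, `mode`.
#' @export
shuffle_null_test <- function(ripple_env, anchor_env, anchors_s, fs,
                              half_window_s = 4, step_s = 0.01, nrem,
                              n_shuffles = 100, shift_range_s = c(4, 10),
                              seed = 1L, mode = c("global", "per_window")) {
  mode <- match.arg(mode)
  stopifnot(length(ripple_env) == length(anchor_env), n_shuffles >= 1)
  ci <- nrem_concat_index(length(ripple_env), fs, nrem)
  if (length(ci$idx) / fs < 2 * shift_range_s[2]) {
    stop("insufficient NREM (", round(length(ci$idx) / fs), " s) for ",
         shift_range_s[2], " s shuffle shifts", call. = FALSE)
  }
  am <- map_anchors(anchors_s, ci, fs)
  if (length(am$pos) == 0) stop("no anchors fall inside NREM", call. = FALSE)
  aenv <- anchor_env[ci$idx]
  renv <- ripple_env[ci$idx]
  prep <- xcorr_prep(aenv, renv, am$pos, am$seg, ci, fs, half_window_s,
                     step_s, max_off_samp = round(shift_range_s[2] * fs))
  observed <- xcorr_core(prep, fs, half_window_s, step_s)
  observed$method <- "amplitude"
  n_anchor <- length(prep$pos)
  set.seed(seed)
  null_peaks <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    if (mode == "global") {
      shift <- round(sample(c(-1, 1), 1) *
                       stats::runif(1, shift_range_s[1], shift_range_s[2]) * fs)
      offs <- rep(shift, n_anchor)
    } else {
      offs <- round(sample(c(-1, 1), n_anchor, replace = TRUE) *
                      stats::runif(n_anchor, shift_range_s[1], shift_range_s[2]) * fs)
    }
    sh <- xcorr_core(prep, fs, half_window_s, step_s, offsets = offs)
    null_peaks[s] <- sh$peak_coef
  }
  pct99 <- sort(null_peaks)[ceiling(0.99 * n_shuffles)]  # nearest rank
  structure(list(observed = observed, null_peaks = null_peaks, pct99 = pct99,
                 observed_peak = observed$peak_coef,
                 is_significant = observed$peak_coef > pct99,
                 n_shuffles = n_shuffles, shift_range_s = shift_range_s,
                 seed = seed, mode = mode),
            class = "shuffle_null")
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat(sprintf("<shuffle_null> observed peak %.4f vs 99th pct %.4f (%d shuffles): %s\n",
              x$observed_peak, x$pct99, x$n_shuffles,
              if (x$is_significant) "significant" else "not significant"))
  invisible(x)
}

#' Event-timestamp cross-correlogram
#'
#' The second coupling measure: ripple and spindle event centres are
#' binarized on a `bin_s` grid over concatenated NREM time and the two 0/1
#' trains are Pearson-correlated at every integer-bin lag spanning
#' `[-half_window_s, half_window_s]`. Sign convention matches the
#' amplitude method: a negative peak lag means ripples lead spindles.
#'
#' @param ripple_events,spindle_events `"event_set"` objects or numeric
#'   vectors of centre times (s).
#' @param half_window_s Half window in seconds (default 4).
#' @param bin_s Bin width / lag increment in seconds (default 0.1).
#' @param nrem NREM intervals.
#' @param fs Nominal sampling rate used to align interval edges (default
#'   1000; only affects sub-millisecond rounding of segment bounds).
#' @return An `"xcorr"` object, `method = "timestamp"`.
#' @export
timestamp_xcorr <- function(ripple_events, spindle_events, half_window_s = 4,
                            bin_s = 0.1, nrem, fs = 1000) {
  rt <- event_centers(ripple_events)
  st <- event_centers(spindle_events)
  if (length(rt) == 0 || length(st) == 0) {
    stop("both event sets must be non-empty", call. = FALSE)
  }
  # map times to concatenated NREM time
  offs <- cumsum(c(0, utils::head(nrem$end_s - nrem$start_s, -1)))
  to_conc <- function(t) {
    k <- findInterval(t, nrem$start_s)
    ok <- k >= 1 & t < nrem$end_s[pmax(k, 1)]
    offs[k[ok]] + (t[ok] - nrem$start_s[k[ok]])
  }
  total <- sum(nrem$end_s - nrem$start_s)
  nb <- ceiling(total / bin_s)
  binarize <- function(t) {
    v <- numeric(nb)
    b <- pmin(nb, floor(to_conc(t) / bin_s) + 1L)
    v[b] <- 1
    v
  }
  x <- binarize(st)                      # spindle train (reference)
  y <- binarize(rt)                      # ripple train (shifted)
  if (sum(x) == 0 || sum(x) == nb || sum(y) == 0 || sum(y) == nb) {
    stop("degenerate event train (empty or saturated after binning)", call. = FALSE)
  }
  K <- round(half_window_s / bin_s)
  lags_s <- seq(-K, K) * bin_s
  coefs <- vapply(seq(-K, K), function(k) {
    i <- max(1L, 1L - k):min(nb, nb - k)
    xs <- x[i]; ys <- y[i + k]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    stats::cor(xs, ys)
  }, numeric(1))
  pk <- pick_peak(coefs, lags_s)
  structure(list(lags_s = lags_s, coefs = coefs,
                 n_windows = length(st), n_skipped = 0L,
                 peak_coef = pk$coef, peak_lag_s = pk$lag,
                 half_window_s = half_window_s, step_s = bin_s,
                 method = "timestamp", anchor = "spindle_center"),
            class = "xcorr")
}

#' @keywords internal
event_centers <- function(x) {
  if (inherits(x, "event_set")) x$events$center_s else as.numeric(x)
}

#' @keywords internal
event_onsets <- function(x) {
  if (inherits(x, "event_set")) x$events$onset_s else as.numeric(x)
}

#' Ripple-spindle joint occurrence rate
#'
#' The third coupling measure: the number of ripples whose centre falls
#' within `window_s` (default 0.25 s) of at least one spindle centre (each
#' ripple counted once), normalized by the number of spindles.
#'
#' @param ripple_events,spindle_events `"event_set"` objects or numeric
#'   centre-time vectors.
#' @param window_s Half window in seconds (default 0.25).
#' @return Joint occurrence rate (coupled ripples / spindle count).
#' @export
joint_occurrence_rate <- function(ripple_events, spindle_events, window_s = 0.25) {
  rt <- event_centers(ripple_events)
  st <- event_centers(spindle_events)
  if (length(st) == 0) stop("zero spindles; joint rate undefined", call. = FALSE)
  if (length(rt) == 0) return(0)
  st <- sort(st)
  near <- vapply(rt, function(r) {
    i <- findInterval(r, st)
    d <- Inf
    if (i >= 1) d <- min(d, abs(r - st[i]))
    if (i < length(st)) d <- min(d, abs(r - st[i + 1]))
    d <= window_s
  }, logical(1))
  sum(near) / length(st)
}

#' Ripple-delta amplitude cross-correlogram
#'
#' The amplitude method anchored at delta-wave onsets with a `+/-0.5` s
#' window and 0.01 s lag increments. A negative peak lag means the ripple
#' leads the delta wave.
#'
#' @param ripple_env,delta_env Envelopes (same length/rate).
#' @param delta_events `"event_set"` of delta waves or numeric onset times.
#' @param fs Sampling rate of the envelopes.
#' @param nrem NREM intervals.
#' @param half_window_s,step_s Window and lag step (defaults 0.5 and 0.01 s).
#' @return An `"xcorr"` object, `anchor = "delta_onset"`.
#' @export
ripple_delta_xcorr <- function(ripple_env, delta_env, delta_events, fs, nrem,
                               half_window_s = 0.5, step_s = 0.01) {
  out <- amplitude_xcorr(ripple_env, delta_env, event_onsets(delta_events), fs,
                         half_window_s = half_window_s, step_s = step_s, nrem = nrem)
  out$anchor <- "delta_onset"
  out
}

#' Normalize a post value to a pre baseline
#'
#' @param post_value,pre_value Scalars; `pre_value` must be non-zero.
#' @return `post_value / pre_value`.
#' @export
normalize_to_baseline <- function(post_value, pre_value) {
  if (!is.finite(pre_value) || pre_value == 0) {
    stop("baseline (pre) value is zero or non-finite; ratio undefined", call. = FALSE)
  }
  post_value / pre_value
}

#' Block-mean decimation of an envelope
#'
#' Reduces an envelope to the lag resolution of the correlogram by
#' averaging non-overlapping blocks of `factor` samples. Averaging (rather
#' than subsampling) acts as an anti-aliasing filter for the slowly
#' varying envelope.
#'
#' @param env Envelope vector.
#' @param factor Integer decimation factor.
#' @return Envelope of length `floor(length(env) / factor)` at rate
#'   `fs / factor`.
#' @export
decimate_envelope <- function(env, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1) return(env)
  nb <- length(env) %/% factor
  colMeans(matrix(env[seq_len(nb * factor)], nrow = factor))
}

#' Export a correlogram as CSV
#'
#' Columns `lag_s, coef` plus `null_pct99` when a `"shuffle_null"` is
#' supplied.
#' @param xc An `"xcorr"`.
#' @param path Output file.
#' @param null Optional `"shuffle_null"`.
#' @export
write_xcorr <- function(xc, path, null = NULL) {
  stopifnot(inherits(xc, "xcorr"))
  tab <- data.frame(lag_s = xc$lags_s, coef = xc$coefs)
  if (!is.null(null)) tab$null_pct99 <- null$pct99
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
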