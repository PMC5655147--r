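# Smooth positive "envelope" at a given rate for correlogram fixtures
smooth_env <- function(n, seed = 1, k = 9) {
  set.seed(seed)
  as.numeric(lfpcoupling:::running_mean(abs(rnorm(n)) + 0.5, k))
}

test_that("self-correlation peaks at exactly 1 at lag 0", {
  fs <- 100
  env <- smooth_env(120 * fs)
  xc <- amplitude_xcorr(env, env, anchors_s = c(30, 60, 90), fs = fs,
                        half_window_s = 4, step_s = 0.01, nrem = nrem_all(120))
  expect_equal(xc$peak_lag_s, 0)
  expect_equal(xc$peak_coef, 1, tolerance = 1e-12)
  expect_true(all(xc$coefs >= -1 - 1e-12 & xc$coefs <= 1 + 1e-12))
  expect_equal(xc$n_windows, 3)
})

test_that("a ripple envelope leading the anchor gives a negative peak lag", {
  fs <- 100
  n <- 120 * fs
  aenv <- smooth_env(n, seed = 2)
  # ripple activity precedes the anchor by 0.07 s: renv(t) = aenv(t + 0.07)
  shift <- round(0.07 * fs)
  renv <- c(aenv[(shift + 1):n], aenv[1:shift])
  xc <- amplitude_xcorr(renv, aenv, anchors_s = c(30, 60, 90), fs = fs,
                        half_window_s = 4, step_s = 0.01, nrem = nrem_all(120))
  expect_equal(xc$peak_lag_s, -0.07, tolerance = 1e-9)
  expect_gt(xc$peak_coef, 0.99)
})

test_that("fast correlogram matches the naive per-lag Pearson oracle to 1e-10", {
  fs <- 100
  env_a <- smooth_env(30 * fs, seed = 3)
  env_r <- smooth_env(30 * fs, seed = 4)
  anchors <- c(10, 15, 20)
  xc <- amplitude_xcorr(env_r, env_a, anchors, fs, half_window_s = 2,
                        step_s = 0.01, nrem = nrem_all(30))
  oracle <- naive_amplitude_xcorr(env_r, env_a, anchors, fs, half_window_s = 2,
                                  step_s = 0.01, nrem = nrem_all(30))
  expect_equal(oracle$n, xc$n_windows)
  expect_lt(max(abs(xc$coefs - oracle$coefs)), 1e-10)
  expect_equal(xc$lags_s, oracle$lags_s)
})

test_that("anchors whose windows cross NREM boundaries are dropped", {
  fs <- 100
  env <- smooth_env(200 * fs)
  nrem <- data.frame(start_s = c(0, 120), end_s = c(100, 200))
  # 50 is safe; 95 is within 2W = 8 s of a segment edge; 110 is in WAKE
  xc <- amplitude_xcorr(env, env, c(50, 95, 110, 160), fs,
                        half_window_s = 4, step_s = 0.01, nrem = nrem)
  expect_equal(xc$n_windows, 2)
  expect_error(amplitude_xcorr(env, env, c(0.5, 99), fs, half_window_s = 4,
                               step_s = 0.01, nrem = nrem), "anchors")
})

test_that("shuffle null is seed-reproducible and applies the documented rule", {
  fs <- 100
  set.seed(10)
  n <- 400 * fs
  renv <- smooth_env(n, seed = 5)
  aenv <- smooth_env(n, seed = 6)
  anchors <- seq(20, 380, by = 20)
  nt1 <- shuffle_null_test(renv, aenv, anchors, fs, half_window_s = 4,
                           step_s = 0.01, nrem = nrem_all(400),
                           n_shuffles = 100, seed = 42)
  nt2 <- shuffle_null_test(renv, aenv, anchors, fs, half_window_s = 4,
                           step_s = 0.01, nrem = nrem_all(400),
                           n_shuffles = 100, seed = 42)
  expect_identical(nt1$null_peaks, nt2$null_peaks)
  nt3 <- shuffle_null_test(renv, aenv, anchors, fs, half_window_s = 4,
                           step_s = 0.01, nrem = nrem_all(400),
                           n_shuffles = 100, seed = 43)
  expect_false(identical(nt1$null_peaks, nt3$null_peaks))
  expect_equal(nt1$observed_peak, nt3$observed_peak)
  # nearest-rank 99th percentile is the maximum of the lowest 99, and
  # significance is strict exceedance
  expect_equal(nt1$pct99, sort(nt1$null_peaks)[99])
  expect_equal(nt1$is_significant, nt1$observed_peak > nt1$pct99)
  # insufficient NREM for the 10 s shifts
  expect_error(shuffle_null_test(renv[1:(15 * fs)], aenv[1:(15 * fs)],
                                 c(7), fs, half_window_s = 2, step_s = 0.01,
                                 nrem = nrem_all(15)), "insufficient NREM")
})

test_that("timestamp correlogram recovers exact event-train lags", {
  nrem <- nrem_all(600)
  sp <- seq(20, 580, by = 12)
  xc0 <- timestamp_xcorr(sp, sp, half_window_s = 4, bin_s = 0.1, nrem = nrem)
  expect_equal(xc0$peak_lag_s, 0)
  expect_equal(xc0$peak_coef, 1, tolerance = 1e-12)
  # ripples exactly 0.5 s after spindles: spindle leads, positive lag
  xc <- timestamp_xcorr(sp + 0.5, sp, half_window_s = 4, bin_s = 0.1,
                        nrem = nrem)
  expect_equal(xc$peak_lag_s, 0.5, tolerance = 1e-9)
  # brute-force oracle at a handful of lags
  nb <- ceiling(600 / 0.1)
  mk <- function(t) { v <- numeric(nb); v[floor(t / 0.1) + 1] <- 1; v }
  x <- mk(sp); y <- mk(sp + 0.5)
  for (k in c(-10, 0, 5, 10)) {
    i <- max(1, 1 - k):min(nb, nb - k)
    expect_equal(xc$coefs[xc$lags_s == k * 0.1], cor(x[i], y[i + k]),
                 tolerance = 1e-12)
  }
  expect_error(timestamp_xcorr(numeric(0), sp, nrem = nrem), "non-empty")
})

test_that("joint occurrence rate counts each ripple once within the window", {
  expect_equal(joint_occurrence_rate(c(10.1, 19.0, 30.2), c(10, 20, 30)), 2 / 3)
  expect_equal(joint_occurrence_rate(numeric(0), c(10, 20)), 0)
  expect_error(joint_occurrence_rate(c(1, 2), numeric(0)), "zero spindles")
  # exhaustive O(n^2) oracle over 100 seeded random instances
  for (s in 1:100) {
    set.seed(s)
    rt <- sort(runif(50, 0, 600))
    st <- sort(runif(50, 0, 600))
    oracle <- sum(vapply(rt, function(r) any(abs(r - st) <= 0.25),
                         logical(1))) / length(st)
    expect_identical(joint_occurrence_rate(rt, st, 0.25), oracle)
  }
})

test_that("ripple-delta correlogram anchors at delta onsets with a 0.5 s window", {
  fs <- 100
  env <- smooth_env(120 * fs, seed = 8)
  ev <- data.frame(kind = "delta", start_s = c(30, 60, 90),
                   end_s = c(30.25, 60.25, 90.25))
  ev$center_s <- ev$start_s + 0.125
  ev$peak_time_s <- ev$center_s
  ev$peak_amp <- 1
  ev$onset_s <- ev$start_s
  es <- event_set("delta", ev)
  xc <- ripple_delta_xcorr(env, env, es, fs, nrem_all(120))
  expect_equal(xc$anchor, "delta_onset")
  expect_equal(xc$half_window_s, 0.5)
  expect_equal(xc$peak_lag_s, 0)
  expect_equal(xc$peak_coef, 1, tolerance = 1e-12)
  expect_equal(length(xc$lags_s), 101)
})

test_that("baseline normalization is a guarded ratio", {
  expect_equal(normalize_to_baseline(0.04, 0.02), 2)
  expect_equal(normalize_to_baseline(0.03, 0.03), 1)
  expect_error(normalize_to_baseline(0.04, 0), "zero")
})

test_that("swapping the envelopes mirrors the correlogram (stationary fixture)", {
  fs <- 100
  n <- 400 * fs
  a <- smooth_env(n, seed = 12, k = 25)
  b <- smooth_env(n, seed = 13, k = 25)
  anchors <- seq(20, 380, by = 10)
  f <- amplitude_xcorr(b, a, anchors, fs, half_window_s = 2, step_s = 0.02,
                       nrem = nrem_all(400))
  g <- amplitude_xcorr(a, b, anchors, fs, half_window_s = 2, step_s = 0.02,
                       nrem = nrem_all(400))
  # r_swap(-tau) ~ r(tau); exact only in the infinite-window limit, so allow
  # a small tolerance on this many-anchor average
  expect_lt(max(abs(rev(g$coefs) - f$coefs)), 0.1)
})
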