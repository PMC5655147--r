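# Rule fixtures are built directly as envelopes: a wiggly baseline around 1
# (so the baseline SD is finite) with rectangular supra-threshold bumps of
# controlled width and spacing.
env_fixture <- function(fs, dur, bumps, amp = 5) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  env <- 1 + 0.1 * sin(2 * pi * 3 * t)
  for (b in bumps) {
    i <- (round(b[1] * fs) + 1):round((b[1] + b[2]) * fs)
    env[i] <- amp
  }
  env
}

test_that("sub-merge-gap interruptions are merged; wider gaps are not", {
  fs <- 1000
  # two 30 ms bumps separated by a 40 ms gap: under the ripple profile
  # (merge < 50 ms) they are one event
  env <- env_fixture(fs, 60, list(c(30, 0.03), c(30.07, 0.03)))
  es <- detect_threshold_events(env, fs, detection_params("ripple"),
                                nrem_all(60), kind = "ripple")
  expect_equal(n_events(es), 1)
  expect_lt(abs(es$events$start_s - 30), 0.005)
  expect_lt(abs(es$events$end_s - 30.1), 0.005)
  # a 60 ms gap stays two events
  env2 <- env_fixture(fs, 60, list(c(30, 0.03), c(30.09, 0.03)))
  es2 <- detect_threshold_events(env2, fs, detection_params("ripple"),
                                 nrem_all(60), kind = "ripple")
  expect_equal(n_events(es2), 2)
})

test_that("duration bounds reject short and long spindle candidates", {
  fs <- 1000
  # 150 ms (too short), 300 ms (accepted), 2.5 s (too long), far apart
  env <- env_fixture(fs, 120, list(c(20, 0.15), c(50, 0.30), c(80, 2.5)))
  es <- detect_threshold_events(env, fs, detection_params("spindle"),
                                nrem_all(120), kind = "spindle")
  expect_equal(n_events(es), 1)
  expect_lt(abs(es$events$start_s - 50), 0.005)
  expect_lt(abs((es$events$end_s - es$events$start_s) - 0.3), 0.01)
  # delta profile: 600 ms run rejected by the 500 ms maximum, 300 ms accepted
  envd <- env_fixture(fs, 120, list(c(20, 0.6), c(60, 0.3)))
  esd <- detect_threshold_events(envd, fs, detection_params("delta"),
                                 nrem_all(120), kind = "delta")
  expect_equal(n_events(esd), 1)
  expect_lt(abs(esd$events$start_s - 60), 0.005)
})

test_that("merging happens before duration filtering", {
  fs <- 1000
  # a 400 ms spindle split by a 60 ms dip into 170 ms halves: each half alone
  # fails the 200 ms minimum, so filtering first would discard the event
  env <- env_fixture(fs, 60, list(c(30, 0.17), c(30.23, 0.17)))
  es <- detect_threshold_events(env, fs, detection_params("spindle"),
                                nrem_all(60), kind = "spindle")
  expect_equal(n_events(es), 1)
  expect_gt(es$events$end_s - es$events$start_s, 0.35)
})

test_that("events honour the NREM mask and are clipped at its edges", {
  fs <- 1000
  nrem <- data.frame(start_s = c(10, 40), end_s = c(30, 60))
  # one bump in WAKE (t = 32), one inside NREM (t = 20)
  env <- env_fixture(fs, 70, list(c(32, 0.3), c(20, 0.3)))
  es <- detect_threshold_events(env, fs, detection_params("spindle"), nrem,
                                kind = "spindle")
  expect_equal(n_events(es), 1)
  expect_lt(abs(es$events$start_s - 20), 0.005)
  # a bump straddling the NREM edge at 30 s is truncated there
  env2 <- env_fixture(fs, 70, list(c(29.75, 0.5)))
  es2 <- detect_threshold_events(env2, fs, detection_params("spindle"), nrem,
                                 kind = "spindle")
  expect_equal(n_events(es2), 1)
  expect_lte(es2$events$end_s, 30 + 1e-6)
  expect_gt(es2$events$end_s - es2$events$start_s, 0.2)
})

test_that("raising the threshold never increases the event count", {
  fs <- 500
  set.seed(11)
  env <- abs(1 + 0.5 * stats::filter(rnorm(60 * fs), rep(0.2, 5), sides = 2))
  env[is.na(env)] <- 1
  counts <- vapply(c(1, 1.5, 2, 2.5, 3), function(k) {
    n_events(detect_threshold_events(as.numeric(env), fs,
                                     detection_params("custom", 1, 100,
                                                      threshold_sd = k),
                                     nrem_all(60), kind = "ripple"))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("degenerate envelopes and empty NREM are rejected", {
  fs <- 500
  expect_error(detect_threshold_events(rep(1, 30 * fs), fs,
                                       detection_params("ripple"),
                                       nrem_all(30)), "degenerate")
  expect_error(detect_threshold_events(rep(1, 30 * fs), fs,
                                       detection_params("ripple"),
                                       data.frame(start_s = numeric(0),
                                                  end_s = numeric(0))), "empty")
})

test_that("detection is invariant to a DC offset on the raw LFP", {
  g <- cached_session(seed = 7, duration_s = 660, fs = 1000)
  rec <- g$recording
  rec_dc <- recording(lapply(rec$channels, function(x) x + 40), fs = rec$fs)
  hyp <- g$truth$hypnogram
  sp1 <- detect_spindles(rec, hyp)
  sp2 <- detect_spindles(rec_dc, hyp)
  # the zero-phase IIR filter attenuates DC by ~1e5, so boundary samples can
  # shift by at most a sample or two
  expect_equal(n_events(sp1), n_events(sp2))
  expect_lt(max(abs(sp1$events$start_s - sp2$events$start_s)), 0.01)
  expect_equal(sp1$events$peak_amp, sp2$events$peak_amp, tolerance = 1e-3)
})

test_that("detectors recover the majority of implanted events on a synthetic session", {
  g <- cached_session(seed = 7, duration_s = 660, fs = 1000)
  rec <- g$recording; tr <- g$truth; hyp <- tr$hypnogram
  rp <- detect_ripples(rec, hyp)
  m <- match_rates(rp$events$peak_time_s, tr$ripple_times, tol = 0.05)
  expect_gt(m$recall, 0.8)
  # spindle detection at snr 5 is marginal by construction (the 2 SD
  # threshold sits at ~0.6 of the event envelope peak); half recovery is
  # what the rule achieves here
  sp <- detect_spindles(rec, hyp)
  ms <- match_rates(sp$events$center_s, tr$spindle_times, tol = 0.3)
  expect_gt(ms$recall, 0.45)
  dl <- detect_deltas(rec, hyp)
  md <- match_rates(dl$events$center_s, tr$delta_times, tol = 0.25)
  expect_gt(md$recall, 0.6)
  # all detected events lie inside NREM
  expect_true(all(state_at(hyp, rp$events$start_s) == "NREM"))
  expect_true(all(state_at(hyp, sp$events$start_s) == "NREM"))
})

test_that("incidence and amplitude summaries follow their definitions", {
  h <- hypnogram(data.frame(start_s = c(0, 100), end_s = c(100, 700),
                            state = c("WAKE", "NREM")), 700)
  ev <- data.frame(kind = "ripple", start_s = seq(110, 690, by = 20),
                   end_s = seq(110, 690, by = 20) + 0.05)
  ev$center_s <- (ev$start_s + ev$end_s) / 2
  ev$peak_time_s <- ev$start_s
  ev$peak_amp <- 3
  ev$onset_s <- ev$start_s
  es <- event_set("ripple", ev[1:30, ])
  expect_equal(event_incidence(es, h), 30 / 10)
  expect_equal(n_events(event_set("ripple", ev[0, ])), 0)
  expect_equal(event_incidence(event_set("ripple", ev[0, ]), h), 0)
  # doubling NREM halves incidence
  h2 <- hypnogram(data.frame(start_s = 0, end_s = 1300, state = "NREM"), 1300)
  h2 <- hypnogram(data.frame(start_s = c(0, 100), end_s = c(100, 1300),
                             state = c("WAKE", "NREM")), 1300)
  expect_equal(event_incidence(es, h2), event_incidence(es, h) / 2)
  # amplitude summary
  ev2 <- ev[1:2, ]; ev2$peak_amp <- c(2, 4)
  expect_equal(event_amplitude_summary(event_set("ripple", ev2)), 3)
  ev1 <- ev[1, ]; ev1$peak_amp <- 5
  expect_equal(event_amplitude_summary(event_set("ripple", ev1)), 5)
  expect_error(event_amplitude_summary(event_set("ripple", ev[0, ])), "empty")
  h0 <- hypnogram(data.frame(start_s = 0, end_s = 700, state = "WAKE"), 700)
  expect_error(event_incidence(es, h0), "zero NREM")
})
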