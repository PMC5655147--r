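#' Configuration for the synthetic session generator
#'
#' Collects every knob of the three-channel synthetic recording generator.
#' Defaults emulate a 30-minute quiet-rest session dominated by NREM sleep
#' (long NREM blocks separated by brief wake, with short rare REM bouts),
#' digitized at 2 kHz. Event rates default to conventional rodent values
#' (ripples are the most frequent NREM event, spindles sparser); they are
#' assumptions of the generator, not measurements.
#'
#' @param duration_s Session length in seconds (>= 120).
#' @param fs Sampling rate in Hz (default 2000; `fs/2` must exceed 250 so
#'   the ripple band is representable).
#' @param state_block_s Named vector of mean block lengths per state in
#'   seconds, `c(WAKE=, NREM=, REM=)`. A zero mean drops the state.
#' @param state_sequence_mode `"fixed_blocks"` (deterministic cycle of the
#'   given lengths) or `"markov"` (exponential block durations with the
#'   given means).
#' @param ripple_rate_hz,spindle_rate_hz,delta_rate_hz Event rates in
#'   events per second of NREM.
#' @param p_couple Probability that a ripple is placed relative to a
#'   spindle centre rather than uniformly over NREM.
#' @param couple_lag_s Signed mean ripple-minus-spindle-centre lag in
#'   seconds; negative means the ripple leads.
#' @param couple_jitter_sd_s SD of Gaussian jitter added to the lag.
#' @param event_snr Ratio of the detection-band envelope at an implanted
#'   event peak to the background envelope SD in that band.
#' @param emg_wake_gain,emg_sleep_gain EMG noise amplitude during WAKE and
#'   NREM/REM respectively.
#' @param theta_rem_gain Amplitude of the 7 Hz REM theta component, in
#'   units of the channel's delta-band background envelope SD.
#' @param noise_exponent Spectral exponent of the 1/f^a LFP background.
#' @param ripple_freq_hz,ripple_dur_s Ripple burst carrier and duration.
#' @param spindle_freq_hz,spindle_dur_s Spindle burst carrier and duration.
#' @param delta_dur_s Duration of the half-wave delta deflection.
#' @param one_ripple_per_spindle Cap coupled ripples at one per spindle.
#' @param seed Integer seed; all randomness derives from it.
#' @return A named list of class `"synth_config"`.
#' @export
synth_config <- function(duration_s = 1800,
                         fs = 2000,
                         state_block_s = c(WAKE = 60, NREM = 240, REM = 20),
                         state_sequence_mode = c("fixed_blocks", "markov"),
                         ripple_rate_hz = 0.15,
                         spindle_rate_hz = 0.08,
                         delta_rate_hz = 0.2,
                         p_couple = 0,
                         couple_lag_s = -0.07,
                         couple_jitter_sd_s = 0.02,
                         event_snr = 5,
                         emg_wake_gain = 10,
                         emg_sleep_gain = 1,
                         theta_rem_gain = 3,
                         noise_exponent = 1,
                         ripple_freq_hz = 150,
                         ripple_dur_s = 0.08,
                         spindle_freq_hz = 13,
                         spindle_dur_s = 0.7,
                         delta_dur_s = 0.25,
                         one_ripple_per_spindle = TRUE,
                         seed = 1L) {
  state_sequence_mode <- match.arg(state_sequence_mode)
  stopifnot(duration_s >= 120, fs / 2 > 250,
            ripple_rate_hz >= 0, spindle_rate_hz >= 0, delta_rate_hz >= 0,
            p_couple >= 0, p_couple <= 1, couple_jitter_sd_s >= 0,
            event_snr > 0, seed == round(seed), abs(seed) < 2^31 - 16)
  stopifnot(all(c("WAKE", "NREM", "REM") %in% names(state_block_s)),
            state_block_s["NREM"] > 0)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a ground-truth state sequence
#'
#' `"fixed_blocks"` cycles WAKE -> NREM -> REM with exactly the configured
#' block lengths (zero-length states skipped), truncating the last block at
#' `duration_s`. `"markov"` draws each block length from an exponential
#' distribution with the configured mean (floored at 2 s), cycling the same
#' state order. REM defaults are short, reflecting how rarely sustained REM
#' appears in recordings of this length.
#'
#' @param cfg A `"synth_config"`.
#' @param seed Optional seed override (default `cfg$seed`).
#' @return A `"hypnogram"` covering `[0, duration_s)` with NREM total > 0.
#' @export
generate_state_sequence <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  order <- c("WAKE", "NREM", "REM")
  means <- cfg$state_block_s[order]
  order <- order[means > 0]
  means <- means[means > 0]
  set.seed(seed)
  starts <- numeric(0); ends <- numeric(0); states <- character(0)
  t <- 0; k <- 1L
  while (t < cfg$duration_s) {
    st <- order[(k - 1L) %% length(order) + 1L]
    len <- if (cfg$state_sequence_mode == "fixed_blocks") means[[st]]
           else max(2, stats::rexp(1, 1 / means[[st]]))
    e <- min(t + len, cfg$duration_s)
    starts <- c(starts, t); ends <- c(ends, e); states <- c(states, st)
    t <- e; k <- k + 1L
  }
  h <- hypnogram(data.frame(start_s = starts, end_s = ends, state = states),
                 cfg$duration_s)
  if (state_total_s(h, "NREM") <= 0) stop("generated hypnogram has no NREM", call. = FALSE)
  h
}

#' 1/f^a background noise via spectral shaping
#'
#' White Gaussian noise is transformed to the frequency domain, its
#' amplitudes scaled by `f^(-a/2)` (flattened below 0.5 Hz to avoid
#' unbounded drift), and transformed back.
#' @keywords internal
one_over_f_noise <- function(n, fs, alpha = 1) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)               # two-sided frequency magnitude
  shape <- pmax(f, 0.5)^(-alpha / 2)
  shape[1] <- 0                      # remove DC
  Re(stats::fft(X * shape, inverse = TRUE) / n)
}

#' Envelope SD of a signal in a band
#'
#' For generator calibration the SD is estimated on a prefix of the trace
#' (default 60 s): the background is stationary by construction, and 60 s
#' of a >= 3 Hz-wide band gives a relative standard error well under 1%.
#' @keywords internal
band_env_sd <- function(x, fs, low, high, max_s = Inf) {
  n <- min(length(x), round(max_s * fs))
  stats::sd(hilbert_envelope(bandpass_filter(x[seq_len(n)], fs, low, high)))
}

# Burst templates, unit peak amplitude -----------------------------------

ripple_waveform <- function(fs, dur_s, freq_hz) {
  t <- seq(-dur_s / 2, dur_s / 2, by = 1 / fs)
  exp(-t^2 / (2 * (dur_s / 6)^2)) * sin(2 * pi * freq_hz * t)
}

spindle_waveform <- function(fs, dur_s, freq_hz) {
  t <- seq(0, dur_s, by = 1 / fs)
  (0.5 - 0.5 * cos(2 * pi * t / dur_s)) * sin(2 * pi * freq_hz * t)  # Hann taper
}

delta_waveform <- function(fs, dur_s) {
  t <- seq(0, dur_s, by = 1 / fs)
  -sin(pi * t / dur_s)               # one half-wave (250 ms = half cycle of 2 Hz)
}

#' Scale a template so its filtered-envelope peak hits a target
#'
#' Measures the peak of the Hilbert envelope of the band-pass-filtered,
#' zero-padded template once, and returns the amplitude multiplier that
#' makes that peak equal `target`. This makes `event_snr` exact by
#' construction for the template alone (the background then adds in
#' quadrature).
#' @keywords internal
template_gain <- function(wave, fs, low, high, target) {
  pad <- round(2 * fs)
  padded <- c(numeric(pad), wave, numeric(pad))
  pk <- max(hilbert_envelope(bandpass_filter(padded, fs, low, high)))
  target / pk
}

#' Draw event centre times inside NREM
#'
#' Uniform placement over the NREM union, with a margin from interval
#' edges and a minimum separation between same-type events (rejection
#' sampling) so implanted events do not merge into each other.
#' @keywords internal
draw_event_times <- function(n, nrem, margin_s, min_sep_s) {
  if (n <= 0) return(numeric(0))
  lo <- nrem$start_s + margin_s
  hi <- nrem$end_s - margin_s
  ok <- hi > lo
  lo <- lo[ok]; hi <- hi[ok]
  if (length(lo) == 0) return(numeric(0))
  w <- hi - lo
  times <- numeric(0)
  attempts <- 0L
  while (length(times) < n && attempts < 200L * n) {
    seg <- sample.int(length(lo), 1, prob = w)
    t0 <- stats::runif(1, lo[seg], hi[seg])
    if (length(times) == 0 || min(abs(times - t0)) >= min_sep_s) {
      times <- c(times, t0)
    }
    attempts <- attempts + 1L
  }
  sort(times)
}

#' Locate the NREM interval containing a time (with margin), or 0
#' @keywords internal
in_nrem <- function(t, nrem, margin_s = 0) {
  any(t >= nrem$start_s + margin_s & t <= nrem$end_s - margin_s)
}

#' Draw the ground-truth event times for a session
#'
#' Event counts are Poisson in `rate x NREM seconds`; spindles and delta
#' waves are placed uniformly over NREM (with edge margins and a minimum
#' same-type separation so implanted events cannot merge). Each ripple is,
#' with probability `p_couple`, attached to an unused spindle at
#' `spindle centre + couple_lag_s + N(0, couple_jitter_sd_s)` (one ripple
#' per spindle by default); otherwise placed uniformly. Coupled draws that
#' would leave NREM fall back to uniform placement, flagged uncoupled.
#' Uses the seeded event sub-stream (`cfg$seed + 4`).
#' @keywords internal
draw_ground_truth_events <- function(cfg, nrem) {
  nrem_total <- sum(nrem$end_s - nrem$start_s)
  warnings <- character(0)
  set.seed(cfg$seed + 4L)
  n_sp <- stats::rpois(1, cfg$spindle_rate_hz * nrem_total)
  n_rp <- stats::rpois(1, cfg$ripple_rate_hz * nrem_total)
  n_dl <- stats::rpois(1, cfg$delta_rate_hz * nrem_total)
  for (kind in c("spindle", "ripple", "delta")) {
    rate <- cfg[[paste0(kind, "_rate_hz")]]
    if (rate > 0 && rate * nrem_total < 1) {
      warnings <- c(warnings, paste0("expected ", kind, " count < 1"))
    }
  }
  sp_margin <- cfg$spindle_dur_s / 2 + 0.1
  spindle_times <- draw_event_times(n_sp, nrem, sp_margin,
                                    min_sep_s = 2 * cfg$spindle_dur_s + 0.5)
  delta_times <- draw_event_times(n_dl, nrem, cfg$delta_dur_s / 2 + 0.1,
                                  min_sep_s = 2 * cfg$delta_dur_s + 0.3)
  rp_margin <- cfg$ripple_dur_s / 2 + 0.05
  ripple_times <- numeric(0)
  coupled_flags <- logical(0)
  free_spindles <- seq_along(spindle_times)
  for (i in seq_len(n_rp)) {
    placed <- FALSE
    if (stats::runif(1) < cfg$p_couple &&
        (length(free_spindles) > 0 || !cfg$one_ripple_per_spindle)) {
      pool <- if (cfg$one_ripple_per_spindle) free_spindles else seq_along(spindle_times)
      if (length(pool) > 0) {
        j <- pool[sample.int(length(pool), 1)]
        t0 <- spindle_times[j] + cfg$couple_lag_s +
          if (cfg$couple_jitter_sd_s > 0) stats::rnorm(1, 0, cfg$couple_jitter_sd_s) else 0
        if (in_nrem(t0, nrem, rp_margin)) {
          ripple_times <- c(ripple_times, t0)
          coupled_flags <- c(coupled_flags, TRUE)
          if (cfg$one_ripple_per_spindle) free_spindles <- setdiff(free_spindles, j)
          placed <- TRUE
        }
      }
    }
    if (!placed) {
      t0 <- draw_event_times(1, nrem, rp_margin, min_sep_s = 0)
      if (length(t0) == 1) {
        ripple_times <- c(ripple_times, t0)
        coupled_flags <- c(coupled_flags, FALSE)
      }
    }
  }
  ord <- order(ripple_times)
  list(ripple_times = ripple_times[ord], spindle_times = spindle_times,
       delta_times = delta_times, coupled_flags = coupled_flags[ord],
       warnings = warnings)
}

#' Generate a synthetic three-channel session with ground truth
#'
#' Builds a `CA1_LFP` + `ACC_LFP` + `EMG` recording from the configured
#' state sequence:
#'
#' * both LFP channels carry 1/f^a background noise, normalized so the
#'   100-250 Hz Hilbert-envelope SD is 1 unit (making `event_snr`
#'   interpretable in envelope units);
#' * CA1 receives Gaussian-windowed ripple bursts at ripple times plus an
#'   attenuated copy of the delta deflections (delta-band leakage);
#' * ACC receives Hann-windowed spindle bursts at spindle times and
#'   half-wave delta deflections at delta times;
#' * during REM both LFPs carry a 7 Hz theta component that dominates the
#'   delta band;
#' * EMG is broadband noise whose amplitude is `emg_wake_gain` during WAKE
#'   and `emg_sleep_gain` during NREM/REM, with 0.5 s ramps at
#'   transitions.
#'
#' Event counts are Poisson in `rate x NREM seconds`. With probability
#' `p_couple` a ripple is placed at a paired spindle centre plus
#' `couple_lag_s` plus Gaussian jitter (at most one ripple per spindle by
#' default); otherwise uniformly over NREM. A coupled draw that would fall
#' outside NREM falls back to uniform placement and is flagged uncoupled.
#'
#' Independent seeded sub-streams drive the state sequence, the noise of
#' each channel, and the event times, so changing one component leaves the
#' others fixed.
#'
#' @param cfg A `"synth_config"`.
#' @return List with elements `recording` (an `"lfp_recording"`) and
#'   `truth` (class `"synth_truth"`: `hypnogram`, `ripple_times`,
#'   `spindle_times`, `delta_times`, `coupled_flags`, `config`,
#'   `warnings`).
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$p_couple > 0 && cfg$spindle_rate_hz == 0) {
    stop("p_couple > 0 requires a positive spindle rate", call. = FALSE)
  }
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  hyp <- generate_state_sequence(cfg, seed = cfg$seed)
  nrem <- state_intervals(hyp, "NREM")
  nrem_total <- sum(nrem$end_s - nrem$start_s)
  warnings <- character(0)

  # --- backgrounds (independent noise sub-streams) ---
  set.seed(cfg$seed + 1L); ca1 <- one_over_f_noise(n, fs, cfg$noise_exponent)
  set.seed(cfg$seed + 2L); acc <- one_over_f_noise(n, fs, cfg$noise_exponent)
  ca1 <- ca1 / band_env_sd(ca1, fs, 100, 250, max_s = 60)
  acc <- acc / band_env_sd(acc, fs, 100, 250, max_s = 60)
  ca1_delta_sd <- band_env_sd(ca1, fs, 1, 4, max_s = 60)
  acc_spindle_sd <- band_env_sd(acc, fs, 12, 15, max_s = 60)
  acc_delta_sd <- band_env_sd(acc, fs, 1, 4, max_s = 60)

  # --- event times (own sub-stream) ---
  ev <- draw_ground_truth_events(cfg, nrem)
  warnings <- c(warnings, ev$warnings)
  spindle_times <- ev$spindle_times
  delta_times <- ev$delta_times
  ripple_times <- ev$ripple_times
  coupled_flags <- ev$coupled_flags

  # --- implant templates, calibrated so the detection-band envelope peak
  #     equals event_snr background-envelope SDs ---
  rp_wave <- ripple_waveform(fs, cfg$ripple_dur_s, cfg$ripple_freq_hz)
  rp_wave <- rp_wave * template_gain(rp_wave, fs, 100, 250, cfg$event_snr * 1)
  sp_wave <- spindle_waveform(fs, cfg$spindle_dur_s, cfg$spindle_freq_hz)
  sp_wave <- sp_wave * template_gain(sp_wave, fs, 12, 15, cfg$event_snr * acc_spindle_sd)
  dl_wave <- delta_waveform(fs, cfg$delta_dur_s)
  dl_wave <- dl_wave * template_gain(dl_wave, fs, 1, 4, cfg$event_snr * acc_delta_sd)

  add_at <- function(x, wave, centre_s) {
    half <- (length(wave) - 1) %/% 2
    for (t0 in centre_s) {
      i0 <- round(t0 * fs) + 1L - half
      i1 <- max(1L, i0); i2 <- min(n, i0 + length(wave) - 1L)
      if (i2 >= i1) x[i1:i2] <- x[i1:i2] + wave[(i1 - i0 + 1L):(i2 - i0 + 1L)]
    }
    x
  }
  ca1 <- add_at(ca1, rp_wave, ripple_times)
  acc <- add_at(acc, sp_wave, spindle_times)
  acc <- add_at(acc, dl_wave, delta_times)
  ca1 <- add_at(ca1, 0.4 * dl_wave * (ca1_delta_sd / acc_delta_sd), delta_times)

  # --- REM theta (7 Hz), amplitude tied to each channel's delta-band SD ---
  rem <- state_intervals(hyp, "REM")
  if (nrow(rem) > 0) {
    tvec <- (seq_len(n) - 1) / fs
    gate <- state_gate(rem, n, fs, ramp_s = 0.5)
    theta <- sin(2 * pi * 7 * tvec)
    ca1 <- ca1 + cfg$theta_rem_gain * ca1_delta_sd * sqrt(2) * gate * theta
    acc <- acc + cfg$theta_rem_gain * acc_delta_sd * sqrt(2) * gate * theta
  }

  # --- EMG: state-gated broadband noise ---
  set.seed(cfg$seed + 3L)
  emg_noise <- stats::rnorm(n)
  wake <- state_intervals(hyp, "WAKE")
  wake_gate <- if (nrow(wake) > 0) state_gate(wake, n, fs, ramp_s = 0.5) else numeric(n)
  emg <- emg_noise * (cfg$emg_sleep_gain + (cfg$emg_wake_gain - cfg$emg_sleep_gain) * wake_gate)

  rec <- recording(list(CA1_LFP = ca1, ACC_LFP = acc, EMG = emg), fs = fs,
                   meta = list(generator = "lfpcoupling::generate_recording",
                               seed = cfg$seed))
  truth <- structure(list(hypnogram = hyp, ripple_times = ripple_times,
                          spindle_times = spindle_times, delta_times = delta_times,
                          coupled_flags = coupled_flags, config = cfg,
                          warnings = warnings),
                     class = "synth_truth")
  list(recording = rec, truth = truth)
}

#' Smooth 0/1 gate over a set of intervals (raised-cosine ramps)
#' @keywords internal
state_gate <- function(intervals, n, fs, ramp_s = 0.5) {
  gate <- numeric(n)
  ramp_n <- max(1L, round(ramp_s * fs))
  ramp <- 0.5 - 0.5 * cos(pi * seq_len(ramp_n) / ramp_n)
  for (k in seq_len(nrow(intervals))) {
    i1 <- max(1L, floor(intervals$start_s[k] * fs) + 1L)
    i2 <- min(n, ceiling(intervals$end_s[k] * fs))
    if (i2 < i1) next
    seg <- rep(1, i2 - i1 + 1L)
    m <- min(ramp_n, length(seg))
    seg[seq_len(m)] <- pmin(seg[seq_len(m)], ramp[seq_len(m)])
    seg[(length(seg) - m + 1L):length(seg)] <-
      pmin(seg[(length(seg) - m + 1L):length(seg)], rev(ramp[seq_len(m)]))
    gate[i1:i2] <- pmax(gate[i1:i2], seg)
  }
  gate
}

#' Write ground truth as CSV + JSON
#'
#' Event times go to `<path>_events.csv` (columns `kind,center_s,coupled`),
#' the hypnogram to `<path>_hypnogram.csv`, and the configuration to
#' `<path>_config.json`.
#' @param truth A `"synth_truth"`.
#' @param path Path stem.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synth_truth"))
  ev <- rbind(
    data.frame(kind = "ripple", center_s = truth$ripple_times,
               coupled = truth$coupled_flags),
    data.frame(kind = "spindle",
               center_s = truth$spindle_times,
               coupled = rep(NA, length(truth$spindle_times))),
    data.frame(kind = "delta", center_s = truth$delta_times,
               coupled = rep(NA, length(truth$delta_times)))
  )
  utils::write.csv(ev, paste0(path, "_events.csv"), row.names = FALSE)
  write_hypnogram(truth$hypnogram, paste0(path, "_hypnogram.csv"))
  cfg <- truth$config
  cfg$state_block_s <- as.list(cfg$state_block_s)
  jsonlite::write_json(unclass(cfg), paste0(path, "_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
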