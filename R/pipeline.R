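#' Session analysis configuration
#'
#' Collects every tunable of the full-session analysis with its default:
#' detection parameter sets for the three oscillations, staging epoch
#' length and threshold multipliers, correlogram windows and lag steps,
#' shuffle settings, and the envelope decimation factor used for the
#' amplitude correlograms (envelopes are averaged down to the lag
#' resolution, 1/`amp_step_s` Hz, before correlation).
#'
#' @param ripple,spindle,delta `"detection_params"` for each detector.
#' @param lfp_role_staging LFP channel driving the theta/delta ratio.
#' @param epoch_s Staging epoch (s).
#' @param ratio_threshold_mult REM threshold multiple of the ratio mode.
#' @param amp_half_window_s,amp_step_s Amplitude-correlogram window and lag
#'   step (s).
#' @param ts_half_window_s,ts_bin_s Timestamp-correlogram window and bin (s).
#' @param joint_window_s Joint-occurrence half window (s).
#' @param delta_half_window_s Ripple-delta correlogram half window (s).
#' @param n_shuffles,shift_range_s,shuffle_mode Shuffle-null settings.
#' @param psd_window_s Welch segment length for band powers (s).
#' @return Named list of class `"session_config"`.
#' @export
session_config <- function(ripple = detection_params("ripple"),
                           spindle = detection_params("spindle"),
                           delta = detection_params("delta"),
                           lfp_role_staging = "CA1_LFP",
                           epoch_s = 2,
                           ratio_threshold_mult = 3.5,
                           amp_half_window_s = 4,
                           amp_step_s = 0.01,
                           ts_half_window_s = 4,
                           ts_bin_s = 0.1,
                           joint_window_s = 0.25,
                           delta_half_window_s = 0.5,
                           n_shuffles = 100,
                           shift_range_s = c(4, 10),
                           shuffle_mode = "global",
                           psd_window_s = 2) {
  structure(as.list(environment()), class = "session_config")
}

#' Run the full single-session analysis
#'
#' Composes every stage on one recording: sleep scoring, ripple / spindle
#' / delta detection within NREM, incidence and mean peak amplitude,
#' per-channel band-power fractions, and the three coupling measures
#' (amplitude cross-correlogram with shuffle null anchored at spindle
#' centres, timestamp cross-correlogram, joint occurrence rate) plus the
#' ripple-delta correlogram.
#'
#' If the session contains no NREM sleep, all NREM-dependent fields are
#' `NULL` with `reason = "no NREM"` recorded, and the report is still
#' returned.
#'
#' @param rec An `"lfp_recording"` (or a rawbin path).
#' @param config A `"session_config"`.
#' @param seed Seed for the shuffle null.
#' @param id Free-form recording identifier stored in the report.
#' @return Object of class `"session_report"`; see
#'   [write_session_report()] for the JSON serialization.
#' @export
run_session <- function(rec, config = session_config(), seed = 1L, id = "session") {
  if (is.character(rec)) rec <- read_recording(rec, "rawbin")
  stopifnot(inherits(rec, "lfp_recording"), inherits(config, "session_config"))
  fs <- rec$fs
  hyp <- score_sleep(rec, lfp_role = config$lfp_role_staging,
                     epoch_s = config$epoch_s,
                     ratio_threshold_mult = config$ratio_threshold_mult)
  arch <- sleep_architecture(hyp)

  band_power <- lapply(c(CA1_LFP = "CA1_LFP", ACC_LFP = "ACC_LFP"), function(role) {
    as.list(band_power_fractions(
      welch_psd(get_channel(rec, role), fs, window_s = config$psd_window_s)))
  })

  report <- list(id = id, seed = seed,
                 duration_s = recording_duration(rec), fs = fs,
                 architecture = arch, band_power = band_power,
                 params = serializable_config(config))

  if (arch$total_nrem_s <= 0) {
    report$events <- NULL
    report$coupling <- NULL
    report$reason <- "no NREM"
    report$hypnogram <- as.data.frame(hyp)
    class(report) <- "session_report"
    return(report)
  }

  nrem <- state_intervals(hyp, "NREM")
  ripples <- detect_ripples(rec, hyp, config$ripple)
  spindles <- detect_spindles(rec, hyp, config$spindle)
  deltas <- detect_deltas(rec, hyp, config$delta)

  ev_summary <- function(es) {
    list(n = n_events(es),
         incidence_per_min = event_incidence(es, hyp),
         mean_peak_amp = if (n_events(es) > 0) event_amplitude_summary(es) else NULL,
         reason = if (n_events(es) > 0) NULL else "no events detected")
  }

  # envelopes for the amplitude correlograms, decimated to the lag grid
  dec <- round(fs * config$amp_step_s)
  env_at <- function(role, lo, hi) {
    decimate_envelope(
      hilbert_envelope(bandpass_filter(get_channel(rec, role), fs, lo, hi)), dec)
  }
  fs_d <- fs / dec
  renv <- env_at("CA1_LFP", config$ripple$band_low_hz, config$ripple$band_high_hz)
  senv <- env_at("ACC_LFP", config$spindle$band_low_hz, config$spindle$band_high_hz)
  denv <- env_at("ACC_LFP", config$delta$band_low_hz, config$delta$band_high_hz)

  coupling <- list()
  if (n_events(spindles) == 0 || n_events(ripples) == 0) {
    coupling <- list(reason = "no ripple or spindle events; coupling undefined")
  } else {
    null_test <- try(shuffle_null_test(
      renv, senv, spindles$events$center_s, fs_d,
      half_window_s = config$amp_half_window_s, step_s = config$amp_step_s,
      nrem = nrem, n_shuffles = config$n_shuffles,
      shift_range_s = config$shift_range_s, seed = seed,
      mode = config$shuffle_mode), silent = TRUE)
    if (inherits(null_test, "try-error")) {
      coupling$amp_xcorr <- list(reason = attr(null_test, "condition")$message)
    } else {
      coupling$amp_xcorr <- list(
        peak_coef = null_test$observed_peak,
        peak_lag_s = null_test$observed$peak_lag_s,
        n_windows = null_test$observed$n_windows,
        null_pct99 = null_test$pct99,
        is_significant = null_test$is_significant)
      attr(coupling, "amp_xcorr_full") <- null_test
    }
    ts <- try(timestamp_xcorr(ripples, spindles,
                              half_window_s = config$ts_half_window_s,
                              bin_s = config$ts_bin_s, nrem = nrem), silent = TRUE)
    coupling$ts_xcorr <- if (inherits(ts, "try-error")) {
      list(reason = attr(ts, "condition")$message)
    } else {
      list(peak_coef = ts$peak_coef, peak_lag_s = ts$peak_lag_s)
    }
    coupling$joint_rate <- joint_occurrence_rate(ripples, spindles,
                                                 config$joint_window_s)
  }
  if (n_events(deltas) > 0 && n_events(ripples) > 0) {
    rd <- try(ripple_delta_xcorr(renv, denv, deltas, fs_d, nrem,
                                 half_window_s = config$delta_half_window_s,
                                 step_s = config$amp_step_s), silent = TRUE)
    coupling$ripple_delta_xcorr <- if (inherits(rd, "try-error")) {
      list(reason = attr(rd, "condition")$message)
    } else {
      list(peak_coef = rd$peak_coef, peak_lag_s = rd$peak_lag_s)
    }
  }

  report$events <- list(ripple = ev_summary(ripples),
                        spindle = ev_summary(spindles),
                        delta = ev_summary(deltas))
  report$coupling <- coupling
  report$hypnogram <- as.data.frame(hyp)
  attr(report, "event_sets") <- list(ripple = ripples, spindle = spindles,
                                     delta = deltas)
  class(report) <- "session_report"
  report
}

#' @keywords internal
serializable_config <- function(config) {
  lapply(unclass(config), function(v) if (inherits(v, "detection_params")) unclass(v) else v)
}

#' Write a session report as JSON
#'
#' Serialization is deterministic: the same report always produces the
#' same bytes (no timestamps are embedded).
#' @param report A `"session_report"`.
#' @param path Output JSON file.
#' @export
write_session_report <- function(report, path) {
  stopifnot(inherits(report, "session_report"))
  out <- report
  attributes(out) <- list(names = names(out))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  invisible(path)
}

#' Structural validation of a session-report JSON
#'
#' Checks a written report against the field schema shipped at
#' `inst/schema/session_report_schema.json` (required top-level and nested
#' field names).
#' @param path Report JSON path.
#' @return TRUE invisibly, or an error naming the missing field.
#' @export
validate_session_report <- function(path) {
  rep <- jsonlite::read_json(path)
  schema <- jsonlite::read_json(system.file("schema", "session_report_schema.json",
                                            package = "lfpcoupling"))
  check <- function(obj, req, where) {
    for (field in names(req)) {
      if (!(field %in% names(obj))) {
        stop("report missing required field '", where, field, "'", call. = FALSE)
      }
      if (is.list(req[[field]]) && length(req[[field]]) > 0 && !is.null(obj[[field]])) {
        check(obj[[field]], req[[field]], paste0(where, field, "."))
      }
    }
  }
  check(rep, schema$required_fields, "")
  invisible(TRUE)
}

#' Compare a post-training session to its pre-training baseline
#'
#' Forms the pre-normalized coupling ratios: post/pre for the amplitude
#' correlogram peak, the timestamp correlogram peak, and the joint
#' occurrence rate. A missing or zero pre value yields `NULL` for that
#' ratio with a reason.
#'
#' @param pre_report,post_report `"session_report"` objects.
#' @return List of class `"comparison_report"`.
#' @export
compare_sessions <- function(pre_report, post_report) {
  stopifnot(inherits(pre_report, "session_report"),
            inherits(post_report, "session_report"))
  ratio_or_null <- function(post, pre, label) {
    if (is.null(pre) || is.null(post)) {
      list(value = NULL, reason = paste0(label, ": missing pre or post value"))
    } else if (!is.finite(pre) || pre == 0) {
      list(value = NULL, reason = paste0(label, ": zero/non-finite pre value"))
    } else {
      list(value = normalize_to_baseline(post, pre), reason = NULL)
    }
  }
  structure(list(
    pre_id = pre_report$id, post_id = post_report$id,
    normalized_peak_amp_xcorr = ratio_or_null(
      post_report$coupling$amp_xcorr$peak_coef,
      pre_report$coupling$amp_xcorr$peak_coef, "amplitude xcorr peak"),
    normalized_ts_xcorr_peak = ratio_or_null(
      post_report$coupling$ts_xcorr$peak_coef,
      pre_report$coupling$ts_xcorr$peak_coef, "timestamp xcorr peak"),
    normalized_joint_rate = ratio_or_null(
      post_report$coupling$joint_rate,
      pre_report$coupling$joint_rate, "joint occurrence rate")
  ), class = "comparison_report")
}
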