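make_rec <- function(dur = 10, fs = 200, seed = 1) {
  set.seed(seed)
  n <- dur * fs
  recording(list(CA1_LFP = rnorm(n), ACC_LFP = rnorm(n), EMG = rnorm(n)), fs = fs)
}

test_that("recording constructor enforces roles, lengths and fs", {
  expect_error(recording(list(FOO = 1:10), fs = 100), "unknown channel role")
  expect_error(recording(list(CA1_LFP = 1:10, EMG = 1:5), fs = 100), "length mismatch")
  expect_error(recording(list(EMG = 1:10), fs = -1), "fs")
  rec <- make_rec()
  expect_equal(recording_duration(rec), 10)
})

test_that("rawbin round-trip is lossless for float64 and quantized for float32", {
  rec <- make_rec()
  p64 <- withr::local_tempfile(fileext = ".bin")
  write_recording(rec, p64, "rawbin", dtype = "float64")
  back <- read_recording(p64, "rawbin")
  expect_identical(back$channels$CA1_LFP, rec$channels$CA1_LFP)
  expect_identical(back$fs, rec$fs)
  p32 <- withr::local_tempfile(fileext = ".bin")
  write_recording(rec, p32, "rawbin", dtype = "float32")
  b32 <- read_recording(p32, "rawbin")
  expect_false(identical(b32$channels$CA1_LFP, rec$channels$CA1_LFP))
  expect_lt(max(abs(b32$channels$CA1_LFP - rec$channels$CA1_LFP)), 1e-6)
  # writing float32 twice reproduces the file bit-for-bit
  b32b <- read_recording(p32, "rawbin")
  expect_identical(b32$channels$ACC_LFP, b32b$channels$ACC_LFP)
})

test_that("rawbin sidecar errors name the missing field; truncated file is caught", {
  rec <- make_rec()
  p <- withr::local_tempfile(fileext = ".bin")
  write_recording(rec, p, "rawbin")
  sc <- jsonlite::read_json(paste0(p, ".json"))
  sc$fs <- NULL
  jsonlite::write_json(sc, paste0(p, ".json"), auto_unbox = TRUE)
  expect_error(read_recording(p, "rawbin"), "'fs'")
  expect_error(read_recording("/nonexistent/file.bin", "rawbin"), "not found")
  # sidecar declaring more samples than the file holds
  write_recording(rec, p, "rawbin")
  sc <- jsonlite::read_json(paste0(p, ".json"))
  sc$n_samples <- sc$n_samples + 10
  jsonlite::write_json(sc, paste0(p, ".json"), auto_unbox = TRUE)
  expect_error(read_recording(p, "rawbin"), "integrity")
})

test_that("EDF round-trip is exact to 16-bit quantization of the physical range", {
  rec <- make_rec(dur = 10, fs = 200)
  p <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, p, "edf")
  back <- read_recording(p, "edf")
  expect_named(back$channels, names(rec$channels))
  expect_equal(back$fs, rec$fs)
  for (role in names(rec$channels)) {
    x <- rec$channels[[role]]
    q <- diff(range(x)) / 2^16
    expect_lt(max(abs(back$channels[[role]] - x)), q + 1e-12)
  }
  # zero-signal recording round-trips to (near) zeros
  z <- recording(list(CA1_LFP = numeric(2000), EMG = numeric(2000)), fs = 200)
  pz <- withr::local_tempfile(fileext = ".edf")
  write_recording(z, pz, "edf")
  expect_lt(max(abs(read_recording(pz, "edf")$channels$CA1_LFP)), 1e-4)
})

test_that("EDF enforces the declared physical range and supports a role map", {
  rec <- make_rec()
  p <- withr::local_tempfile(fileext = ".edf")
  expect_error(
    write_recording(rec, p, "edf",
                    physical_range = list(CA1_LFP = c(-0.5, 0.5))),
    "physical range")
  write_recording(rec, p, "edf")
  mapped <- read_recording(p, "edf",
                           role_map = c(CA1_LFP = "CA1_LFP", ACC_LFP = "ACC_LFP",
                                        EMG = "EMG"))
  expect_named(mapped$channels, c("CA1_LFP", "ACC_LFP", "EMG"))
  expect_error(read_recording(p, "edf", role_map = c(OTHER = "EMG")),
               "role_map")
})

test_that("event tables round-trip events, params and the empty set", {
  ev <- data.frame(kind = "ripple",
                   start_s = c(1.123456789, 5.5, 9.000000001),
                   end_s = c(1.2, 5.75, 9.05),
                   center_s = c(1.161728394, 5.625, 9.025),
                   peak_time_s = c(1.15, 5.6, 9.01),
                   peak_amp = c(4.2, 5.1, 3.3))
  ev$onset_s <- ev$start_s
  es <- event_set("ripple", ev, params = detection_params("ripple"),
                  source_role = "CA1_LFP")
  p <- withr::local_tempfile(fileext = ".csv")
  write_event_table(es, p)
  back <- read_event_table(p)
  expect_equal(back$events$start_s, ev$start_s, tolerance = 1e-12)
  expect_equal(back$events$peak_amp, ev$peak_amp, tolerance = 1e-12)
  expect_equal(back$kind, "ripple")
  expect_equal(back$params$threshold_sd, 3)
  # empty set
  empty <- event_set("spindle", ev[0, ], params = detection_params("spindle"))
  write_event_table(empty, p)
  expect_equal(n_events(read_event_table(p)), 0)
})

test_that("malformed event rows error with their line number", {
  ev <- data.frame(kind = "delta", start_s = 2, end_s = 1, center_s = 1.5,
                   peak_time_s = 1.7, peak_amp = 2, onset_s = 2)
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# kind=delta",
               "kind,start_s,end_s,center_s,peak_time_s,peak_amp",
               "delta,2,1,1.5,1.7,2"), p)
  expect_error(read_event_table(p), "line 3")
  writeLines(c("# kind=delta",
               "kind,start_s,end_s,center_s,peak_time_s,peak_amp",
               "delta,1,2,1.5"), p)
  expect_error(read_event_table(p), "line 3")
})

test_that("hypnogram enforces coverage, merges same-state neighbours, looks up states", {
  h <- hypnogram(data.frame(start_s = c(0, 60, 180), end_s = c(60, 180, 200),
                            state = c("WAKE", "NREM", "NREM")), 200)
  expect_equal(nrow(h), 2)  # NREM neighbours merged
  expect_equal(state_total_s(h, "NREM"), 140)
  expect_equal(state_at(h, c(0, 59.99, 60, 199.9)),
               c("WAKE", "WAKE", "NREM", "NREM"))
  expect_true(is.na(state_at(h, 200)))  # half-open at the end
  expect_error(hypnogram(data.frame(start_s = c(0, 70), end_s = c(60, 200),
                                    state = c("WAKE", "NREM")), 200), "gaps")
  expect_error(hypnogram(data.frame(start_s = 0, end_s = 100, state = "NAP"), 100),
               "unknown state")
  # CSV round trip
  p <- withr::local_tempfile(fileext = ".csv")
  write_hypnogram(h, p)
  h2 <- read_hypnogram(p)
  expect_equal(as.data.frame(h2), as.data.frame(h))
  expect_equal(hypnogram_duration(h2), 200)
})
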