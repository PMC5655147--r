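#!/usr/bin/env Rscript
# Simulate a pre/post pair of synthetic dual-site sessions.
#
# The "pre-training" session has weak baseline ripple-spindle coupling and
# the "post-training" session strengthened coupling (higher p_couple),
# mimicking the learning-dependent increase the pipeline is built to
# quantify. Both are written as rawbin recordings with ground truth next
# to them, so every later stage can be checked against what was implanted.
#
# Sessions are 11 minutes at 1 kHz (reduced from the 2-kHz two-hour
# recordings the defaults emulate) to keep the full workflow quick.

library(lfpcoupling)

out_dir <- file.path("results", "data")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

base <- list(duration_s = 660, fs = 1000,
             state_block_s = c(WAKE = 60, NREM = 540, REM = 20),
             couple_lag_s = -0.07)

cfg_pre <- do.call(synth_config, c(base, list(p_couple = 0.15, seed = 101L)))
cfg_post <- do.call(synth_config, c(base, list(p_couple = 0.6, seed = 202L)))

for (tag in c("pre", "post")) {
  cfg <- if (tag == "pre") cfg_pre else cfg_post
  g <- generate_recording(cfg)
  write_recording(g$recording, file.path(out_dir, paste0(tag, ".bin")),
                  "rawbin", dtype = "float32")
  write_ground_truth(g$truth, file.path(out_dir, paste0(tag, "_truth")))
  tr <- g$truth
  cat(sprintf(
    "%s session: %.0f s (%.0f s NREM), %d ripples (%d coupled), %d spindles, %d deltas\n",
    tag, cfg$duration_s, state_total_s(tr$hypnogram, "NREM"),
    length(tr$ripple_times), sum(tr$coupled_flags),
    length(tr$spindle_times), length(tr$delta_times)))
}
cat("wrote recordings and ground truth under", out_dir, "\n")
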