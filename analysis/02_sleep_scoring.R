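#!/usr/bin/env Rscript
# Score sleep on the simulated sessions from EMG immobility and the
# adaptive theta/delta ratio, and check the hypnograms against the
# generator's ground truth.

library(lfpcoupling)

out_dir <- "results"
arch_rows <- list()
for (tag in c("pre", "post")) {
  rec <- read_recording(file.path(out_dir, "data", paste0(tag, ".bin")), "rawbin")
  hyp <- score_sleep(rec)
  write_hypnogram(hyp, file.path(out_dir, paste0(tag, "_hypnogram.csv")))
  truth <- read_hypnogram(file.path(out_dir, "data", paste0(tag, "_truth_hypnogram.csv")))
  tt <- seq(0.25, recording_duration(rec) - 0.25, by = 0.5)
  agree <- mean(state_at(hyp, tt) == state_at(truth, tt))
  a <- sleep_architecture(hyp)
  arch_rows[[tag]] <- data.frame(session = tag, agreement = round(agree, 3),
                                 total_nrem_s = a$total_nrem_s,
                                 n_nrem_epochs = a$n_nrem_epochs,
                                 mean_nrem_epoch_s = round(a$mean_nrem_epoch_s, 1),
                                 total_rem_s = a$total_rem_s,
                                 total_wake_s = a$total_wake_s)
  cat(sprintf("%s: %.1f%% agreement with ground truth; %.0f s NREM in %d bouts\n",
              tag, 100 * agree, a$total_nrem_s, a$n_nrem_epochs))
}
arch <- do.call(rbind, arch_rows)
write.csv(arch, file.path(out_dir, "sleep_architecture.csv"), row.names = FALSE)
cat("wrote", file.path(out_dir, "sleep_architecture.csv"), "\n")
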