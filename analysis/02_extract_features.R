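#!/usr/bin/env Rscript
# Stage 2 -- qEEG feature extraction for one subject.
#
# Reads subject 1's EEG back from the EDF written by stage 1, computes the
# three features (minAI, BSR, SEF) on 2-s bipolar intervals, and writes
# the per-derivation and channel-averaged feature tables. Logs per-stage
# counts so silent data loss is visible.

library(fetalqeeg)

out_dir <- "results"
edf <- file.path(out_dir, "raw", "subject1.edf")
if (!file.exists(edf)) stop("run analysis/01_simulate.R first")

rec <- read_eeg(edf, montage = montage_spec())
feats <- compute_features(rec)
write_features(feats, file.path(out_dir, "subject1_features.tsv"))

avg <- feats[feats$derivation == "average", ]
env_counts <- table(feats$derivation)
cat(sprintf("recording: %.0f s, %d channels\n",
            nrow(rec$samples) / rec$sample_rate_hz, ncol(rec$samples)))
cat(sprintf("intervals computed: %d per derivation (%s)\n",
            nrow(avg), paste(names(env_counts), collapse = ", ")))
cat(sprintf("SEF undefined (suppressed) intervals: %d of %d (%.2f%%)\n",
            sum(is.na(avg$sef_hz)), nrow(avg),
            100 * mean(is.na(avg$sef_hz))))
cat(sprintf("intervals with BSR > 0: %d\n", sum(avg$bsr_percent > 0)))
cat(sprintf("stability medians -- minAI %.1f uV, BSR %.1f%%, SEF %.2f Hz\n",
            median(avg$minai_uV[avg$interval_start_s < 3600]),
            median(avg$bsr_percent[avg$interval_start_s < 3600]),
            median(avg$sef_hz[avg$interval_start_s < 3600], na.rm = TRUE)))
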