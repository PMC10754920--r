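#!/usr/bin/env Rscript
# Stage 5 -- qEEG trend figures.
#
# Plots the channel-averaged BSR, SEF and minAI of subject 1 against time
# across the stability hour and the three occlusion phases, with occlusion
# events marked, in the style of a bedside qEEG trend display.

library(fetalqeeg)
library(ggplot2)

out_dir <- "results"
fig_dir <- file.path(out_dir, "figures")
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

f_feat <- file.path(out_dir, "subject1_features.tsv")
if (!file.exists(f_feat)) stop("run analysis/02_extract_features.R first")
feats <- read_features(f_feat)
schedule <- read_schedule(file.path(out_dir, "schedule.json"))

avg <- feats[feats$derivation == "average", ]
long <- rbind(
  data.frame(t = avg$interval_start_s, value = avg$bsr_percent, panel = "BSR (%)"),
  data.frame(t = avg$interval_start_s, value = avg$sef_hz, panel = "SEF (Hz)"),
  data.frame(t = avg$interval_start_s, value = avg$minai_uV, panel = "minAI (uV)"))
occ <- schedule$events[schedule$events$label == "occlusion", ]
phase_edges <- c(3600, 7200, 10800)

p <- ggplot(long, aes(t / 60, value)) +
  geom_rect(data = data.frame(xmin = occ$start_s / 60, xmax = occ$end_s / 60),
            aes(xmin = xmin, xmax = xmax, ymin = -Inf, ymax = Inf),
            inherit.aes = FALSE, fill = "red", alpha = 0.15) +
  geom_vline(xintercept = phase_edges / 60, linetype = "dashed",
             colour = "grey40") +
  geom_line(linewidth = 0.2, na.rm = TRUE) +
  facet_grid(panel ~ ., scales = "free_y") +
  labs(x = "time (min)  [dashed: S|A|B|C phase boundaries; red: occlusions]",
       y = NULL, title = "qEEG trends under progressive umbilical cord occlusion") +
  theme_minimal(base_size = 9)

ggsave(file.path(fig_dir, "subject1_qeeg_trends.pdf"), p,
       width = 10, height = 6)
cat("wrote", file.path(fig_dir, "subject1_qeeg_trends.pdf"), "\n")

# per-phase distribution of the channel-averaged features
avg$phase <- cut(avg$interval_start_s, c(-1, phase_edges, Inf),
                 labels = c("S", "A", "B", "C"))
p2 <- ggplot(tidyr::pivot_longer(avg, c("bsr_percent", "sef_hz", "minai_uV")),
             aes(phase, value)) +
  geom_boxplot(outlier.size = 0.3, na.rm = TRUE) +
  facet_wrap(~name, scales = "free_y") +
  theme_minimal(base_size = 9) +
  labs(x = "phase", y = NULL,
       title = "Per-interval qEEG features by protocol phase (subject 1)")
ggsave(file.path(fig_dir, "subject1_phase_boxplots.pdf"), p2,
       width = 8, height = 3.5)
cat("wrote", file.path(fig_dir, "subject1_phase_boxplots.pdf"), "\n")
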