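#!/usr/bin/env Rscript
# Stage 4 -- nonparametric statistical stage.
#
# Reads the per-subject phase summaries written by stage 3 and reports:
# (i) the Friedman repeated-measures test of each marker across phases
# (complete-case subjects), (ii) pairwise Wilcoxon signed-rank post-hoc
# tests where the Friedman test is significant at alpha = 0.05 (no
# multiple-testing correction, matching the source analysis), and
# (iii) the Spearman correlation grid between the six qEEG markers and
# the eight gasometric/haemodynamic markers over pooled subject-phase
# observations.

library(fetalqeeg)

out_dir <- "results"
f_long <- file.path(out_dir, "subject_summaries.tsv")
if (!file.exists(f_long)) stop("run analysis/03_phase_tables.R first")
long <- utils::read.delim(f_long, na.strings = "")
alpha <- 0.05

cat("Friedman tests across phases (complete-case subjects):\n")
for (mk in c("wBSR", "wSEF", "wminAI", "ocBSR", "ocSEF", "ocminAI",
             "pH", "pCO2", "pO2", "lactate", "pHR", "pMBP", "ocHR", "ocMBP")) {
  phases <- if (startsWith(mk, "oc")) c("A", "B", "C") else c("S", "A", "B", "C")
  grid <- feature_grid(long, mk, phases)
  res <- tryCatch(friedman_phases(grid), error = function(e) NULL)
  if (is.null(res)) {
    cat(sprintf("  %-8s insufficient complete cases\n", mk))
    next
  }
  cat(sprintf("  %-8s chi2(%d) = %6.2f, p = %.4f, n = %d%s\n", mk, res$df,
              res$statistic, res$p_value, res$n_used,
              if (res$p_value <= alpha) "  *" else ""))
  if (res$p_value <= alpha) {
    ph <- wilcoxon_posthoc(grid)
    for (j in seq_len(nrow(ph)))
      cat(sprintf("      %s vs %s: p = %.4f (%s)\n", ph$phase1[j],
                  ph$phase2[j], ph$p_value[j], ph$method[j]))
  }
}

obs <- cohort_observations(long)
corr <- correlation_table(obs)
write_report(corr, file.path(out_dir, "correlation_grid.tsv"))

cat("\nSpearman correlations (rho; p), qEEG rows x physiological columns:\n")
wide <- reshape(corr[, c("qeeg", "physio", "rho", "p_value")],
                idvar = "qeeg", timevar = "physio", direction = "wide")
print(wide, digits = 2, row.names = FALSE)
sig <- corr[!is.na(corr$p_value) & corr$p_value <= alpha, ]
cat(sprintf("\n%d of %d marker pairs significant at p <= %.2f\n",
            nrow(sig), nrow(corr), alpha))
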