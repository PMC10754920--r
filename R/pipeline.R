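# End-to-end cohort analysis: simulate each subject, extract qEEG
# features, reduce to phase summaries, and run the statistical stage.

#' Analyse one simulated subject
#'
#' @param subject List with `id` and `config` (an element of
#'   [simulate_cohort()]).
#' @param protocol A [protocol_config()].
#' @param montage A [montage_spec()].
#' @param ... Feature parameters forwarded to [compute_features()].
#' @return List with `schedule`, `features` (qEEG series), `summary`
#'   (per-phase marker medians), and `truncated_at_s`.
#' @export
analyze_subject <- function(subject, protocol = protocol_config(),
                            montage = montage_spec(), ...) {
  sim <- simulate_subject(subject$config, protocol)
  features <- compute_features(sim$eeg, montage, ...)
  summ <- subject_phase_summary(features, sim$physio, sim$schedule)
  list(schedule = sim$schedule, features = features, summary = summ,
       truncated_at_s = sim$schedule$truncated_at_s)
}

#' Analyse a cohort end to end
#'
#' Runs [analyze_subject()] over a cohort (discarding each subject's raw
#' signals once summarised), then assembles the cohort summary table, the
#' Friedman/Wilcoxon stage per qEEG and physiological marker, and the
#' Spearman correlation grid.
#'
#' @param cohort A `uco_cohort` from [simulate_cohort()].
#' @param protocol A [protocol_config()].
#' @param montage A [montage_spec()].
#' @param alpha Significance threshold gating the Wilcoxon post-hoc.
#' @param ... Forwarded to [compute_features()].
#' @return List with `subject_summaries` (long data frame), `table`
#'   (cohort medians/quartiles), `friedman`, `posthoc`, `correlations`.
#' @export
analyze_cohort <- function(cohort, protocol = protocol_config(),
                           montage = montage_spec(), alpha = 0.05, ...) {
  stopifnot(inherits(cohort, "uco_cohort"))
  summaries <- lapply(cohort, function(s) {
    res <- analyze_subject(s, protocol, montage, ...)
    cbind(subject = s$id, res$summary)
  })
  long <- do.call(rbind, summaries)
  tab <- cohort_table(long)

  markers <- c(QEEG_MARKERS, PHYSIO_MARKERS)
  fried <- list()
  posthoc <- list()
  for (mk in markers) {
    phases <- if (startsWith(mk, "oc")) c("A", "B", "C") else c("S", "A", "B", "C")
    grid <- feature_grid(long, mk, phases)
    res <- tryCatch(friedman_phases(grid), error = function(e) NULL)
    if (is.null(res)) next
    fried[[mk]] <- data.frame(feature = mk, statistic = res$statistic,
                              df = res$df, p_value = res$p_value,
                              n_used = res$n_used)
    if (!is.na(res$p_value) && res$p_value <= alpha) {
      ph <- wilcoxon_posthoc(grid)
      posthoc[[mk]] <- cbind(feature = mk, ph)
    }
  }
  obs <- cohort_observations(long)
  corr <- correlation_table(obs)
  list(subject_summaries = long, table = tab,
       friedman = do.call(rbind, c(fried, list(make.row.names = FALSE))),
       posthoc = if (length(posthoc) > 0)
         do.call(rbind, c(posthoc, list(make.row.names = FALSE))) else NULL,
       correlations = corr, observations = obs)
}

#' Summary-level cohort generator for statistical calibration
#'
#' Generates per-subject phase summary values directly at the level the
#' Friedman test consumes: value = subject offset + phase mean + noise.
#' With constant `phase_means` this is a null generator (no phase effect)
#' for type-I calibration; with a severity ladder it measures power, at a
#' fraction of the cost of re-simulating raw EEG for every replicate.
#'
#' @param n_subjects Number of subjects.
#' @param phase_means Named numeric vector of condition means.
#' @param subject_sd Between-subject SD of the additive subject offset.
#' @param noise_sd Within-subject residual SD.
#' @param seed Integer seed.
#' @return Numeric matrix subjects x conditions.
#' @export
simulate_summary_grid <- function(n_subjects, phase_means, subject_sd,
                                  noise_sd, seed) {
  k <- length(phase_means)
  with_substream(seed, "summary-grid", expr = {
    offs <- rnorm(n_subjects, 0, subject_sd)
    grid <- matrix(rep(phase_means, each = n_subjects), n_subjects, k) +
      offs + matrix(rnorm(n_subjects * k, 0, noise_sd), n_subjects, k)
    colnames(grid) <- names(phase_means)
    grid
  })
}

#' Estimate summary-generator parameters from a measured feature grid
#'
#' Decomposes a subjects x phases grid into phase means, a between-subject
#' offset SD and a residual SD, so calibration replicates can be generated
#' at the statistics the full pipeline actually produced.
#'
#' @param grid Numeric matrix subjects x phases (complete cases used).
#' @return List with `phase_means`, `subject_sd`, `noise_sd`.
#' @export
calibrate_summary_generator <- function(grid) {
  g <- grid[stats::complete.cases(grid), , drop = FALSE]
  n <- nrow(g)
  k <- ncol(g)
  phase_means <- colMeans(g)
  offs <- rowMeans(g) - mean(g)
  resid <- g - outer(offs, rep(1, k)) -
    matrix(rep(phase_means, each = n), n)
  # two-way additive decomposition: residual MS on (n-1)(k-1) df, and the
  # noise share of the subject-mean variance removed from the offset SD
  noise_var <- sum(resid^2) / ((n - 1) * (k - 1))
  subj_var <- max(sum(offs^2) / (n - 1) - noise_var / k, 0)
  list(phase_means = phase_means,
       subject_sd = sqrt(subj_var),
       noise_sd = sqrt(noise_var))
}
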