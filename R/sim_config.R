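#' Per-subject simulation configuration
#'
#' Defaults describe a near-term fetal sheep under the staged occlusion
#' protocol. Physiological levels are calibrated to the experiment's
#' reported phase medians: stability pH 7.39 falling to 6.98 at the last
#' pause of phase C, stability heart rate 186 bpm with per-occlusion
#' bradycardia to 85/80/79 bpm in phases A/B/C, mean blood pressure 48 mmHg
#' rising between occlusions (58/62/64 mmHg) and collapsing to 37 mmHg
#' during severe occlusions. EEG severity follows a ladder: the fraction of
#' amplitude retained during an occlusion is 0.8 (mild), 0.5 (moderate) and
#' 0.1 (severe), while the between-occlusion background progressively slows
#' and loses amplitude.
#'
#' @param seed Integer; fully determines all of the subject's signals.
#' @param baseline_spectrum Data frame `low_hz`, `high_hz`, `rel_power`:
#'   relative band powers shaping the stability EEG background.
#' @param baseline_amplitude_uV Target RMS amplitude of the stability EEG, uV.
#' @param suppression_depth Named (A, B, C) fraction of EEG amplitude
#'   retained during an occlusion (0 = isoelectric).
#' @param suppression_latency_s Seconds from occlusion onset to the start of
#'   suppression.
#' @param suppression_ramp_s Seconds over which the amplitude gain ramps
#'   between background and suppressed levels.
#' @param transient_wave_amplitude_uV Amplitude of the large slow transient
#'   waves that may accompany occlusion onset and release.
#' @param transient_wave_prob Probability that a given onset/release shows a
#'   transient wave.
#' @param background_slowing Named (S, A, B, C) multiplicative shift of the
#'   spectral band edges between occlusions (< 1 slows the background).
#' @param background_amplitude_scale Named (S, A, B, C) multiplicative
#'   amplitude factor of the between-occlusion background.
#' @param amplitude_modulation_depth,amplitude_modulation_period_s Slow
#'   sinusoidal amplitude lability of the background (depth as a fraction).
#' @param noise_floor_uV RMS of the unsuppressible instrumentation noise, uV.
#' @param hr_baseline_bpm Heart rate outside occlusions, bpm.
#' @param hr_occlusion_bpm Named (A, B, C) per-occlusion heart rate, bpm.
#' @param mbp_baseline_mmHg Stability mean blood pressure, mmHg.
#' @param mbp_pause_delta_mmHg Named (A, B, C) rise of between-occlusion MBP
#'   above baseline, mmHg.
#' @param mbp_occlusion_mmHg Named (A, B, C) per-occlusion MBP, mmHg.
#' @param hr_noise_bpm,mbp_noise_mmHg Gaussian noise SD of the 1-Hz series.
#' @param gas_trajectory Data frame `phase`, `ph`, `pco2`, `po2`, `lactate`:
#'   targets reached at the stability sample and the last pause of each
#'   phase; a dense latent trajectory interpolates between them.
#' @param gas_noise Named list of measurement noise SDs for `ph`, `pco2`,
#'   `po2`, `lactate`.
#' @return An object of class `subject_sim_config`.
#' @export
subject_sim_config <- function(
    seed = 1L,
    baseline_spectrum = data.frame(
      low_hz = c(0.5, 3.5, 8, 13, 30),
      high_hz = c(3.5, 8, 13, 30, 70),
      rel_power = c(0.60, 0.34, 0.045, 0.012, 0.003)),
    baseline_amplitude_uV = 11,
    suppression_depth = c(A = 0.8, B = 0.5, C = 0.1),
    suppression_latency_s = 5,
    suppression_ramp_s = 1,
    transient_wave_amplitude_uV = 60,
    transient_wave_prob = 0.5,
    background_slowing = c(S = 1, A = 0.95, B = 0.85, C = 0.75),
    background_amplitude_scale = c(S = 1, A = 0.95, B = 0.8, C = 0.7),
    amplitude_modulation_depth = 0.25,
    amplitude_modulation_period_s = 60,
    noise_floor_uV = 0.1,
    hr_baseline_bpm = 186,
    hr_occlusion_bpm = c(A = 85, B = 80, C = 79),
    mbp_baseline_mmHg = 48,
    mbp_pause_delta_mmHg = c(A = 10, B = 14, C = 16),
    mbp_occlusion_mmHg = c(A = 56, B = 54, C = 37),
    hr_noise_bpm = 3,
    mbp_noise_mmHg = 2,
    gas_trajectory = data.frame(
      phase = c("S", "A", "B", "C"),
      ph = c(7.39, 7.28, 7.10, 6.98),
      pco2 = c(45.3, 50.6, 54.0, 64.9),
      po2 = c(12, 16, 15, 16.5),
      lactate = c(2.27, 6.0, 12.8, 15.9)),
    gas_noise = list(ph = 0.01, pco2 = 1.0, po2 = 1.0, lactate = 0.3)) {
  stopifnot(all(suppression_depth >= 0), all(suppression_depth <= 1),
            baseline_amplitude_uV >= 0, transient_wave_amplitude_uV >= 0,
            suppression_latency_s >= 0,
            all(c("A", "B", "C") %in% names(suppression_depth)),
            all(c("S", "A", "B", "C") %in% names(background_slowing)),
            all(c("S", "A", "B", "C") %in% names(background_amplitude_scale)),
            all(c("low_hz", "high_hz", "rel_power") %in% names(baseline_spectrum)),
            all(baseline_spectrum$rel_power >= 0),
            all(c("S", "A", "B", "C") %in% gas_trajectory$phase))
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "subject_sim_config")
}

#' Simulate a cohort of subjects with inter-individual variability
#'
#' Draws `n` per-subject configurations around `base_config`, applying
#' seeded multiplicative jitter to amplitude, heart rate, blood pressure,
#' suppression depth and gasometric targets (additive on pH). Subject `i`
#' receives its own signal seed derived from `seed`, so a cohort is fully
#' reproducible from `(n, base_config, seed)` and signals can be generated
#' per subject with [simulate_subject()].
#'
#' @param n Number of subjects (>= 1).
#' @param base_config A `subject_sim_config` shared by the cohort.
#' @param seed Master cohort seed.
#' @param jitter Named list of jitter scales: `amplitude`, `hr`, `mbp`,
#'   `gas` (log-normal sdlog), `ph` (additive SD, pH units),
#'   `suppression` (SD on the logit of the retained fraction). Set all to 0
#'   for a homogeneous cohort.
#' @param overrides Optional list: `overrides[[i]]` is a named list of
#'   `subject_sim_config` fields replacing subject `i`'s jittered values
#'   (e.g. a gas trajectory that breaches the pH stop rule).
#' @return Object of class `uco_cohort`: list of subjects, each a list with
#'   `id` and `config`.
#' @export
simulate_cohort <- function(n, base_config = subject_sim_config(), seed = 1L,
                            jitter = list(amplitude = 0.15, hr = 0.04,
                                          mbp = 0.08, gas = 0.08, ph = 0.02,
                                          suppression = 0.25),
                            overrides = NULL) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- base_config
    with_substream(seed, "subject", i, "jitter", expr = {
      amp_f <- exp(rnorm(1, 0, jitter$amplitude))
      hr_f <- exp(rnorm(1, 0, jitter$hr))
      mbp_f <- exp(rnorm(1, 0, jitter$mbp))
      gas_f <- exp(rnorm(1, 0, jitter$gas))
      ph_d <- rnorm(1, 0, jitter$ph)
      sup_d <- rnorm(1, 0, jitter$suppression)
      cfg$baseline_amplitude_uV <- cfg$baseline_amplitude_uV * amp_f
      cfg$hr_baseline_bpm <- cfg$hr_baseline_bpm * hr_f
      cfg$hr_occlusion_bpm <- cfg$hr_occlusion_bpm * hr_f
      cfg$mbp_baseline_mmHg <- cfg$mbp_baseline_mmHg * mbp_f
      cfg$mbp_pause_delta_mmHg <- cfg$mbp_pause_delta_mmHg * mbp_f
      cfg$mbp_occlusion_mmHg <- cfg$mbp_occlusion_mmHg * mbp_f
      # shift retained fraction on the logit scale, keeping it in (0, 1)
      d <- pmin(pmax(cfg$suppression_depth, 1e-4), 1 - 1e-4)
      cfg$suppression_depth <- stats::plogis(stats::qlogis(d) + sup_d)
      cfg$gas_trajectory$ph <- cfg$gas_trajectory$ph + ph_d
      cfg$gas_trajectory$pco2 <- cfg$gas_trajectory$pco2 * gas_f
      cfg$gas_trajectory$lactate <- cfg$gas_trajectory$lactate * gas_f
    })
    if (!is.null(overrides) && length(overrides) >= i && !is.null(overrides[[i]])) {
      for (nm in names(overrides[[i]])) cfg[[nm]] <- overrides[[i]][[nm]]
    }
    cfg$seed <- substream_seed(seed, "subject", i, "signals")
    subjects[[i]] <- list(id = i, config = cfg)
  }
  structure(subjects, class = "uco_cohort")
}
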