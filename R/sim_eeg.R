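# EEG synthesis: coloured noise shaped in the frequency domain by a band
# power profile, amplitude-modulated by the occlusion schedule.

EEG_FS <- 256
EEG_CHANNELS <- c("F_left", "F_right", "P_left", "P_right")
EEG_BAND <- c(0.5, 70)

# Spectral density (power per Hz) at frequencies f for a band profile whose
# edges are multiplied by `slowing`; zero outside the acquisition band.
band_density <- function(f, spectrum, slowing = 1) {
  lo <- spectrum$low_hz * slowing
  hi <- spectrum$high_hz * slowing
  dens <- spectrum$rel_power / (hi - lo)
  out <- numeric(length(f))
  for (i in seq_along(lo)) {
    out <- out + dens[i] * (f >= lo[i] & f < hi[i])
  }
  out[f < EEG_BAND[1] | f > EEG_BAND[2]] <- 0
  out
}

# Gaussian noise with power spectrum proportional to `density(f)`, scaled
# to a target RMS. Shaping is exact in the frequency domain, so power
# outside the acquisition band is identically zero.
shaped_noise <- function(n, fs, density_at, rms) {
  if (n == 0) return(numeric(0))
  white <- rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f, fs - f)
  mask <- sqrt(density_at(f_fold))
  x <- Re(stats::fft(stats::fft(white) * mask, inverse = TRUE)) / n
  sd_x <- stats::sd(x)
  if (sd_x > 0) x <- x * (rms / sd_x)
  x
}

phase_spans <- function(schedule) {
  ev <- schedule$events
  phases <- intersect(c("S", "A", "B", "C"), unique(ev$phase))
  do.call(rbind, lapply(phases, function(ph) {
    e <- ev[ev$phase == ph, ]
    data.frame(phase = ph, start_s = min(e$start_s), end_s = max(e$end_s))
  }))
}

# Damped ~1 Hz high-amplitude wavelet spanning the 2 s after t = 0.
transient_wavelet <- function(t, amplitude_uV) {
  amplitude_uV * sin(2 * pi * 1 * t) * exp(-t / 0.7) * (t >= 0 & t <= 2)
}

#' Simulate multichannel fetal EEG under an occlusion schedule
#'
#' Generates 4 monopolar channels (left/right frontal and parietal) at
#' 256 Hz, band-limited to 0.5-70 Hz. The between-occlusion background is
#' coloured noise shaped by the configured band spectrum, with per-phase
#' spectral slowing and amplitude loss and a slow sinusoidal amplitude
#' lability. During each occlusion the amplitude is scaled down to the
#' phase's `suppression_depth` after `suppression_latency_s` (with a short
#' ramp), recovering at release; large damped slow waves may accompany
#' onset and release. An unsuppressible instrumentation noise floor
#' remains. All draws come from named substreams of the subject seed, so
#' the same `(schedule, config)` yields bit-identical samples.
#'
#' @param schedule A `uco_schedule` (possibly truncated by the stop rule).
#' @param config A [subject_sim_config()].
#' @return Object of class `eeg_recording`: list with `samples` (numeric
#'   matrix, one column per channel, uV), `channel_labels`,
#'   `sample_rate_hz`, `start_time_s`.
#' @export
simulate_eeg <- function(schedule, config) {
  stopifnot(inherits(schedule, "uco_schedule"),
            inherits(config, "subject_sim_config"))
  if (nrow(schedule$events) == 0) stop("empty schedule", call. = FALSE)
  fs <- EEG_FS
  total_s <- schedule_end_s(schedule)
  n_total <- round(total_s * fs)
  spans <- phase_spans(schedule)
  occl <- schedule$events[schedule$events$label == "occlusion", ]

  # shared across channels: occlusion amplitude gain and lability phase
  gain <- numeric(n_total)
  for (i in seq_len(nrow(spans))) {
    idx <- (round(spans$start_s[i] * fs) + 1):round(spans$end_s[i] * fs)
    gain[idx] <- config$background_amplitude_scale[[spans$phase[i]]]
  }
  am_phase <- with_substream(config$seed, "am", expr = runif(1, 0, 2 * pi))
  tt <- (seq_len(n_total) - 1) / fs
  gain <- gain * (1 + config$amplitude_modulation_depth *
                    sin(2 * pi * tt / config$amplitude_modulation_period_s + am_phase))

  sup_mult <- rep(1, n_total)
  ramp <- max(config$suppression_ramp_s, 1 / fs)
  for (i in seq_len(nrow(occl))) {
    depth <- config$suppression_depth[[occl$phase[i]]]
    t_on <- occl$start_s[i] + config$suppression_latency_s
    t_off <- occl$end_s[i]
    if (t_on >= t_off) next
    idx <- (floor(t_on * fs) + 1):min(ceiling((t_off + ramp) * fs), n_total)
    tseg <- tt[idx]
    m <- rep(depth, length(idx))
    down <- tseg < t_on + ramp
    m[down] <- 1 + (depth - 1) * (tseg[down] - t_on) / ramp
    up <- tseg >= t_off
    m[up] <- depth + (1 - depth) * (tseg[up] - t_off) / ramp
    m[tseg < t_on] <- 1
    sup_mult[idx] <- pmin(sup_mult[idx], m)
  }
  gain <- gain * sup_mult

  # transient large waves at occlusion onset/release, shared across channels
  transients <- numeric(n_total)
  if (nrow(occl) > 0 && config$transient_wave_prob > 0) {
    cand <- sort(c(occl$start_s, occl$end_s))
    cand <- cand[cand < total_s]
    show <- with_substream(config$seed, "transients",
                           expr = runif(length(cand)) < config$transient_wave_prob)
    for (t0 in cand[show]) {
      idx <- (round(t0 * fs) + 1):min(round((t0 + 2) * fs), n_total)
      transients[idx] <- transients[idx] +
        transient_wavelet(tt[idx] - t0, config$transient_wave_amplitude_uV)
    }
  }

  samples <- matrix(0, n_total, length(EEG_CHANNELS),
                    dimnames = list(NULL, EEG_CHANNELS))
  for (ch in EEG_CHANNELS) {
    x <- numeric(n_total)
    for (i in seq_len(nrow(spans))) {
      ph <- spans$phase[i]
      idx <- (round(spans$start_s[i] * fs) + 1):round(spans$end_s[i] * fs)
      x[idx] <- with_substream(
        config$seed, "eeg", ch, ph,
        expr = shaped_noise(length(idx), fs,
                            function(f) band_density(f, config$baseline_spectrum,
                                                     config$background_slowing[[ph]]),
                            rms = config$baseline_amplitude_uV))
    }
    # white instrumentation floor; at 0.1 uV RMS its out-of-band share of
    # total power is ~1e-4, so the recording stays band-limited in practice
    floor_noise <- with_substream(
      config$seed, "floor", ch,
      expr = rnorm(n_total, 0, config$noise_floor_uV))
    samples[, ch] <- x * gain + floor_noise + transients
  }
  structure(list(samples = samples, channel_labels = EEG_CHANNELS,
                 sample_rate_hz = fs, start_time_s = 0),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", ncol(x$samples), " channels x ",
      nrow(x$samples), " samples @ ", x$sample_rate_hz, " Hz (",
      nrow(x$samples) / x$sample_rate_hz, " s)\n", sep = "")
  invisible(x)
}
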