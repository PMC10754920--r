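# Shared fixtures, built in code. The short protocol keeps simulation
# tests fast while preserving the structure of the full protocol
# (stability, three phases, blocks of occlusion cycles plus one pause).

short_protocol <- function(...) {
  protocol_config(phase_duration_s = 720, occlusion_duration_s = 10,
                  inter_occlusion_period_s = c(A = 60, B = 45, C = 30),
                  pause_period_s = 240, pause_duration_s = 60,
                  stability_duration_s = 240, ...)
}

quiet_subject <- function(seed = 1L, ...) {
  subject_sim_config(seed = seed, hr_noise_bpm = 0, mbp_noise_mmHg = 0,
                     gas_noise = list(ph = 0, pco2 = 0, po2 = 0, lactate = 0),
                     transient_wave_prob = 0, ...)
}

make_recording <- function(channels, fs = 256) {
  samples <- do.call(cbind, channels)
  colnames(samples) <- names(channels)
  structure(list(samples = samples, channel_labels = names(channels),
                 sample_rate_hz = fs, start_time_s = 0),
            class = "eeg_recording")
}

sine_uV <- function(freq_hz, peak_uV, duration_s, fs = 256) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  peak_uV * sin(2 * pi * freq_hz * t)
}

# Random step-wise envelope with runs on both sides of the threshold.
random_envelope <- function(n, fs, threshold = 10) {
  lens <- pmax(1, stats::rgeom(n, 1 / (0.4 * fs)) + 1)
  vals <- stats::runif(n, 0, 2 * threshold)
  rep(vals, lens)
}

# A long data frame of per-subject phase summaries built directly (no
# simulation), for table/stat construction oracles.
synthetic_summaries <- function(values_by_feature,
                                phases = c("S", "A", "B", "C")) {
  rows <- list()
  for (feature in names(values_by_feature)) {
    grid <- values_by_feature[[feature]]  # subjects x phases
    for (s in seq_len(nrow(grid))) {
      for (p in seq_along(phases)) {
        rows[[length(rows) + 1]] <- data.frame(
          subject = s, feature = feature, phase = phases[p],
          value = grid[s, p])
      }
    }
  }
  do.call(rbind, rows)
}
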