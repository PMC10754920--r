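test_that("identical seed and config give bit-identical signals", {
  sch <- build_protocol(short_protocol())
  cfg <- subject_sim_config(seed = 11L)
  e1 <- simulate_eeg(sch, cfg)
  e2 <- simulate_eeg(sch, cfg)
  expect_identical(e1$samples, e2$samples)
  p1 <- simulate_physio(sch, cfg)
  p2 <- simulate_physio(sch, cfg)
  expect_identical(p1, p2)
  # a different seed actually changes the draw
  e3 <- simulate_eeg(sch, subject_sim_config(seed = 12L))
  expect_false(identical(e1$samples, e3$samples))
})

test_that("noise-free haemodynamics are piecewise-constant at configured levels", {
  sch <- build_protocol(short_protocol())
  cfg <- quiet_subject(seed = 3L)
  phys <- simulate_physio(sch, cfg)
  ev <- sch$events
  occ <- ev[ev$label == "occlusion", ]
  for (i in seq_len(nrow(occ))) {
    sel <- phys$hr$time_s >= occ$start_s[i] & phys$hr$time_s < occ$end_s[i]
    expect_true(all(phys$hr$bpm[sel] == cfg$hr_occlusion_bpm[[occ$phase[i]]]))
    expect_true(all(phys$mbp$mmHg[sel] == cfg$mbp_occlusion_mmHg[[occ$phase[i]]]))
  }
  stab <- phys$hr$time_s < 240
  expect_true(all(phys$hr$bpm[stab] == cfg$hr_baseline_bpm))
  expect_true(all(phys$mbp$mmHg[stab] == cfg$mbp_baseline_mmHg))
  pauses <- ev[ev$label == "pause", ]
  for (i in seq_len(nrow(pauses))) {
    sel <- phys$mbp$time_s >= pauses$start_s[i] &
      phys$mbp$time_s < pauses$end_s[i]
    expect_true(all(phys$mbp$mmHg[sel] ==
                      cfg$mbp_baseline_mmHg +
                      cfg$mbp_pause_delta_mmHg[[pauses$phase[i]]]))
  }
})

test_that("noise-free gasometry reproduces the configured phase targets", {
  sch <- build_protocol(short_protocol())
  cfg <- quiet_subject(seed = 5L)
  phys <- simulate_physio(sch, cfg)
  gas <- phys$gasometry
  expect_equal(gas$phase, c("S", "A", "B", "C"))
  expect_equal(gas$ph, cfg$gas_trajectory$ph, tolerance = 1e-6)
  expect_equal(gas$pco2_mmHg, cfg$gas_trajectory$pco2, tolerance = 1e-6)
  expect_equal(gas$lactate_mmol_l, cfg$gas_trajectory$lactate,
               tolerance = 1e-6)
})

test_that("full suppression leaves only the noise floor inside occlusions", {
  sch <- build_protocol(short_protocol())
  cfg <- quiet_subject(seed = 9L,
                       suppression_depth = c(A = 0, B = 0, C = 0),
                       suppression_latency_s = 0)
  rec <- simulate_eeg(sch, cfg)
  fs <- rec$sample_rate_hz
  occ <- sch$events[sch$events$label == "occlusion" &
                      sch$events$phase == "C", ]
  for (i in seq_len(nrow(occ))) {
    # skip the 1-s entry/exit ramps
    idx <- (round((occ$start_s[i] + 1.5) * fs)):(round((occ$end_s[i] - 0.5) * fs))
    rms <- sqrt(mean(rec$samples[idx, 1]^2))
    expect_lt(rms, 3 * cfg$noise_floor_uV)
  }
})

test_that("simulated EEG is band-limited to the acquisition band", {
  sch <- build_protocol(short_protocol())
  rec <- simulate_eeg(sch, subject_sim_config(seed = 21L))
  for (ch in 1:4) {
    x <- rec$samples[, ch]
    sp <- Mod(stats::fft(x))^2
    f <- (seq_along(sp) - 1) * rec$sample_rate_hz / length(sp)
    f <- pmin(f, rec$sample_rate_hz - f)
    expect_lt(sum(sp[f > 70]) / sum(sp), 0.01)
  }
})

test_that("a pH trajectory crossing the threshold stops the protocol", {
  traj <- data.frame(phase = c("S", "A", "B", "C"),
                     ph = c(7.39, 7.25, 7.00, 6.70),
                     pco2 = c(45.3, 50.6, 54.0, 64.9),
                     po2 = c(12, 16, 15, 16.5),
                     lactate = c(2.27, 6.0, 12.8, 15.9))
  sub <- simulate_subject(quiet_subject(seed = 2L, gas_trajectory = traj),
                          short_protocol())
  expect_false(is.na(sub$schedule$truncated_at_s))
  # truncation happens inside phase C, where the latent pH crosses 6.90
  expect_gt(sub$schedule$truncated_at_s, 240 + 2 * 720)
  expect_true(all(sub$physio$hr$time_s < sub$schedule$truncated_at_s))
  expect_equal(nrow(sub$eeg$samples),
               sub$schedule$truncated_at_s * sub$eeg$sample_rate_hz)
  # untruncated defaults (phase-C pause pH 6.98) never trigger the rule
  sub0 <- simulate_subject(quiet_subject(seed = 2L), short_protocol())
  expect_true(is.na(sub0$schedule$truncated_at_s))
})

test_that("cohorts are reproducible and jitter behaves as configured", {
  base <- subject_sim_config()
  c1 <- simulate_cohort(9, base, seed = 42L)
  c2 <- simulate_cohort(9, base, seed = 42L)
  expect_identical(c1, c2)
  expect_error(simulate_cohort(0, base), "n must be")

  zero_jitter <- list(amplitude = 0, hr = 0, mbp = 0, gas = 0, ph = 0,
                      suppression = 0)
  cz <- simulate_cohort(2, base, seed = 7L, jitter = zero_jitter)
  cfg1 <- cz[[1]]$config
  cfg2 <- cz[[2]]$config
  expect_false(cfg1$seed == cfg2$seed)  # independent signal streams remain
  cfg1$seed <- cfg2$seed <- 0L
  expect_equal(cfg1, cfg2, tolerance = 1e-12)

  cj <- simulate_cohort(2, base, seed = 7L)
  expect_false(cj[[1]]$config$baseline_amplitude_uV ==
                 cj[[2]]$config$baseline_amplitude_uV)
})

test_that("deeper occlusion suppression never lowers per-occlusion BSR", {
  sch <- build_protocol(short_protocol())
  occ_c <- sch$events[sch$events$label == "occlusion" &
                        sch$events$phase == "C", ]
  med_bsr <- function(retained) {
    cfg <- quiet_subject(seed = 30L, suppression_latency_s = 0,
                         suppression_depth = c(A = 0.8, B = 0.5, C = retained))
    rec <- simulate_eeg(sch, cfg)
    feats <- compute_features(rec)
    avg <- feats[feats$derivation == "average", ]
    sel <- vapply(avg$interval_start_s, function(t0)
      any(t0 >= occ_c$start_s & t0 + 2 <= occ_c$end_s), TRUE)
    median(avg$bsr_percent[sel])
  }
  vals <- vapply(c(0.9, 0.5, 0.1), med_bsr, 0)
  expect_true(all(diff(vals) >= 0))
})
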