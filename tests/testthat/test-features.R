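test_that("bipolar derivation is the sample-wise channel difference", {
  set.seed(1)
  n <- 512
  rec <- make_recording(list(F_left = rnorm(n), F_right = rnorm(n),
                             P_left = rnorm(n), P_right = rnorm(n)))
  bip <- derive_bipolar(rec)
  expect_equal(bip$samples[, "frontal"],
               rec$samples[, "F_left"] - rec$samples[, "F_right"])
  expect_equal(bip$samples[, "parietal"],
               rec$samples[, "P_left"] - rec$samples[, "P_right"])

  self <- derive_bipolar(rec, montage_spec(list(z = c("F_left", "F_left"))))
  expect_true(all(self$samples == 0))
  ident <- derive_bipolar(
    make_recording(list(a = sine_uV(5, 10, 2), b = numeric(n))),
    montage_spec(list(d = c("a", "b"))))
  expect_equal(ident$samples[, "d"], sine_uV(5, 10, 2))
  expect_error(derive_bipolar(rec, montage_spec(list(d = c("F_left", "Oz")))),
               "montage")
})

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  fs <- 256
  in_tone <- sine_uV(10, 1, 10, fs)
  out_tone <- sine_uV(40, 1, 10, fs)
  mid <- (2 * fs):(8 * fs)  # away from filter edges
  y_in <- eeg_bandpass(in_tone, 2, 20, fs)
  y_out <- eeg_bandpass(out_tone, 2, 20, fs)
  expect_gt(max(abs(y_in[mid])), 0.95)
  expect_lt(max(abs(y_in[mid])), 1.05)
  expect_lt(max(abs(y_out[mid])), 0.10)
  expect_equal(eeg_bandpass(numeric(1000), 2, 20, fs), numeric(1000))
  expect_error(eeg_bandpass(in_tone, 20, 2, fs), "invalid band")
  expect_error(eeg_bandpass(in_tone, 2, 200, fs), "invalid band")
})

test_that("envelope recovers constant and modulated amplitude profiles", {
  fs <- 256
  expect_equal(amplitude_envelope(numeric(10 * fs), fs), numeric(10 * fs))

  x <- sine_uV(10, 30, 20, fs)
  env <- amplitude_envelope(x, fs)
  mid <- (2 * fs):(18 * fs)
  expect_true(all(abs(env[mid] - 30) / 30 < 0.05))

  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  profile <- 20 + 10 * sin(2 * pi * 0.2 * t)
  xm <- profile * sin(2 * pi * 10 * t)
  envm <- amplitude_envelope(xm, fs)
  expect_true(all(abs(envm[mid] - profile[mid]) / profile[mid] < 0.10))
})

test_that("minAI equals the exhaustive scan minimum", {
  fs <- 64
  expect_equal(min_ai(rep(12, 10 * fs), fs, c(2, 8)), 12)
  env <- rep(20, 10 * fs)
  env[5 * fs + 3] <- 5
  expect_equal(min_ai(env, fs, c(2, 8)), 5)
  set.seed(4)
  for (i in 1:20) {
    env <- runif(10 * fs, 0, 30)
    iv <- sort(runif(2, 0, 10))
    if (diff(iv) < 2 / fs) next
    expect_equal(min_ai(env, fs, iv), oracle_min(env, fs, iv))
  }
  expect_error(min_ai(env, fs, c(20, 21)), "empty interval")
})

test_that("suppression detection applies the strict amplitude and duration rules", {
  fs <- 100
  # 0.4-s dip: too short under the strict > 500 ms rule
  env <- rep(20, 10 * fs)
  env[(2 * fs):(2 * fs + 0.4 * fs - 1)] <- 3
  expect_equal(nrow(detect_suppressions(env, fs)), 0)
  # exactly 0.5 s is still too short (strict inequality)
  env2 <- rep(20, 10 * fs)
  env2[(2 * fs + 1):(2 * fs + 0.5 * fs)] <- 3
  expect_equal(nrow(detect_suppressions(env2, fs)), 0)

  seg <- detect_suppressions(numeric(60 * fs), fs)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$end_s - seg$start_s, 60)

  env3 <- rep(20, 20 * fs)
  plant <- function(at_s, len_s) env3[(at_s * fs + 1):((at_s + len_s) * fs)] <<- 1
  plant(2, 0.3); plant(5, 0.6); plant(9, 1.2)
  got <- detect_suppressions(env3, fs)
  expect_equal(got$start_s, c(5, 9))
  expect_equal(got$end_s - got$start_s, c(0.6, 1.2))
})

test_that("suppression detection matches the sample-wise run scanner", {
  fs <- 50
  set.seed(11)
  for (i in 1:50) {
    env <- random_envelope(40, fs)
    expect_identical(detect_suppressions(env, fs),
                     oracle_suppressions(env, fs))
  }
})

test_that("BSR is the percentage overlap of suppression with the interval", {
  none <- data.frame(start_s = numeric(0), end_s = numeric(0))
  expect_equal(bsr(none, c(0, 2)), 0)
  expect_equal(bsr(data.frame(start_s = -5, end_s = 10), c(0, 2)), 100)
  expect_equal(bsr(data.frame(start_s = 0.5, end_s = 1.5), c(0, 2)), 50.0)
  # straddling segments contribute only their overlap
  expect_equal(bsr(data.frame(start_s = c(-1, 1.8), end_s = c(0.2, 3)),
                   c(0, 2)), 20.0)
  expect_error(bsr(none, c(1, 1)), "interval length")
})

test_that("BSR is monotone non-decreasing in the suppression threshold", {
  fs <- 50
  set.seed(12)
  env <- random_envelope(60, fs)
  iv <- c(5, 15)
  vals <- vapply(c(2, 5, 10, 15, 25), function(thr)
    bsr(detect_suppressions(env, fs, threshold_uV = thr), iv), 0)
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= 0 & vals <= 100))
})

test_that("SEF finds the spectral edge of line spectra", {
  fs <- 256
  expect_equal(sef(sine_uV(8, 20, 2, fs), fs), 8.0, tolerance = 0.51)
  two <- sine_uV(4, 20, 2, fs) + sine_uV(16, 20, 2, fs)
  expect_equal(sef(two, fs), 16.0)
  expect_true(is.na(sef(numeric(2 * fs), fs)))
  expect_error(sef(sine_uV(8, 20, 1, fs), fs), "shorter than 2 s")
})

test_that("SEF is amplitude-invariant and monotone in the quantile", {
  fs <- 256
  set.seed(5)
  x <- eeg_bandpass(rnorm(2 * fs, sd = 20), 2, 30, fs)
  expect_equal(sef(x, fs), sef(5 * x, fs))
  qs <- c(0.5, 0.75, 0.9, 0.95, 0.99)
  vals <- vapply(qs, function(q) sef(x, fs, quantile = q), 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("scaling the signal scales minAI and leaves SEF unchanged", {
  fs <- 256
  sch <- build_protocol(short_protocol())
  rec <- simulate_eeg(sch, subject_sim_config(seed = 14L))
  rec$samples <- rec$samples[1:(60 * fs), ]
  k <- 3.7
  rec_k <- rec
  rec_k$samples <- rec_k$samples * k
  f1 <- compute_features(rec)
  fk <- compute_features(rec_k)
  expect_equal(fk$minai_uV, k * f1$minai_uV, tolerance = 1e-8)
  expect_equal(fk$sef_hz, f1$sef_hz)
})

test_that("feature series: averaging, suppressed blocks, stability background", {
  fs <- 256
  # identical derivations -> average equals the single-channel values
  s <- sine_uV(10, 30, 30, fs)
  rec <- make_recording(list(F_left = s, F_right = numeric(length(s)),
                             P_left = s, P_right = numeric(length(s))))
  feats <- compute_features(rec)
  avg <- feats[feats$derivation == "average", ]
  fro <- feats[feats$derivation == "frontal", ]
  expect_equal(avg$minai_uV, fro$minai_uV)
  expect_equal(avg$bsr_percent, fro$bsr_percent)
  expect_equal(avg$sef_hz, fro$sef_hz)

  # a 60-s suppressed block inside a 180-s recording: interior intervals
  # read BSR 100, intervals clear of the block read 0, and every interval
  # matches the continuous-timeline overlap oracle
  x <- sine_uV(10, 30, 180, fs)
  x[(60 * fs + 1):(120 * fs)] <- 0
  rec2 <- make_recording(list(F_left = x, F_right = numeric(length(x)),
                              P_left = x, P_right = numeric(length(x))))
  f2 <- compute_features(rec2)
  a2 <- f2[f2$derivation == "frontal", ]
  interior <- a2$interval_start_s >= 62 & a2$interval_start_s + 2 <= 118
  expect_true(all(a2$bsr_percent[interior] == 100))
  expect_gte(sum(interior), 28)
  clear <- a2$interval_start_s + 2 <= 59 | a2$interval_start_s >= 121
  expect_true(all(a2$bsr_percent[clear] == 0))
  env <- amplitude_envelope(eeg_bandpass(x, 2, 20, fs), fs)
  segs <- detect_suppressions(env, fs)
  oracle_bsr <- vapply(a2$interval_start_s, function(t0)
    bsr(segs, c(t0, t0 + 2)), 0)
  expect_equal(a2$bsr_percent, oracle_bsr, tolerance = 1e-8)
  # fully suppressed intervals have undefined SEF, never a numeric artefact
  expect_true(all(is.na(a2$sef_hz[interior])))

  # stability-like background: no suppression, SEF defined on every interval
  sch <- build_protocol(short_protocol())
  bg <- simulate_eeg(sch, subject_sim_config(seed = 15L))
  bg$samples <- bg$samples[1:(240 * fs), ]  # stability period only
  f3 <- compute_features(bg)
  a3 <- f3[f3$derivation == "average", ]
  expect_equal(median(a3$bsr_percent), 0)
  expect_true(all(!is.na(a3$sef_hz)))
  expect_error(compute_features(make_recording(list(
    F_left = numeric(100), F_right = numeric(100),
    P_left = numeric(100), P_right = numeric(100)))), "shorter")
})

test_that("planted suppression fractions are recovered within tolerance", {
  # suppress known fractions of two 20-s windows; the envelope smears each
  # boundary by a fixed few hundred ms, so the recovered share must sit
  # within 5 percentage points of the planted one
  fs <- 256
  x <- sine_uV(10, 30, 80, fs)
  x[(25 * fs + 1):(31 * fs)] <- 0   # 6 s of [20, 40): 30%
  x[(43 * fs + 1):(57 * fs)] <- 0   # 14 s of [40, 60): 70%
  env <- amplitude_envelope(eeg_bandpass(x, 2, 20, fs), fs)
  segs <- detect_suppressions(env, fs)
  expect_lt(abs(bsr(segs, c(20, 40)) - 30), 5)
  expect_lt(abs(bsr(segs, c(40, 60)) - 70), 5)
  expect_lt(bsr(segs, c(0, 20)), 5)
})
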