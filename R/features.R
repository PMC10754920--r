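# qEEG features: minimum amplitude index (minAI), burst suppression ratio
# (BSR) and 95% spectral edge frequency (SEF), computed on 2-s intervals of
# bipolar fronto-parietal derivations and averaged across the two channels.

#' Bipolar montage specification
#'
#' @param derivations Named list of 2-element character vectors; each
#'   derivation is `first - second` of the named monopolar channels.
#'   Defaults to left-right frontal and left-right parietal.
#' @return Object of class `montage_spec`.
#' @export
montage_spec <- function(derivations = list(frontal = c("F_left", "F_right"),
                                            parietal = c("P_left", "P_right"))) {
  stopifnot(length(derivations) >= 1,
            all(vapply(derivations, length, 1L) == 2))
  structure(list(derivations = derivations), class = "montage_spec")
}

#' Re-reference a recording to a bipolar montage
#'
#' @param rec An `eeg_recording` with monopolar channels.
#' @param montage A [montage_spec()].
#' @return An `eeg_recording` whose channels are the sample-wise
#'   differences `first - second` of each derivation pair.
#' @export
derive_bipolar <- function(rec, montage = montage_spec()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(montage, "montage_spec"))
  labels <- colnames(rec$samples)
  needed <- unique(unlist(montage$derivations))
  missing <- setdiff(needed, labels)
  if (length(missing) > 0)
    stop("montage channel(s) not in recording: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- vapply(montage$derivations,
                function(p) rec$samples[, p[1]] - rec$samples[, p[2]],
                numeric(nrow(rec$samples)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)  # 1-sample recording
  colnames(out) <- names(montage$derivations)
  rec$samples <- out
  rec$channel_labels <- names(montage$derivations)
  rec
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' ([signal::filtfilt()]), giving zero phase distortion and a stop-band
#' attenuation well beyond 40 dB one octave outside the band.
#'
#' @param x Numeric signal.
#' @param low_hz,high_hz Band edges, Hz; must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @param fs Sampling rate, Hz.
#' @return Filtered signal, same length as `x`.
#' @export
eeg_bandpass <- function(x, low_hz, high_hz, fs) {
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < fs / 2))
    stop("invalid band: need 0 < low_hz < high_hz < fs/2", call. = FALSE)
  bf <- signal::butter(4, c(low_hz, high_hz) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

# Max over a centred k-sample window, O(n log k) by doubling.
running_max <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  l1 <- floor((k - 1) / 2)
  l2 <- k - 1 - l1
  y <- c(rep(-Inf, l1), x, rep(-Inf, l2))
  covered <- 1
  while (covered < k) {
    s <- min(covered, k - covered)
    y <- pmax(y, c(rep(-Inf, s), y[seq_len(length(y) - s)]))
    covered <- covered + s
  }
  y[k:(k + n - 1)]
}

# Mean over a centred k-sample window (shrinking at the edges), O(n).
running_mean <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  l1 <- floor((k - 1) / 2)
  l2 <- k - 1 - l1
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - l1, 1)
  hi <- pmin(seq_len(n) + l2, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Amplitude envelope of a band-passed EEG signal (CFM/aEEG style)
#'
#' Rectifies the signal, takes the maximum over a sliding 125-ms window and
#' smooths with a 0.5-s moving average. For a constant-amplitude sine the
#' envelope converges to the peak amplitude away from the edges.
#'
#' @param x Signal already band-passed to 2-20 Hz (uV).
#' @param fs Sampling rate, Hz.
#' @param peak_window_s Sliding-maximum window, seconds.
#' @param smooth_window_s Moving-average window, seconds.
#' @return Non-negative envelope on the same sampling grid, uV.
#' @export
amplitude_envelope <- function(x, fs, peak_window_s = 0.125,
                               smooth_window_s = 0.5) {
  running_mean(running_max(abs(x), max(1, round(peak_window_s * fs))),
               max(1, round(smooth_window_s * fs)))
}

#' Minimum amplitude index over an interval
#'
#' The minimum of the amplitude envelope inside `[interval[1], interval[2])`
#' on the recording timeline.
#'
#' @param envelope Envelope as returned by [amplitude_envelope()].
#' @param fs Sampling rate, Hz.
#' @param interval Numeric length 2: start and end, seconds.
#' @param start_time_s Time of the first envelope sample.
#' @return Minimum envelope value, uV.
#' @export
min_ai <- function(envelope, fs, interval, start_time_s = 0) {
  t <- start_time_s + (seq_along(envelope) - 1) / fs
  idx <- t >= interval[1] & t < interval[2]
  if (!any(idx)) stop("empty interval", call. = FALSE)
  min(envelope[idx])
}

#' Detect suppression segments on the continuous envelope
#'
#' Maximal runs where the envelope stays strictly below `threshold_uV` for
#' strictly longer than `min_duration_s`, found on the whole timeline (so a
#' suppression spanning an analysis-interval edge is not lost).
#'
#' @param envelope Non-negative amplitude envelope, uV.
#' @param fs Sampling rate, Hz.
#' @param threshold_uV Suppression amplitude criterion (strict `<`).
#' @param min_duration_s Minimum run duration (strict `>`), seconds.
#' @param start_time_s Time of the first envelope sample.
#' @return Data frame with columns `start_s`, `end_s` (sorted, disjoint).
#' @export
detect_suppressions <- function(envelope, fs, threshold_uV = 10,
                                min_duration_s = 0.5, start_time_s = 0) {
  below <- envelope < threshold_uV
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths / fs > min_duration_s)
  data.frame(start_s = start_time_s + (starts[keep] - 1) / fs,
             end_s = start_time_s + ends[keep] / fs)
}

#' Burst suppression ratio of an interval
#'
#' Percentage of `[interval[1], interval[2])` covered by suppression
#' segments; a segment straddling the boundary contributes only its overlap.
#'
#' @param segments Data frame `start_s`, `end_s` from [detect_suppressions()].
#' @param interval Numeric length 2: start and end, seconds.
#' @return BSR in percent, in `[0, 100]`.
#' @export
bsr <- function(segments, interval) {
  len <- interval[2] - interval[1]
  if (!(len > 0)) stop("interval length must be > 0", call. = FALSE)
  if (is.null(segments) || nrow(segments) == 0) return(0)
  overlap <- pmax(0, pmin(segments$end_s, interval[2]) -
                    pmax(segments$start_s, interval[1]))
  min(100, 100 * sum(overlap) / len)
}

#' Spectral edge frequency of an interval
#'
#' The smallest frequency in `band` below which at least `quantile` of the
#' interval's in-band spectral power lies, from a periodogram of the raw
#' interval (0.5-Hz resolution for 2 s at 256 Hz). When total in-band power
#' falls below the power floor (an isoelectric/suppressed interval) the SEF
#' is undefined and `NA` is returned -- never an arbitrary numeric value.
#'
#' @param x Signal samples of the interval (>= 2 s).
#' @param fs Sampling rate, Hz.
#' @param quantile Power quantile (default 0.95).
#' @param band Analysis band, Hz.
#' @param taper `"rect"` (default) or `"hann"` periodogram taper.
#' @param floor_rms_uV Defines the undefined-SEF floor: total in-band power
#'   of white noise with this RMS.
#' @return SEF in Hz, or `NA_real_` when undefined.
#' @export
sef <- function(x, fs, quantile = 0.95, band = c(0.5, 70),
                taper = c("rect", "hann"), floor_rms_uV = 1) {
  if (length(x) < 2 * fs)
    stop("interval shorter than 2 s", call. = FALSE)
  taper <- match.arg(taper)
  w <- if (taper == "hann") hann_window(length(x)) else rep(1, length(x))
  n <- length(x)
  X <- stats::fft(w * x)
  nb <- floor(n / 2) + 1
  power <- Mod(X[seq_len(nb)])^2
  freq <- (seq_len(nb) - 1) * fs / n
  in_band <- freq >= band[1] & freq <= band[2]
  p <- power[in_band]
  f <- freq[in_band]
  total <- sum(p)
  floor_power <- sum(in_band) * sum(w^2) * floor_rms_uV^2
  if (total < floor_power) return(NA_real_)
  f[which(cumsum(p) >= quantile * total)[1]]
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' Compute the qEEG feature series of a recording
#'
#' Applies the bipolar montage, then on non-overlapping intervals aligned
#' to the recording start computes, per derivation: minAI (minimum of the
#' 2-20 Hz amplitude envelope), BSR (envelope suppressions `< 10` uV for
#' `> 500` ms, detected on the continuous timeline and intersected with the
#' intervals) and SEF (95% spectral edge of the 0.5-70 Hz signal). The
#' channel-averaged series is the arithmetic mean of the two derivations;
#' for SEF the mean is over defined values, undefined only if both are.
#'
#' @param rec An `eeg_recording` (monopolar).
#' @param montage A [montage_spec()].
#' @param interval_s Analysis interval length, seconds.
#' @param envelope_band,sef_band Filter bands, Hz.
#' @param suppression_threshold_uV,suppression_min_duration_s Suppression
#'   criteria.
#' @param sef_quantile Spectral edge quantile.
#' @param sef_taper,sef_floor_rms_uV Passed to [sef()].
#' @return Object of class `qeeg_series`: data frame with columns
#'   `interval_start_s`, `derivation` (each montage derivation plus
#'   `"average"`), `minai_uV`, `bsr_percent`, `sef_hz` (`NA` = undefined).
#' @export
compute_features <- function(rec, montage = montage_spec(), interval_s = 2,
                             envelope_band = c(2, 20), sef_band = c(0.5, 70),
                             suppression_threshold_uV = 10,
                             suppression_min_duration_s = 0.5,
                             sef_quantile = 0.95, sef_taper = "rect",
                             sef_floor_rms_uV = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate_hz
  nper <- round(interval_s * fs)
  n <- nrow(rec$samples)
  if (n < nper)
    stop("recording shorter than one analysis interval", call. = FALSE)
  bip <- derive_bipolar(rec, montage)
  m <- floor(n / nper)
  starts_s <- rec$start_time_s + (seq_len(m) - 1) * interval_s
  used <- m * nper

  per_deriv <- lapply(colnames(bip$samples), function(dv) {
    x <- bip$samples[, dv]
    env <- amplitude_envelope(eeg_bandpass(x, envelope_band[1],
                                           envelope_band[2], fs), fs)
    # suppression mask on the continuous timeline, then per-interval share
    below <- env < suppression_threshold_uV
    r <- rle(below)
    keep <- r$values & (r$lengths / fs > suppression_min_duration_s)
    mask <- rep(r$values & keep, r$lengths)
    env_m <- matrix(env[seq_len(used)], nrow = nper)
    mask_m <- matrix(mask[seq_len(used)], nrow = nper)
    sig_m <- matrix(x[seq_len(used)], nrow = nper)

    minai <- apply(env_m, 2, min)
    bsr_v <- 100 * colMeans(mask_m)
    w <- if (sef_taper == "hann") hann_window(nper) else rep(1, nper)
    X <- stats::mvfft(sig_m * w)
    nb <- floor(nper / 2) + 1
    power <- Mod(X[seq_len(nb), , drop = FALSE])^2
    freq <- (seq_len(nb) - 1) * fs / nper
    in_band <- freq >= sef_band[1] & freq <= sef_band[2]
    p <- power[in_band, , drop = FALSE]
    f <- freq[in_band]
    tot <- colSums(p)
    cum <- apply(p, 2, cumsum)
    idx <- colSums(cum < rep(sef_quantile * tot, each = nrow(cum))) + 1
    sef_v <- f[pmin(idx, length(f))]
    floor_power <- sum(in_band) * sum(w^2) * sef_floor_rms_uV^2
    sef_v[tot < floor_power] <- NA_real_
    data.frame(interval_start_s = starts_s, derivation = dv,
               minai_uV = minai, bsr_percent = bsr_v, sef_hz = sef_v)
  })

  tab <- do.call(rbind, per_deriv)
  minai_avg <- rowMeans(sapply(per_deriv, `[[`, "minai_uV"))
  bsr_avg <- rowMeans(sapply(per_deriv, `[[`, "bsr_percent"))
  sef_mat <- sapply(per_deriv, `[[`, "sef_hz")
  sef_avg <- rowMeans(sef_mat, na.rm = TRUE)
  sef_avg[is.nan(sef_avg)] <- NA_real_
  tab <- rbind(tab, data.frame(interval_start_s = starts_s,
                               derivation = "average", minai_uV = minai_avg,
                               bsr_percent = bsr_avg, sef_hz = sef_avg))
  rownames(tab) <- NULL
  structure(tab, class = c("qeeg_series", "data.frame"),
            interval_s = interval_s, sample_rate_hz = fs)
}
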