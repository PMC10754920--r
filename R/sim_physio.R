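#' Simulate haemodynamic and gasometric signals under an occlusion schedule
#'
#' Heart rate and mean blood pressure are generated at 1 Hz: HR sits at the
#' baseline outside occlusions and drops to the phase's per-occlusion level
#' during each occlusion (the bradycardia appears from the very first
#' occlusion); MBP rises above baseline between occlusions by the phase's
#' pause delta and takes the phase's per-occlusion value during occlusions
#' (hypotension in the severe phase). Gasometry follows a dense latent
#' trajectory interpolating the per-phase targets, sampled (with
#' measurement noise) at the stability draw and at the midpoint of the last
#' pause of each phase -- the experiment's sampling scheme.
#'
#' @param schedule A `uco_schedule`.
#' @param config A [subject_sim_config()].
#' @return Object of class `physio_record`: list with `hr` (`time_s`,
#'   `bpm`), `mbp` (`time_s`, `mmHg`), `gasometry` (`time_s`, `ph`,
#'   `pco2_mmHg`, `po2_mmHg`, `lactate_mmol_l`, `phase`) and `latent_gas`
#'   (the noise-free 1-Hz trajectory used by the stop rule).
#' @export
simulate_physio <- function(schedule, config) {
  stopifnot(inherits(schedule, "uco_schedule"),
            inherits(config, "subject_sim_config"))
  ev <- schedule$events
  if (nrow(ev) == 0) stop("empty schedule", call. = FALSE)
  total_s <- schedule_end_s(schedule)
  time_s <- seq(0, total_s - 1)

  hr <- rep(config$hr_baseline_bpm, length(time_s))
  mbp <- rep(config$mbp_baseline_mmHg, length(time_s))
  for (i in seq_len(nrow(ev))) {
    idx <- time_s >= ev$start_s[i] & time_s < ev$end_s[i]
    ph <- ev$phase[i]
    if (ev$label[i] == "occlusion") {
      hr[idx] <- config$hr_occlusion_bpm[[ph]]
      mbp[idx] <- config$mbp_occlusion_mmHg[[ph]]
    } else if (ev$label[i] %in% c("pause", "inter-occlusion")) {
      mbp[idx] <- config$mbp_baseline_mmHg + config$mbp_pause_delta_mmHg[[ph]]
    }
  }
  hr <- hr + with_substream(config$seed, "hr",
                            expr = rnorm(length(hr), 0, config$hr_noise_bpm))
  mbp <- mbp + with_substream(config$seed, "mbp",
                              expr = rnorm(length(mbp), 0, config$mbp_noise_mmHg))

  anchors <- gas_anchor_times(schedule)
  traj <- config$gas_trajectory
  traj <- traj[match(anchors$phase, traj$phase), ]
  latent <- data.frame(time_s = time_s)
  for (v in c("ph", "pco2", "po2", "lactate")) {
    latent[[v]] <- stats::approx(anchors$time_s, traj[[v]], xout = time_s,
                                 rule = 2)$y
  }
  noise <- with_substream(config$seed, "gas", expr = list(
    ph = rnorm(nrow(anchors), 0, config$gas_noise$ph),
    pco2 = rnorm(nrow(anchors), 0, config$gas_noise$pco2),
    po2 = rnorm(nrow(anchors), 0, config$gas_noise$po2),
    lactate = rnorm(nrow(anchors), 0, config$gas_noise$lactate)))
  at <- findInterval(anchors$time_s, time_s)
  gas <- data.frame(
    time_s = anchors$time_s,
    ph = latent$ph[at] + noise$ph,
    pco2_mmHg = pmax(latent$pco2[at] + noise$pco2, 0),
    po2_mmHg = pmax(latent$po2[at] + noise$po2, 0),
    lactate_mmol_l = pmax(latent$lactate[at] + noise$lactate, 0),
    phase = anchors$phase)

  structure(list(hr = data.frame(time_s = time_s, bpm = hr),
                 mbp = data.frame(time_s = time_s, mmHg = mbp),
                 gasometry = gas, latent_gas = latent),
            class = "physio_record")
}

# Gasometry sampling times: mid-stability, then the midpoint of the last
# pause of each phase present in the schedule.
gas_anchor_times <- function(schedule) {
  ev <- schedule$events
  out <- list()
  stab <- ev[ev$label == "stability", ]
  if (nrow(stab) > 0)
    out[[1]] <- data.frame(phase = "S",
                           time_s = floor((stab$start_s[1] + stab$end_s[1]) / 2))
  for (ph in c("A", "B", "C")) {
    pauses <- ev[ev$label == "pause" & ev$phase == ph, ]
    if (nrow(pauses) == 0) next
    last <- pauses[nrow(pauses), ]
    out[[length(out) + 1]] <- data.frame(
      phase = ph, time_s = floor((last$start_s + last$end_s) / 2))
  }
  do.call(rbind, out)
}

# Augment measured gasometry with the first latent crossing of the stop
# threshold, so the stop rule can act mid-phase the way continuous clinical
# surveillance would.
gas_with_latent_stop <- function(physio, threshold) {
  gas <- physio$gasometry[, c("time_s", "ph")]
  lat <- physio$latent_gas
  hit <- which(lat$ph < threshold)
  if (length(hit) > 0) {
    gas <- rbind(gas, data.frame(time_s = lat$time_s[hit[1]],
                                 ph = lat$ph[hit[1]]))
    gas <- gas[order(gas$time_s), ]
  }
  list(gasometry = gas)
}

# Truncate the physiological record at the schedule's truncation time.
truncate_physio <- function(physio, t_stop) {
  if (is.na(t_stop)) return(physio)
  physio$hr <- physio$hr[physio$hr$time_s < t_stop, ]
  physio$mbp <- physio$mbp[physio$mbp$time_s < t_stop, ]
  physio$gasometry <- physio$gasometry[physio$gasometry$time_s <= t_stop, ]
  physio$latent_gas <- physio$latent_gas[physio$latent_gas$time_s <= t_stop, ]
  physio
}

#' Simulate one subject end to end
#'
#' Builds the protocol, simulates physiology, applies the pH stop rule
#' (using the dense latent pH trajectory, so the protocol can stop
#' mid-phase), truncates the physiology accordingly, and simulates the EEG
#' over the (possibly truncated) schedule.
#'
#' @param config A [subject_sim_config()].
#' @param protocol A [protocol_config()].
#' @return List with `schedule` (truncated if the stop rule fired),
#'   `physio`, `eeg`.
#' @export
simulate_subject <- function(config = subject_sim_config(),
                             protocol = protocol_config()) {
  schedule <- build_protocol(protocol)
  physio <- simulate_physio(schedule, config)
  schedule <- apply_stop_rule(schedule,
                              gas_with_latent_stop(physio, protocol$ph_stop_threshold),
                              protocol$ph_stop_threshold)
  physio <- truncate_physio(physio, schedule$truncated_at_s)
  eeg <- simulate_eeg(schedule, config)
  list(schedule = schedule, physio = physio, eeg = eeg)
}
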