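#' Occlusion protocol configuration
#'
#' Parameters of the staged umbilical-cord-occlusion protocol: a 1-h
#' stability (pre-occlusion) period followed by three 1-h occlusion phases
#' A, B, C with 1-min total occlusions repeated every 5, 3 and 2 minutes
#' respectively, a 5-min occlusion-free "pause" every 20 min, and a stop
#' rule triggered when arterial pH falls below 6.90.
#'
#' Within each phase hour the pause layout is a documented convention: the
#' hour is split into `phase_duration_s / pause_period_s` blocks (three by
#' default), each consisting of occlusion cycles followed by one pause.
#' Occlusion onsets are placed every `inter_occlusion_period_s` from the
#' block start, while a full onset-to-onset cycle fits inside the
#' occlusion portion of the block.
#'
#' @param phase_duration_s Duration of each occlusion phase, seconds.
#' @param occlusion_duration_s Duration of one total occlusion, seconds.
#' @param inter_occlusion_period_s Named numeric vector (A, B, C): spacing
#'   of occlusion onsets within each phase, seconds.
#' @param pause_period_s One pause occurs every this many seconds.
#' @param pause_duration_s Duration of each pause, seconds.
#' @param stability_duration_s Duration of the pre-occlusion stability
#'   period, seconds.
#' @param ph_stop_threshold Arterial pH below which the protocol is stopped.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(phase_duration_s = 3600,
                            occlusion_duration_s = 60,
                            inter_occlusion_period_s = c(A = 300, B = 180, C = 120),
                            pause_period_s = 1200,
                            pause_duration_s = 300,
                            stability_duration_s = 3600,
                            ph_stop_threshold = 6.90) {
  if (is.null(names(inter_occlusion_period_s)))
    names(inter_occlusion_period_s) <- c("A", "B", "C")
  stopifnot(all(c("A", "B", "C") %in% names(inter_occlusion_period_s)))
  durs <- c(phase_duration_s, occlusion_duration_s, inter_occlusion_period_s,
            pause_period_s, pause_duration_s, stability_duration_s)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("all protocol durations must be positive", call. = FALSE)
  if (any(occlusion_duration_s >= inter_occlusion_period_s))
    stop("occlusion_duration_s must be shorter than every inter-occlusion period",
         call. = FALSE)
  if (pause_duration_s >= pause_period_s)
    stop("pause_duration_s must be shorter than pause_period_s", call. = FALSE)
  if (phase_duration_s %% pause_period_s != 0)
    stop("phase_duration_s must be a whole number of pause periods", call. = FALSE)
  structure(
    list(phase_duration_s = phase_duration_s,
         occlusion_duration_s = occlusion_duration_s,
         inter_occlusion_period_s = inter_occlusion_period_s[c("A", "B", "C")],
         pause_period_s = pause_period_s,
         pause_duration_s = pause_duration_s,
         stability_duration_s = stability_duration_s,
         ph_stop_threshold = ph_stop_threshold),
    class = "protocol_config")
}

#' Build the timed event schedule of the occlusion protocol
#'
#' Expands a [protocol_config()] into an ordered, contiguous event table:
#' one `stability` event, then for each phase A, B, C a sequence of
#' `occlusion` / `inter-occlusion` cycles interleaved with `pause` events.
#'
#' @param config A `protocol_config`.
#' @return An object of class `uco_schedule`: a list with `events`
#'   (data.frame with columns `label`, `phase`, `start_s`, `end_s`),
#'   `config`, and `truncated_at_s` (`NA` unless [apply_stop_rule()] has
#'   truncated the schedule).
#' @export
build_protocol <- function(config = protocol_config()) {
  stopifnot(inherits(config, "protocol_config"))
  ev <- list(data.frame(label = "stability", phase = "S", start_s = 0,
                        end_s = config$stability_duration_s))
  t_phase <- config$stability_duration_s
  n_blocks <- config$phase_duration_s / config$pause_period_s
  cycle_span <- config$pause_period_s - config$pause_duration_s
  for (phase in c("A", "B", "C")) {
    p <- config$inter_occlusion_period_s[[phase]]
    n_occ <- floor(cycle_span / p)          # full onset-to-onset cycles only
    onsets <- seq(0, by = p, length.out = n_occ)
    for (b in seq_len(n_blocks) - 1) {
      t0 <- t_phase + b * config$pause_period_s
      for (k in seq_along(onsets)) {
        occ_start <- t0 + onsets[k]
        occ_end <- occ_start + config$occlusion_duration_s
        next_start <- if (k < length(onsets)) t0 + onsets[k + 1] else t0 + cycle_span
        ev[[length(ev) + 1]] <- data.frame(
          label = c("occlusion", "inter-occlusion"), phase = phase,
          start_s = c(occ_start, occ_end), end_s = c(occ_end, next_start))
      }
      ev[[length(ev) + 1]] <- data.frame(
        label = "pause", phase = phase,
        start_s = t0 + cycle_span, end_s = t0 + config$pause_period_s)
    }
    t_phase <- t_phase + config$phase_duration_s
  }
  events <- do.call(rbind, ev)
  events <- events[events$end_s > events$start_s, ]
  rownames(events) <- NULL
  structure(list(events = events, config = config, truncated_at_s = NA_real_),
            class = "uco_schedule")
}

#' @export
print.uco_schedule <- function(x, ...) {
  ev <- x$events
  cat("<uco_schedule> ", nrow(ev), " events, span [",
      min(ev$start_s), ", ", max(ev$end_s), ") s",
      if (!is.na(x$truncated_at_s))
        paste0(", truncated at ", x$truncated_at_s, " s"),
      "\n", sep = "")
  counts <- table(ev$phase, ev$label)
  print(counts)
  invisible(x)
}

schedule_end_s <- function(schedule) max(schedule$events$end_s)

#' Truncate a schedule at the first gasometry sample breaching the pH stop rule
#'
#' The experimental protocol is stopped when arterial pH falls below the
#' configured threshold. The schedule is truncated at the time of the first
#' gasometry sample with `pH < threshold`: events starting at or after that
#' time are removed, the event containing it is cut short, and
#' `truncated_at_s` is set. Applying the rule twice is the same as once.
#'
#' @param schedule A `uco_schedule`.
#' @param physio A `physio_record` (see [simulate_physio()]) or any list
#'   with a `gasometry` data.frame holding `time_s` and `ph`.
#' @param threshold pH threshold; defaults to the schedule's configured
#'   `ph_stop_threshold`.
#' @return The (possibly truncated) `uco_schedule`.
#' @export
apply_stop_rule <- function(schedule, physio,
                            threshold = schedule$config$ph_stop_threshold) {
  stopifnot(inherits(schedule, "uco_schedule"))
  gas <- physio$gasometry
  stopifnot(!is.null(gas), !is.unsorted(gas$time_s))
  hit <- which(gas$ph < threshold)
  if (length(hit) == 0) return(schedule)
  t_stop <- gas$time_s[hit[1]]
  if (!is.na(schedule$truncated_at_s) && schedule$truncated_at_s <= t_stop)
    return(schedule)
  ev <- schedule$events
  ev <- ev[ev$start_s < t_stop, ]
  ev$end_s <- pmin(ev$end_s, t_stop)
  rownames(ev) <- NULL
  schedule$events <- ev
  schedule$truncated_at_s <- t_stop
  schedule
}
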