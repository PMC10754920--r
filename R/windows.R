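# Analysis-window logic: the experiment summarises every feature over the
# stability hour, over each whole occlusion phase, over the last completed
# occlusion of each phase (1 min) and over the last completed pause (5 min).

#' Select the analysis windows of a schedule
#'
#' Returns one `stability_hour` window plus, for each occlusion phase
#' present, a `whole_phase`, a `last_occlusion` (latest occlusion event
#' completed at its full duration) and a `last_pause` window. Under stop-rule
#' truncation "last" means last completed before the truncation time;
#' phases with no completed occlusion or pause contribute no such window.
#'
#' @param schedule A `uco_schedule`, possibly truncated.
#' @return Data frame with columns `kind`, `phase`, `start_s`, `end_s`.
#' @export
select_windows <- function(schedule) {
  stopifnot(inherits(schedule, "uco_schedule"))
  ev <- schedule$events
  if (nrow(ev) == 0) stop("empty schedule", call. = FALSE)
  cfg <- schedule$config
  out <- list()
  stab <- ev[ev$label == "stability", ]
  if (nrow(stab) > 0)
    out[[1]] <- data.frame(kind = "stability_hour", phase = "S",
                           start_s = stab$start_s[1], end_s = stab$end_s[1])
  for (ph in c("A", "B", "C")) {
    pev <- ev[ev$phase == ph, ]
    if (nrow(pev) == 0) next
    out[[length(out) + 1]] <- data.frame(kind = "whole_phase", phase = ph,
                                         start_s = min(pev$start_s),
                                         end_s = max(pev$end_s))
    occ <- pev[pev$label == "occlusion" &
                 (pev$end_s - pev$start_s) >= cfg$occlusion_duration_s, ]
    if (nrow(occ) > 0)
      out[[length(out) + 1]] <- data.frame(kind = "last_occlusion", phase = ph,
                                           start_s = occ$start_s[nrow(occ)],
                                           end_s = occ$end_s[nrow(occ)])
    pau <- pev[pev$label == "pause" &
                 (pev$end_s - pev$start_s) >= cfg$pause_duration_s, ]
    if (nrow(pau) > 0)
      out[[length(out) + 1]] <- data.frame(kind = "last_pause", phase = ph,
                                           start_s = pau$start_s[nrow(pau)],
                                           end_s = pau$end_s[nrow(pau)])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Median and quartiles of a timed series over a window
#'
#' Summarises all defined values whose timestamps fall in
#' `[window$start_s, window$end_s)`. Quartiles use linear interpolation
#' between order statistics (quantile type 7). Undefined values (`NA`, e.g.
#' SEF of suppressed intervals) are excluded; if no defined value remains
#' the summary is the missing marker (`NA` everywhere, `n = 0`).
#'
#' @param time_s,value Numeric vectors of equal length.
#' @param window List or one-row data frame with `start_s`, `end_s`.
#' @param quartile_type Passed to [stats::quantile()] `type`.
#' @return List with `median`, `q1`, `q3`, `n` (defined values used).
#' @export
summarize_feature <- function(time_s, value, window, quartile_type = 7) {
  stopifnot(length(time_s) == length(value))
  sel <- time_s >= window$start_s & time_s < window$end_s & !is.na(value)
  v <- value[sel]
  if (length(v) == 0)
    return(list(median = NA_real_, q1 = NA_real_, q3 = NA_real_, n = 0L))
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = quartile_type,
                       names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], n = length(v))
}

# Feature names of the per-subject per-phase summary grid.
QEEG_MARKERS <- c("wBSR", "wSEF", "wminAI", "ocBSR", "ocSEF", "ocminAI")
PHYSIO_MARKERS <- c("pHR", "pMBP", "ocHR", "ocMBP", "pH", "pCO2", "pO2",
                    "lactate")

#' Per-subject phase summaries of qEEG and physiological markers
#'
#' Applies the window logic to one subject's channel-averaged qEEG series
#' and physiology: `w*` features over the stability hour (phase S) and each
#' whole phase; `oc*` features and ocHR/ocMBP over the last completed
#' occlusion; pHR/pMBP over the stability hour (S) or last completed pause;
#' gasometry from the sample drawn at the stability draw or last pause.
#' Each cell is the per-subject median over the window (the gasometric
#' cells are single measurements).
#'
#' @param features A `qeeg_series` from [compute_features()].
#' @param physio A `physio_record`.
#' @param schedule The subject's (possibly truncated) `uco_schedule`.
#' @return Data frame with columns `feature`, `phase`, `value` (`NA` for
#'   windows lost to truncation).
#' @export
subject_phase_summary <- function(features, physio, schedule) {
  win <- select_windows(schedule)
  avg <- features[features$derivation == "average", ]
  get_win <- function(kind, phase) {
    w <- win[win$kind == kind & win$phase == phase, ]
    if (nrow(w) == 0) NULL else w[1, ]
  }
  med <- function(time_s, value, w) {
    if (is.null(w)) return(NA_real_)
    summarize_feature(time_s, value, w)$median
  }
  rows <- list()
  add <- function(feature, phase, value)
    rows[[length(rows) + 1]] <<- data.frame(feature = feature, phase = phase,
                                            value = value)
  qeeg_cols <- c(BSR = "bsr_percent", SEF = "sef_hz", minAI = "minai_uV")
  for (ph in c("S", "A", "B", "C")) {
    w_whole <- get_win(if (ph == "S") "stability_hour" else "whole_phase", ph)
    for (mk in names(qeeg_cols))
      add(paste0("w", mk), ph,
          med(avg$interval_start_s, avg[[qeeg_cols[mk]]], w_whole))
    w_occ <- if (ph == "S") NULL else get_win("last_occlusion", ph)
    for (mk in names(qeeg_cols))
      add(paste0("oc", mk), ph,
          med(avg$interval_start_s, avg[[qeeg_cols[mk]]], w_occ))
    w_pause <- if (ph == "S") w_whole else get_win("last_pause", ph)
    add("pHR", ph, med(physio$hr$time_s, physio$hr$bpm, w_pause))
    add("pMBP", ph, med(physio$mbp$time_s, physio$mbp$mmHg, w_pause))
    add("ocHR", ph, med(physio$hr$time_s, physio$hr$bpm, w_occ))
    add("ocMBP", ph, med(physio$mbp$time_s, physio$mbp$mmHg, w_occ))
    gas <- physio$gasometry[physio$gasometry$phase == ph, ]
    gv <- function(col) if (nrow(gas) == 0) NA_real_ else gas[[col]][1]
    add("pH", ph, gv("ph"))
    add("pCO2", ph, gv("pco2_mmHg"))
    add("pO2", ph, gv("po2_mmHg"))
    add("lactate", ph, gv("lactate_mmol_l"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort summary table (median and quartiles across subjects)
#'
#' For each feature and phase, the across-subject median and quartiles of
#' the per-subject summary values ("median of medians"), with the number of
#' subjects contributing to the cell -- subjects lost to the stop rule
#' reduce `n` in the affected phases, as in the source experiment's n = 8
#' in the severe phase.
#'
#' @param subject_summaries Either a list of data frames from
#'   [subject_phase_summary()] or one long data frame with an added
#'   `subject` column.
#' @return Data frame `feature`, `phase`, `median`, `q1`, `q3`, `n`.
#' @export
cohort_table <- function(subject_summaries) {
  if (is.data.frame(subject_summaries)) {
    long <- subject_summaries
  } else {
    long <- do.call(rbind, lapply(seq_along(subject_summaries), function(i)
      cbind(subject = i, subject_summaries[[i]])))
  }
  cells <- unique(long[, c("feature", "phase")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    v <- long$value[long$feature == cells$feature[i] &
                      long$phase == cells$phase[i]]
    v <- v[!is.na(v)]
    if (length(v) == 0)
      return(data.frame(feature = cells$feature[i], phase = cells$phase[i],
                        median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                        n = 0L))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(feature = cells$feature[i], phase = cells$phase[i],
               median = q[2], q1 = q[1], q3 = q[3], n = length(v))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract one feature's subjects-by-phases grid from cohort summaries
#'
#' @param subject_summaries As in [cohort_table()].
#' @param feature Feature name (e.g. `"wSEF"`).
#' @param phases Condition columns, in order.
#' @return Numeric matrix subjects x phases (NA for missing cells), ready
#'   for [friedman_phases()].
#' @export
feature_grid <- function(subject_summaries, feature,
                         phases = c("S", "A", "B", "C")) {
  if (!is.data.frame(subject_summaries)) {
    subject_summaries <- do.call(rbind, lapply(seq_along(subject_summaries),
                                               function(i)
      cbind(subject = i, subject_summaries[[i]])))
  }
  d <- subject_summaries[subject_summaries$feature == feature &
                           subject_summaries$phase %in% phases, ]
  subjects <- sort(unique(d$subject))
  grid <- matrix(NA_real_, length(subjects), length(phases),
                 dimnames = list(subjects, phases))
  for (i in seq_len(nrow(d)))
    grid[as.character(d$subject[i]), d$phase[i]] <- d$value[i]
  grid
}
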