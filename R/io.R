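# Delimited/JSON/YAML interchange for everything that is not EEG:
# physiology series, gasometry, schedules, feature tables, reports.

#' Write / read the physiological record as delimited text
#'
#' Two tab-separated files: `<stem>_haemodynamics.tsv` (`time_s`, `hr_bpm`,
#' `mbp_mmHg`) and `<stem>_gasometry.tsv` (`time_s`, `ph`, `pco2_mmHg`,
#' `po2_mmHg`, `lactate_mmol_l`, `phase`).
#'
#' @param physio A `physio_record`.
#' @param stem Output path stem.
#' @return The two file paths, invisibly.
#' @export
write_physio <- function(physio, stem) {
  haemo <- data.frame(time_s = physio$hr$time_s, hr_bpm = physio$hr$bpm,
                      mbp_mmHg = physio$mbp$mmHg)
  f1 <- paste0(stem, "_haemodynamics.tsv")
  f2 <- paste0(stem, "_gasometry.tsv")
  utils::write.table(haemo, f1, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(physio$gasometry, f2, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(f1, f2))
}

#' @rdname write_physio
#' @export
read_physio <- function(stem) {
  haemo <- utils::read.delim(paste0(stem, "_haemodynamics.tsv"))
  gas <- utils::read.delim(paste0(stem, "_gasometry.tsv"))
  structure(list(hr = data.frame(time_s = haemo$time_s, bpm = haemo$hr_bpm),
                 mbp = data.frame(time_s = haemo$time_s, mmHg = haemo$mbp_mmHg),
                 gasometry = gas, latent_gas = NULL),
            class = "physio_record")
}

#' Write / read a protocol schedule as JSON
#'
#' @param schedule A `uco_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  obj <- list(events = schedule$events,
              truncated_at_s = schedule$truncated_at_s,
              config = unclass(schedule$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  config <- protocol_config(
    phase_duration_s = cfg$phase_duration_s,
    occlusion_duration_s = cfg$occlusion_duration_s,
    inter_occlusion_period_s = unlist(cfg$inter_occlusion_period_s),
    pause_period_s = cfg$pause_period_s,
    pause_duration_s = cfg$pause_duration_s,
    stability_duration_s = cfg$stability_duration_s,
    ph_stop_threshold = cfg$ph_stop_threshold)
  structure(list(events = as.data.frame(obj$events), config = config,
                 truncated_at_s = if (is.null(obj$truncated_at_s))
                   NA_real_ else obj$truncated_at_s),
            class = "uco_schedule")
}

#' Write a qEEG feature series as tab-separated text
#'
#' Undefined SEF values are written as empty fields.
#'
#' @param features A `qeeg_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tab <- utils::read.delim(path, na.strings = "")
  structure(tab, class = c("qeeg_series", "data.frame"))
}

#' Run configuration file (YAML)
#'
#' All protocol, simulation, feature and statistical parameters in one
#' human-readable file that round-trips losslessly.
#'
#' @param config Nested list as produced by [default_run_config()].
#' @param path YAML path.
#' @return `path` / the configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname write_run_config
#' @export
default_run_config <- function() {
  list(
    protocol = unclass(protocol_config())[
      c("phase_duration_s", "occlusion_duration_s", "pause_period_s",
        "pause_duration_s", "stability_duration_s", "ph_stop_threshold")],
    inter_occlusion_period_s = as.list(
      protocol_config()$inter_occlusion_period_s),
    cohort = list(n_subjects = 9, seed = 1),
    features = list(interval_s = 2, envelope_band_hz = c(2, 20),
                    sef_band_hz = c(0.5, 70), sef_quantile = 0.95,
                    suppression_threshold_uV = 10,
                    suppression_min_duration_s = 0.5),
    stats = list(alpha = 0.05, correction = "none"))
}

# Polynomial rolling hash over a serialised object (31-bit); stable
# configuration identifier for manifests.
config_hash <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

#' Write a run manifest
#'
#' Records the seed, a configuration hash, package version and the paths of
#' every stage output, so a rerun with the same hash and seed can be
#' checked for byte-identical feature tables.
#'
#' @param path JSON output path.
#' @param config Run configuration list.
#' @param seed Master seed used.
#' @param outputs Named character vector of output file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, outputs) {
  obj <- list(config_hash = config_hash(config), seed = seed,
              package_version = as.character(utils::packageVersion("fetalqeeg")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              outputs = as.list(outputs))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write the cohort phase table / correlation grid as delimited reports
#'
#' @param table Data frame from [cohort_table()] or [correlation_table()].
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
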