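# Minimal EDF (European Data Format) reader/writer for multichannel EEG.
# Fixed-layout ASCII header + 16-bit little-endian samples in 1-s data
# records; physical unit uV with a configurable symmetric physical range.

edf_pad <- function(x, width) formatC(as.character(x), width = -width)

edf_num <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = 8)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write an EEG recording as EDF
#'
#' One data record per second, all channels at the recording's sampling
#' rate, physical dimension uV over a symmetric physical range mapped onto
#' the 16-bit digital range. Samples outside the physical range are
#' clipped; the quantisation step is `2 * physical_max / 2^16`.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @param physical_max_uV Physical range bound, uV (default 1000).
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path, physical_max_uV = 1000) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate_hz
  if (fs != round(fs)) stop("EDF export needs an integer sampling rate",
                            call. = FALSE)
  ns <- ncol(rec$samples)
  n <- nrow(rec$samples)
  n_rec <- ceiling(n / fs)
  pad <- n_rec * fs - n
  x <- rbind(rec$samples, matrix(0, pad, ns))
  dig_max <- 32767
  scaled <- round(pmax(pmin(x / physical_max_uV, 1), -1) * dig_max)

  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),                          # patient id
    edf_pad("Startdate X X X X", 80),                # recording id
    "01.01.00", "00.00.00",
    edf_pad(256 + 256 * ns, 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4),
    paste(vapply(colnames(rec$samples), edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),  # transducer
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(rep(edf_num(-physical_max_uV, 8), ns), collapse = ""),
    paste(rep(edf_num(physical_max_uV, 8), ns), collapse = ""),
    paste(rep(edf_num(-dig_max, 8), ns), collapse = ""),
    paste(rep(edf_num(dig_max, 8), ns), collapse = ""),
    paste(rep(edf_pad("BP:0.5-70Hz", 80), ns), collapse = ""),
    paste(rep(edf_num(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = ""))
  writeChar(header, con, eos = NULL)
  # record-major, channel blocks inside each record
  idx <- matrix(seq_len(n_rec * fs), nrow = fs)
  out <- integer(n_rec * fs * ns)
  for (r in seq_len(n_rec)) {
    block <- as.integer(scaled[idx[, r], ])
    out[((r - 1) * fs * ns + 1):(r * fs * ns)] <- block
  }
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file into an EEG recording
#'
#' Supports the subset written by [write_eeg()]: identical sampling rate
#' across channels and integer-second data records. Signals are rescaled
#' to physical units from each channel's physical/digital ranges.
#'
#' @param path EDF file path.
#' @param montage Optional [montage_spec()]; when given, all montage
#'   channels must be present or a montage error is raised.
#' @return An `eeg_recording`.
#' @export
read_eeg <- function(path, montage = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(k) readChar(con, k, useBytes = TRUE)
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # ids, date, time
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(header_bytes))
    stop("malformed EDF header", call. = FALSE)
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fld(16)
  fld(80)                                 # transducer
  dims <- fld(8)
  phys_min <- as.numeric(fld(8))
  phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8))
  dig_max <- as.numeric(fld(8))
  fld(80)                                 # prefiltering
  spr <- as.integer(fld(8))
  fld(32)
  if (any(is.na(phys_min)) || any(is.na(spr)))
    stop("malformed EDF signal header", call. = FALSE)
  if (!all(dims %in% c("uV", "µV")))
    stop("unit mismatch: expected uV channels, got ",
         paste(unique(dims), collapse = ", "), call. = FALSE)
  if (length(unique(spr)) != 1)
    stop("channels with differing sampling rates are not supported",
         call. = FALSE)
  fs <- spr[1] / rec_dur
  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                 endian = "little")
  samples <- matrix(0, n_rec * spr[1], ns, dimnames = list(NULL, labels))
  per_rec <- sum(spr)
  for (ch in seq_len(ns)) {
    off <- c(0, cumsum(spr))[ch]
    sel <- as.vector(outer(off + seq_len(spr[ch]), (seq_len(n_rec) - 1) * per_rec, "+"))
    gain <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
    samples[, ch] <- (raw[sel] - dig_min[ch]) * gain + phys_min[ch]
  }
  rec <- structure(list(samples = samples, channel_labels = labels,
                        sample_rate_hz = fs, start_time_s = 0),
                   class = "eeg_recording")
  if (!is.null(montage)) {
    missing <- setdiff(unique(unlist(montage$derivations)), labels)
    if (length(missing) > 0)
      stop("montage channel(s) not in EDF: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  rec
}
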