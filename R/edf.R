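# Minimal EDF (European Data Format) reader/writer: 16-bit integer samples,
# ASCII header, one physical dimension per channel. Covers the plain EDF
# subset used by CHB-MIT-style scalp recordings; no EDF+ annotation channels.

edf_field <- function(con, width) {
  trimws(rawToChar(readBin(con, "raw", n = width)))
}

edf_num <- function(con, width) {
  as.numeric(edf_field(con, width))
}

#' Read an EDF file
#'
#' Parses a 16-bit EDF file into per-channel physical-unit signals.
#'
#' @param path Path to an EDF file.
#' @return A list with `labels`, `fs` (per-channel sampling rates),
#'   `signals` (list of numeric vectors in physical units), `units`,
#'   `record_duration_s` and `n_records`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("EDF file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_field(con, 8)
  if (!identical(version, "0")) stopf("not a valid EDF file (version field '%s')", version)
  readBin(con, "raw", n = 80 + 80 + 8 + 8)      # patient, recording, date, time
  header_bytes <- edf_num(con, 8)
  edf_field(con, 44)                            # reserved
  n_records <- edf_num(con, 8)
  record_dur <- edf_num(con, 8)
  ns <- as.integer(edf_num(con, 4))
  if (is.na(ns) || ns < 1) stopf("EDF header reports %s signals", ns)
  labels <- vapply(seq_len(ns), function(i) edf_field(con, 16), "")
  for (i in seq_len(ns)) edf_field(con, 80)     # transducer
  units <- vapply(seq_len(ns), function(i) edf_field(con, 8), "")
  pmin <- vapply(seq_len(ns), function(i) edf_num(con, 8), 0)
  pmax <- vapply(seq_len(ns), function(i) edf_num(con, 8), 0)
  dmin <- vapply(seq_len(ns), function(i) edf_num(con, 8), 0)
  dmax <- vapply(seq_len(ns), function(i) edf_num(con, 8), 0)
  for (i in seq_len(ns)) edf_field(con, 80)     # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(edf_num(con, 8)), 1L)
  for (i in seq_len(ns)) edf_field(con, 32)     # reserved
  if (header_bytes != 256 * (ns + 1)) {
    stopf("EDF header size %d inconsistent with %d signals", header_bytes, ns)
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  signals <- lapply(seq_len(ns), function(i) numeric(n_records * spr[i]))
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      signals[[i]][seq((r - 1) * spr[i] + 1, r * spr[i])] <-
        (dig - dmin[i]) * scale[i] + pmin[i]
    }
  }
  list(labels = labels, fs = spr / record_dur, signals = signals, units = units,
       record_duration_s = record_dur, n_records = n_records)
}

#' Write a recording to EDF
#'
#' Writes an [eeg_recording()] (or a pre-ictal window) as a 16-bit EDF file
#' with one-second data records. The signal is truncated to whole seconds;
#' amplitudes are quantized to the per-channel physical range.
#'
#' @param rec An `eeg_recording` or `preictal_window`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  data <- rec$data
  fs <- rec$fs
  if (fs != round(fs)) stopf("EDF writer requires an integer sampling rate")
  ns <- nrow(data)
  n_records <- floor(ncol(data) / fs)
  if (n_records < 1) stopf("recording shorter than one EDF record (1 s)")
  if (n_records * fs < ncol(data)) {
    warnf("truncating %d trailing samples to whole EDF records",
          ncol(data) - n_records * fs)
    data <- data[, seq_len(n_records * fs), drop = FALSE]
  }
  pmax <- apply(abs(data), 1, max)
  pmax <- ifelse(pmax <= 0, 1, pmax * 1.0001)   # avoid zero-width range
  pmin <- -pmax
  dmin <- -32768; dmax <- 32767

  pad <- function(x, width) {
    x <- as.character(x)
    x <- substr(x, 1, width)
    formatC(x, width = width, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeBin(charToRaw(pad(x, width)), con)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8); wr("", 44); wr(n_records, 8); wr("1", 8); wr(ns, 4)
  for (lab in rec$channel_labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(formatC(pmin[i], format = "g", digits = 6), 8)
  for (i in seq_len(ns)) wr(formatC(pmax[i], format = "g", digits = 6), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  # header strings were written with formatC; recompute ranges from them so
  # the round trip uses exactly the values a reader will parse
  pmin_w <- as.numeric(formatC(pmin, format = "g", digits = 6))
  pmax_w <- as.numeric(formatC(pmax, format = "g", digits = 6))
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      seg <- data[i, seq((r - 1) * fs + 1, r * fs)]
      dig <- round((seg - pmin_w[i]) / (pmax_w[i] - pmin_w[i]) * (dmax - dmin) + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
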