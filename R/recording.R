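#' Default 18-channel bipolar montage
#'
#' The longitudinal-bipolar ("double banana") derivations used throughout the
#' package. Eighteen channels give an integer per-channel budget for the
#' 1,440-dimensional feature vector (80 features per channel).
#'
#' @return Character vector of 18 montage labels.
#' @export
default_montage <- function() {
  c("FP1-F7", "F7-T7", "T7-P7", "P7-O1",
    "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
    "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
    "FP2-F8", "F8-T8", "T8-P8", "P8-O2",
    "FZ-CZ", "CZ-PZ")
}

#' Construct an EEG recording
#'
#' A recording is a channels-by-samples numeric matrix in microvolts with a
#' sampling rate, ordered channel labels and a subject identifier.
#'
#' @param data Numeric matrix, channels x samples, amplitudes in microvolts.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_labels Character vector of unique montage labels, one per row.
#' @param subject_id Subject identifier string.
#' @param source_file Originating file name, if any (carried into window
#'   manifests).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels, subject_id = "unknown",
                          source_file = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1L) {
    stopf("recording needs a numeric matrix with at least one channel")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stopf("fs must be a positive number (got %s)", format(fs))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stopf("%d channel labels for %d data rows", length(channel_labels), nrow(data))
  }
  if (anyDuplicated(channel_labels)) {
    stopf("channel labels must be unique")
  }
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 subject_id = as.character(subject_id),
                 source_file = as.character(source_file)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Construct a pre-ictal window
#'
#' A provenance-carrying slice of a recording ending at (or a configured gap
#' before) an annotated seizure onset.
#'
#' @param data Channels x samples matrix in microvolts.
#' @param fs Sampling rate (Hz).
#' @param channel_labels Channel labels, one per row.
#' @param subject_id Subject identifier.
#' @param seizure_index 1-based index of the seizure this window precedes.
#' @param start_s,end_s Window boundaries in source-recording seconds
#'   (half-open interval, `end_s` exclusive).
#' @param window_id Unique identifier; defaults to `subject_id` and
#'   `seizure_index`.
#' @param source_file Originating file name, if any.
#' @return An object of class `preictal_window`.
#' @export
preictal_window <- function(data, fs, channel_labels, subject_id,
                            seizure_index = 1L, start_s = 0, end_s = NULL,
                            window_id = NULL, source_file = NA_character_) {
  data <- as.matrix(data)
  if (is.null(end_s)) end_s <- start_s + ncol(data) / fs
  dur <- end_s - start_s
  if (abs(dur * fs - ncol(data)) > 1e-6) {
    stopf("window spans %.6f s but holds %d samples at %g Hz", dur, ncol(data), fs)
  }
  channel_labels <- as.character(channel_labels)
  rownames(data) <- channel_labels
  if (is.null(window_id)) window_id <- sprintf("%s_w%02d", subject_id, seizure_index)
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 subject_id = as.character(subject_id),
                 seizure_index = as.integer(seizure_index),
                 start_s = start_s, end_s = end_s,
                 window_id = as.character(window_id),
                 source_file = as.character(source_file)),
            class = "preictal_window")
}

#' @export
print.preictal_window <- function(x, ...) {
  cat(sprintf("<preictal_window> %s: %d ch x %d samples @ %g Hz, source %.1f-%.1f s\n",
              x$window_id, nrow(x$data), ncol(x$data), x$fs, x$start_s, x$end_s))
  invisible(x)
}

window_duration_s <- function(window) ncol(window$data) / window$fs

frontal_channel_idx <- function(channel_labels) {
  which(grepl("^FP[12]", normalize_label(channel_labels)))
}
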