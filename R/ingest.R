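# Ingest: EDF recordings, seizure annotations, pre-ictal window extraction.

#' Read an EEG recording restricted to a montage
#'
#' Reads an EDF file and returns the requested channels, in the requested
#' order, as an [eeg_recording()]. Label matching is case-insensitive and
#' tolerant of hyphen/space spelling differences.
#'
#' @param path Path to an EDF file.
#' @param montage Character vector of channel labels to select, in order.
#'   Defaults to the 18-channel bipolar montage of [default_montage()].
#' @param subject_id Subject identifier to attach; defaults to the file stem.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, montage = default_montage(), subject_id = NULL) {
  if (length(montage) < 1L) stopf("montage must name at least one channel")
  edf <- read_edf(path)
  have <- normalize_label(edf$labels)
  want <- normalize_label(montage)
  idx <- match(want, have)
  if (anyNA(idx)) {
    stopf("channel(s) not present in %s: %s", basename(path),
          paste(montage[is.na(idx)], collapse = ", "))
  }
  fs <- edf$fs[idx]
  if (length(unique(fs)) != 1L) {
    stopf("requested channels have mixed sampling rates: %s",
          paste(unique(fs), collapse = ", "))
  }
  data <- do.call(rbind, edf$signals[idx])
  if (is.null(subject_id)) {
    subject_id <- sub("_.*$", "", tools::file_path_sans_ext(basename(path)))
  }
  eeg_recording(data, fs[1], montage, subject_id, source_file = basename(path))
}

#' Parse a CHB-MIT-style seizure summary
#'
#' Parses the plain-text annotation dialect in which each recording block
#' lists `File Name:`, `Number of Seizures in File:` and per-seizure
#' `Seizure Start Time: N seconds` / `Seizure End Time: M seconds` lines.
#'
#' @param text Character scalar (or vector of lines) with the summary text.
#' @return Named list mapping file name to a data frame with columns
#'   `onset_s`, `offset_s`, `source_file`, ordered by onset.
#' @export
parse_seizure_summary <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines)
  out <- list()
  current <- NULL
  declared <- NULL
  starts <- numeric(0)
  ends <- numeric(0)
  flush <- function() {
    if (is.null(current)) return()
    if (length(starts) != length(ends)) {
      stopf("file %s: %d start times but %d end times", current,
            length(starts), length(ends))
    }
    if (!is.null(declared) && declared != length(starts)) {
      stopf("file %s declares %d seizures but lists %d", current, declared,
            length(starts))
    }
    bad <- which(ends < starts)
    if (length(bad)) {
      stopf("file %s: seizure end %g s before start %g s", current,
            ends[bad[1]], starts[bad[1]])
    }
    ord <- order(starts)
    out[[current]] <<- data.frame(onset_s = starts[ord], offset_s = ends[ord],
                                  source_file = rep(current, length(starts)),
                                  stringsAsFactors = FALSE)
  }
  for (ln in lines) {
    if (grepl("^File Name:", ln)) {
      flush()
      current <- trimws(sub("^File Name:", "", ln))
      declared <- NULL; starts <- numeric(0); ends <- numeric(0)
    } else if (grepl("^Number of Seizures in File:", ln)) {
      declared <- as.integer(sub("^Number of Seizures in File:", "", ln))
    } else if (grepl("^Seizure( [0-9]+)? Start Time:", ln)) {
      starts <- c(starts, as.numeric(gsub("[^0-9.]", "", sub(".*Start Time:", "", ln))))
    } else if (grepl("^Seizure( [0-9]+)? End Time:", ln)) {
      ends <- c(ends, as.numeric(gsub("[^0-9.]", "", sub(".*End Time:", "", ln))))
    }
  }
  flush()
  out
}

#' Extract one pre-ictal window before a seizure onset
#'
#' Cuts the `[onset - gap - duration, onset - gap)` slice from a recording.
#' Windows with insufficient pre-onset signal are skipped with a warning and
#' `NULL` is returned, so callers can keep a manifest of skipped events
#' rather than crash.
#'
#' @param rec An [eeg_recording()].
#' @param onset_s Seizure onset in seconds from recording start.
#' @param duration_s Window length in seconds (default 30).
#' @param gap_s Gap between window end and onset in seconds (default 0:
#'   the window abuts the onset).
#' @param seizure_index 1-based seizure counter used for provenance.
#' @return A [preictal_window()], or `NULL` if the window would start before
#'   the recording does.
#' @export
extract_preictal_window <- function(rec, onset_s, duration_s = 30, gap_s = 0,
                                    seizure_index = 1L) {
  start_s <- onset_s - gap_s - duration_s
  end_s <- onset_s - gap_s
  if (start_s < 0) {
    warnf("seizure %d of %s at %g s: only %g s of pre-onset signal (< %g s); skipped",
          seizure_index, rec$subject_id, onset_s, max(0, end_s), duration_s)
    return(NULL)
  }
  if (end_s > ncol(rec$data) / rec$fs + 1e-9) {
    stopf("onset %g s lies beyond the recording (%g s)", onset_s,
          ncol(rec$data) / rec$fs)
  }
  i0 <- round(start_s * rec$fs)
  n <- round(duration_s * rec$fs)
  preictal_window(rec$data[, seq(i0 + 1, i0 + n), drop = FALSE],
                  fs = rec$fs, channel_labels = rec$channel_labels,
                  subject_id = rec$subject_id, seizure_index = seizure_index,
                  start_s = start_s, end_s = end_s,
                  source_file = rec$source_file %||% NA_character_)
}

#' Extract all pre-ictal windows for a recording
#'
#' @param rec An [eeg_recording()].
#' @param events Data frame with an `onset_s` column (as produced by
#'   [parse_seizure_summary()]).
#' @param duration_s,gap_s Passed to [extract_preictal_window()].
#' @return List with `windows` (list of [preictal_window()]) and `manifest`
#'   (data frame, one row per event, with a `skipped` flag).
#' @export
extract_preictal_windows <- function(rec, events, duration_s = 30, gap_s = 0) {
  windows <- list()
  rows <- list()
  for (i in seq_len(nrow(events))) {
    w <- withCallingHandlers(
      extract_preictal_window(rec, events$onset_s[i], duration_s, gap_s, i),
      warning = function(cnd) invokeRestart("muffleWarning"))
    skipped <- is.null(w)
    rows[[i]] <- data.frame(
      subject_id = rec$subject_id,
      source_file = events$source_file[i] %||% NA_character_,
      seizure_index = i,
      start_s = if (skipped) NA_real_ else w$start_s,
      end_s = if (skipped) NA_real_ else w$end_s,
      n_samples = if (skipped) NA_integer_ else ncol(w$data),
      skipped = skipped,
      stringsAsFactors = FALSE)
    if (!skipped) windows[[length(windows) + 1L]] <- w
  }
  manifest <- do.call(rbind, rows)
  if (any(manifest$skipped)) {
    warnf("%d of %d seizure(s) skipped: insufficient pre-onset signal",
          sum(manifest$skipped), nrow(manifest))
  }
  list(windows = windows, manifest = manifest)
}

#' Write a window manifest as TSV
#'
#' @param windows List of [preictal_window()] objects.
#' @param path Output TSV path.
#' @return The manifest data frame, invisibly.
#' @export
write_window_manifest <- function(windows, path) {
  manifest <- do.call(rbind, lapply(windows, function(w) {
    data.frame(subject_id = w$subject_id,
               source_file = w$source_file %||% NA_character_,
               window_id = w$window_id,
               seizure_index = w$seizure_index, start_s = w$start_s,
               end_s = w$end_s, n_samples = ncol(w$data),
               stringsAsFactors = FALSE)
  }))
  write_tsv(manifest, path)
  invisible(manifest)
}
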