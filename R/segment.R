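# Segmentation: split pre-ictal windows into fixed-length non-overlapping
# segments with cohort bookkeeping. Sample indexing is 0-based half-open:
# segment i covers samples [i * seg_len * fs, (i + 1) * seg_len * fs).

#' Split a pre-ictal window into non-overlapping segments
#'
#' @param window A [preictal_window()].
#' @param seg_len_s Segment length in seconds (default 5, so a 30-s window
#'   yields six segments).
#' @return List of `eeg_segment` objects in temporal order. A trailing
#'   partial remainder is dropped with a warning.
#' @export
segment_window <- function(window, seg_len_s = 5) {
  if (!is.numeric(seg_len_s) || seg_len_s <= 0) stopf("seg_len_s must be > 0")
  dur <- window_duration_s(window)
  if (dur < seg_len_s) stopf("window (%.1f s) shorter than one segment (%g s)", dur, seg_len_s)
  n_seg <- floor(dur / seg_len_s + 1e-9)
  spseg <- round(seg_len_s * window$fs)
  if (n_seg * spseg < ncol(window$data)) {
    warnf("window %s: dropping %.2f s trailing remainder (%d segments kept)",
          window$window_id, dur - n_seg * seg_len_s, n_seg)
  }
  lapply(seq_len(n_seg) - 1L, function(i) {
    structure(list(
      data = window$data[, seq(i * spseg + 1, (i + 1) * spseg), drop = FALSE],
      fs = window$fs,
      channel_labels = window$channel_labels,
      subject_id = window$subject_id,
      window_id = window$window_id,
      segment_index = i,
      start_sample = i * spseg,
      end_sample = (i + 1L) * spseg),
      class = "eeg_segment")
  })
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %s[%d]: %d ch x %d samples @ %g Hz\n",
              x$window_id, x$segment_index, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Segment a set of windows and tabulate per-subject counts
#'
#' @param windows Non-empty list of [preictal_window()] objects.
#' @param seg_len_s Segment length in seconds.
#' @return A `segment_set`: list with `segments` (flat, ordered list of
#'   segments), `per_subject_counts` (data frame subject_id/windows/segments)
#'   and `totals`.
#' @export
segment_dataset <- function(windows, seg_len_s = 5) {
  if (length(windows) < 1L) stopf("no windows to segment")
  segs <- unlist(lapply(windows, segment_window, seg_len_s = seg_len_s),
                 recursive = FALSE)
  subj_w <- vapply(windows, function(w) w$subject_id, "")
  subj_s <- vapply(segs, function(s) s$subject_id, "")
  subjects <- unique(subj_w)
  counts <- data.frame(
    subject_id = subjects,
    windows = as.integer(table(factor(subj_w, levels = subjects))),
    segments = as.integer(table(factor(subj_s, levels = subjects))),
    stringsAsFactors = FALSE)
  structure(list(segments = segs,
                 per_subject_counts = counts,
                 totals = c(windows = length(windows), segments = length(segs))),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d windows -> %d segments across %d subjects\n",
              x$totals["windows"], x$totals["segments"],
              nrow(x$per_subject_counts)))
  invisible(x)
}

#' Write a segment manifest as TSV
#'
#' @param segment_set A `segment_set` from [segment_dataset()].
#' @param path Output TSV path.
#' @return The manifest data frame, invisibly.
#' @export
write_segment_manifest <- function(segment_set, path) {
  manifest <- do.call(rbind, lapply(segment_set$segments, function(s) {
    data.frame(subject_id = s$subject_id, window_id = s$window_id,
               segment_index = s$segment_index, start_sample = s$start_sample,
               end_sample = s$end_sample, stringsAsFactors = FALSE)
  }))
  write_tsv(manifest, path)
  invisible(manifest)
}
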