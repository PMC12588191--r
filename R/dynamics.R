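# Cluster-transition dynamics: per-window label sequences, categorical
# moving-average smoothing, and row-stochastic transition matrices.
# Transitions never span window boundaries, and noise labels (-1) break
# pair adjacency rather than bridging it.

#' Build per-window label sequences
#'
#' @param meta Data frame with `window_id` and `segment_index` columns, one
#'   row per segment (as in a `feature_matrix`'s `meta`), in any order.
#' @param labels Integer labels aligned with the rows of `meta`
#'   (-1 allowed for filtered segments).
#' @return Named list of integer label vectors, one per window, ordered by
#'   `segment_index`.
#' @export
build_sequences <- function(meta, labels) {
  if (nrow(meta) != length(labels)) stopf("one label per segment required")
  key <- paste(meta$window_id, meta$segment_index)
  if (anyDuplicated(key)) {
    stopf("duplicate (window_id, segment_index) pair: %s", key[duplicated(key)][1])
  }
  out <- split(data.frame(idx = meta$segment_index, lab = labels),
               meta$window_id)
  out <- lapply(out, function(d) {
    d <- d[order(d$idx), ]
    if (!identical(as.integer(d$idx), seq_len(nrow(d)) - 1L)) {
      stopf("missing segment_index in window (found: %s)",
            paste(d$idx, collapse = ","))
    }
    as.integer(d$lab)
  })
  out[unique(meta$window_id)]                     # original window order
}

#' Moving-average smoothing of a categorical label sequence
#'
#' Labels are one-hot encoded and averaged over a trailing window of
#' `window` elements of the original sequence; the smoothed label is the
#' argmax, with ties resolved in favor of the previous smoothed label. The
#' first element is unchanged; `window = 1` is the identity.
#'
#' @param seq_labels Integer vector of labels (-1 allowed).
#' @param window Trailing window length in segments (default 2).
#' @return Integer vector of smoothed labels.
#' @export
smooth_labels <- function(seq_labels, window = 2) {
  if (window < 1) stopf("window must be >= 1")
  n <- length(seq_labels)
  if (n == 0 || window == 1) return(seq_labels)
  states <- sort(unique(seq_labels))
  out <- seq_labels
  for (i in 2:n) {
    lo <- max(1, i - window + 1)
    votes <- table(factor(seq_labels[lo:i], levels = states))
    top <- states[votes == max(votes)]
    out[i] <- if (out[i - 1] %in% top) out[i - 1] else top[1]
  }
  out
}

#' Empirical transition matrix over within-window sequences
#'
#' Counts consecutive label pairs inside each window (never across windows)
#' and row-normalizes the counts. Pairs involving the noise label -1 are
#' skipped when `exclude_noise` is TRUE. Rows with no outgoing transitions
#' are all-zero in `probs`.
#'
#' @param sequences List of integer label vectors (from
#'   [build_sequences()]).
#' @param exclude_noise Skip pairs touching -1 (default TRUE).
#' @return A `transition_matrix`: `counts` (k x k integer), `probs`
#'   (k x k row-stochastic), `state_ids` (ordered labels).
#' @export
transition_matrix <- function(sequences, exclude_noise = TRUE) {
  pairs_from <- integer(0)
  pairs_to <- integer(0)
  for (s in sequences) {
    if (length(s) < 2) next
    a <- s[-length(s)]; b <- s[-1]
    if (exclude_noise) {
      ok <- a != -1L & b != -1L
      a <- a[ok]; b <- b[ok]
    }
    pairs_from <- c(pairs_from, a)
    pairs_to <- c(pairs_to, b)
  }
  if (!length(pairs_from)) stopf("no transitions observed")
  states <- sort(unique(c(pairs_from, pairs_to)))
  k <- length(states)
  counts <- matrix(0L, k, k, dimnames = list(states, states))
  for (i in seq_along(pairs_from)) {
    r <- match(pairs_from[i], states); c0 <- match(pairs_to[i], states)
    counts[r, c0] <- counts[r, c0] + 1L
  }
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, probs = probs, state_ids = states),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d states, %d transitions\n",
              length(x$state_ids), sum(x$counts)))
  print(round(x$probs, 3))
  invisible(x)
}

label_changes <- function(sequences) {
  sum(vapply(sequences, function(s) sum(diff(s) != 0), 0L))
}

#' Summarize transition dynamics
#'
#' Per-state top destinations, the overall most and least frequent observed
#' transitions, and the within-window label-change count before vs after
#' smoothing (smoothing never increases it).
#'
#' @param tm A `transition_matrix`.
#' @param sequences The raw label sequences the matrix was built from.
#' @param smooth_window Smoothing window passed to [smooth_labels()]
#'   (default 2).
#' @return A `dynamics_report` list.
#' @export
dynamics_report <- function(tm, sequences, smooth_window = 2) {
  k <- length(tm$state_ids)
  top_dest <- data.frame(
    from = tm$state_ids,
    to = tm$state_ids[apply(tm$probs, 1, which.max)],
    prob = apply(tm$probs, 1, max))
  top_dest$to[rowSums(tm$counts) == 0] <- NA_integer_
  observed <- which(tm$counts > 0, arr.ind = TRUE)
  cnt <- tm$counts[observed]
  most <- observed[which.max(cnt), ]
  least <- observed[which.min(cnt), ]
  smoothed <- lapply(sequences, smooth_labels, window = smooth_window)
  structure(list(
    top_destinations = top_dest,
    most_frequent = c(from = tm$state_ids[most[1]], to = tm$state_ids[most[2]],
                      count = max(cnt)),
    least_frequent = c(from = tm$state_ids[least[1]], to = tm$state_ids[least[2]],
                       count = min(cnt)),
    changes_before = label_changes(sequences),
    changes_after = label_changes(smoothed),
    smooth_window = smooth_window,
    smoothed_sequences = smoothed),
    class = "dynamics_report")
}

#' @export
print.dynamics_report <- function(x, ...) {
  cat(sprintf("<dynamics_report> label changes %d -> %d after smoothing (window %d)\n",
              x$changes_before, x$changes_after, x$smooth_window))
  invisible(x)
}

#' Write a transition matrix as TSV files
#'
#' @param tm A `transition_matrix`.
#' @param prefix Output path prefix: writes `<prefix>_counts.tsv` and
#'   `<prefix>_probs.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_transition_matrix <- function(tm, prefix) {
  write_tsv(as.data.frame(tm$counts), paste0(prefix, "_counts.tsv"))
  write_tsv(as.data.frame(round(tm$probs, 6)), paste0(prefix, "_probs.tsv"))
  invisible(prefix)
}
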