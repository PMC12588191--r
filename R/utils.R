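# shared internal helpers

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so pipeline calls do not disturb user code.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a base seed and a stream label, keeping the result
# within the 32-bit integer range R requires.
derive_seed <- function(seed, stream) {
  cp <- utf8ToInt(as.character(stream))
  h <- sum(cp * seq_along(cp))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Normalize an electrode/montage label: case- and separator-insensitive.
normalize_label <- function(x) {
  gsub("[^A-Z0-9]", "", toupper(trimws(x)))
}

# Zero-phase Butterworth filtering (forward-backward) with odd reflection
# padding at both ends to suppress filter edge transients.
filtfilt_pad <- function(filt, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, max(3L * 8L, 256L))
  if (pad < 1L) return(signal::filtfilt(filt, x))
  head_pad <- 2 * x[1] - x[seq(pad + 1, 2)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - pad)]
  y <- signal::filtfilt(filt, c(head_pad, x, tail_pad))
  y[seq(pad + 1, pad + n)]
}

percent_reduction <- function(pre, post) {
  if (!is.finite(pre) || pre <= 0) return(NA_real_)
  100 * (pre - post) / pre
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
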