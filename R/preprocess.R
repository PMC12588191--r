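# Preprocessing: z-scoring, zero-phase band-pass, seeded FastICA artifact
# removal, and quantitative blink / mains-noise metrics.

#' Z-score a window per channel
#'
#' Each channel is centered and scaled to population standard deviation 1
#' over the window. Zero-variance channels are set to zeros and flagged
#' with a warning instead of producing NaNs.
#'
#' @param window A [preictal_window()].
#' @return The window with normalized data; the original per-channel means
#'   and SDs are kept in the `zscore` field (used to express artifact
#'   metrics in microvolts after cleaning).
#' @export
zscore_normalize <- function(window) {
  x <- window$data
  if (length(x) == 0) stopf("empty window")
  mu <- rowMeans(x)
  xc <- x - mu
  sds <- sqrt(rowMeans(xc^2))          # population SD
  flagged <- which(sds == 0)
  if (length(flagged)) {
    warnf("zero-variance channel(s) set to 0: %s",
          paste(window$channel_labels[flagged], collapse = ", "))
  }
  div <- ifelse(sds == 0, 1, sds)
  window$data <- xc / div
  window$zscore <- list(means = mu, sds = sds, flagged = flagged)
  window
}

butter_hp <- function(low, fs, order) {
  signal::butter(order, low / (fs / 2), type = "high")
}

butter_lp <- function(high, fs, order) {
  signal::butter(order, high / (fs / 2), type = "low")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth high-pass at `low` Hz followed by an
#' order-`order` low-pass at `high` Hz, each forward-backward (zero phase,
#' squared magnitude response) with reflection padding to suppress edge
#' transients. The high-/low-pass cascade keeps the recursion numerically
#' stable for the very asymmetric 0.5-45 Hz band.
#'
#' @param window A [preictal_window()].
#' @param low,high Band edges in Hz (defaults 0.5 and 45).
#' @param order Butterworth order per section (default 4).
#' @return The filtered window.
#' @export
bandpass <- function(window, low = 0.5, high = 45, order = 4) {
  fs <- window$fs
  if (!(low > 0 && low < high)) stopf("need 0 < low < high (got %g, %g)", low, high)
  if (high >= fs / 2) stopf("high edge %g Hz at or above Nyquist (%g Hz)", high, fs / 2)
  hp <- butter_hp(low, fs, order)
  lp <- butter_lp(high, fs, order)
  pad <- min(ncol(window$data) - 1L, as.integer(2 * fs))
  window$data <- t(apply(window$data, 1, function(ch) {
    filtfilt_pad(lp, filtfilt_pad(hp, ch, pad), pad)
  }))
  rownames(window$data) <- window$channel_labels
  window
}

#' Fit a seeded FastICA decomposition
#'
#' Symmetric FastICA (logcosh contrast) on the channels of a window after
#' per-channel centering and PCA whitening. Deterministic given `seed`;
#' extracted sources have unit variance.
#'
#' @param window A [preictal_window()], ideally high-pass filtered
#'   (>= 0.5 Hz) beforehand.
#' @param n_components Number of components (default: number of channels).
#' @param seed Integer seed for the random orthogonal initialization.
#' @param max_iter Maximum fixed-point iterations (default 200).
#' @param tol Convergence tolerance on the unmixing update (default 1e-4).
#' @return An `ica_decomposition` with `mixing` (channels x components),
#'   `unmixing` (components x channels), `sources` (components x samples),
#'   channel means, and fit metadata.
#' @export
fit_ica <- function(window, n_components = NULL, seed = 1L, max_iter = 200L,
                    tol = 1e-4) {
  x <- window$data
  p <- nrow(x)
  if (is.null(n_components)) n_components <- p
  if (n_components > p) {
    stopf("n_components (%d) exceeds channel count (%d)", n_components, p)
  }
  n <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_components)
  d <- pmax(eg$values[keep], .Machine$double.eps)
  K <- diag(1 / sqrt(d), n_components) %*% t(eg$vectors[, keep, drop = FALSE])
  z <- K %*% xc                                   # whitened: cov(z) = I
  W <- with_seed(seed, {
    m0 <- matrix(rnorm(n_components^2), n_components)
    qr.Q(qr(m0))
  })
  sym_decorrelate <- function(W) {
    e <- eigen(tcrossprod(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)),
                       n_components) %*% t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    wz <- W %*% z
    g <- tanh(wz)
    gprime <- rowMeans(1 - g^2)
    W1 <- tcrossprod(g, z) / n - diag(gprime, n_components) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    cnd <- simpleError(sprintf("FastICA did not converge after %d iterations (tol %g)",
                               iter, tol))
    cnd$iterations <- iter
    stop(cnd)
  }
  unmixing <- W %*% K
  sources <- unmixing %*% xc
  mixing <- tcrossprod(xc, sources) / n           # sources are white
  structure(list(mixing = mixing, unmixing = unmixing, sources = sources,
                 means = mu, n_components = n_components, seed = seed,
                 iterations = iter, converged = TRUE,
                 channel_labels = window$channel_labels, fs = window$fs),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components over %d channels (%d iterations)\n",
              x$n_components, length(x$channel_labels), x$iterations))
  invisible(x)
}

source_power_fractions <- function(src, fs, bands) {
  n <- length(src)
  p <- Mod(stats::fft(src))^2
  half <- seq_len(floor(n / 2) + 1L)
  p <- p[half]
  f <- (half - 1) * fs / n
  total <- sum(p)
  if (total == 0) return(rep(0, length(bands)))
  vapply(bands, function(b) sum(p[f >= b[1] & f <= b[2]]) / total, 0)
}

#' Flag blink and line-noise independent components
#'
#' A component is flagged as blink when its frontal-channel loading fraction
#' exceeds `frontal_fraction`, its sample excess kurtosis exceeds
#' `kurtosis_min`, and more than `lowfreq_fraction` of its power lies below
#' 5 Hz. A component is flagged as line noise when the fraction of its power
#' within `mains_hz` +/- 1 Hz exceeds `line_fraction`.
#'
#' @param ica An `ica_decomposition` fitted on `window`.
#' @param window The window the decomposition was fitted on (provides
#'   channel labels for the frontal test).
#' @param mains_hz Mains frequency (default 50).
#' @param frontal_fraction,kurtosis_min,lowfreq_fraction,line_fraction
#'   Detection thresholds (defaults 0.6, 5, 0.5, 0.3).
#' @return List with integer vectors `blink` and `line` (possibly empty).
#' @export
flag_artifact_components <- function(ica, window, mains_hz = 50,
                                     frontal_fraction = 0.6, kurtosis_min = 5,
                                     lowfreq_fraction = 0.5, line_fraction = 0.3) {
  frontal <- frontal_channel_idx(window$channel_labels)
  blink <- integer(0)
  line <- integer(0)
  for (i in seq_len(ica$n_components)) {
    load <- abs(ica$mixing[, i])
    s <- ica$sources[i, ]
    fr <- source_power_fractions(s, ica$fs,
                                 list(c(0, 5), c(mains_hz - 1, mains_hz + 1)))
    if (length(frontal)) {
      ffrac <- sum(load[frontal]) / sum(load)
      k <- excess_kurtosis(s)
      if (ffrac > frontal_fraction && k > kurtosis_min && fr[1] > lowfreq_fraction) {
        blink <- c(blink, i)
      }
    }
    if (fr[2] > line_fraction) line <- c(line, i)
  }
  list(blink = blink, line = line)
}

#' Reconstruct a window with selected components removed
#'
#' @param ica An `ica_decomposition` fitted on `window`.
#' @param window The window to clean.
#' @param indices Component indices to zero out (empty set = identity).
#' @return The window with flagged sources removed from its data.
#' @export
remove_components <- function(ica, window, indices) {
  indices <- unique(as.integer(indices))
  if (length(indices) && (min(indices) < 1 || max(indices) > ica$n_components)) {
    stopf("component index out of range 1..%d", ica$n_components)
  }
  keep <- setdiff(seq_len(ica$n_components), indices)
  recon <- ica$mixing[, keep, drop = FALSE] %*%
    ica$sources[keep, , drop = FALSE] + ica$means
  # channels outside the retained PCA subspace are untouched only when
  # n_components == n_channels; residual is preserved explicitly:
  resid <- window$data - (ica$mixing %*% ica$sources + ica$means)
  window$data <- recon + resid
  rownames(window$data) <- window$channel_labels
  window
}

#' Mains-line amplitude in a narrow band
#'
#' Estimates the amplitude of mains interference as the sinusoid-equivalent
#' amplitude of the power in `[mains_hz - 1, mains_hz + 1]` Hz from a
#' rectangular-window DFT of the whole window (single-sided 2/N amplitude
#' normalization): `sqrt(sum of squared bin amplitudes)` per channel, then
#' the median across channels. A pure on-bin sine of amplitude A returns
#' exactly A.
#'
#' @param window A [preictal_window()] of at least 2 s.
#' @param mains_hz Mains frequency (default 50; set 60 for US recordings).
#' @return Median line amplitude across channels, in the window's units.
#' @export
line_noise_amplitude <- function(window, mains_hz = 50) {
  n <- ncol(window$data)
  fs <- window$fs
  if (n < 2 * fs) stopf("window must be at least 2 s for the line-noise metric")
  if (mains_hz + 1 >= fs / 2) {
    stopf("band [%g, %g] Hz outside Nyquist (%g Hz)", mains_hz - 1, mains_hz + 1, fs / 2)
  }
  X <- stats::mvfft(t(window$data))
  half <- seq_len(floor(n / 2) + 1L)
  f <- (half - 1) * fs / n
  bins <- half[f >= mains_hz - 1 & f <= mains_hz + 1]
  amp <- (2 / n) * Mod(X[bins, , drop = FALSE])
  stats::median(sqrt(colSums(amp^2)))
}

#' Blink events per 30 seconds
#'
#' Averages the frontal channels (labels beginning FP1/FP2), band-passes the
#' mean to 0.5-5 Hz, and counts events where its absolute value exceeds
#' `threshold_sigmas` times the MAD-based robust SD, requiring at least
#' `min_separation_s` between events. The count is normalized to a
#' per-30-second rate.
#'
#' @param window A [preictal_window()] containing frontal channels.
#' @param threshold_sigmas Detection threshold in robust SDs (default 4).
#' @param min_separation_s Minimum separation between events (default 0.5).
#' @return Blink rate per 30 s.
#' @export
blink_count <- function(window, threshold_sigmas = 4, min_separation_s = 0.5) {
  frontal <- frontal_channel_idx(window$channel_labels)
  if (!length(frontal)) stopf("no frontal (FP1/FP2) channels in window")
  fs <- window$fs
  m <- colMeans(window$data[frontal, , drop = FALSE])
  hp <- butter_hp(0.5, fs, 4)
  lp <- butter_lp(5, fs, 4)
  pad <- min(length(m) - 1L, as.integer(2 * fs))
  lowband <- filtfilt_pad(lp, filtfilt_pad(hp, m, pad), pad)
  robust_sd <- stats::mad(lowband)
  if (robust_sd == 0) return(0)
  # blinks are positive deflections of the frontal mean: one-sided test
  exceed <- which(lowband > threshold_sigmas * robust_sd)
  if (!length(exceed)) return(0)
  gaps <- diff(exceed)
  n_events <- 1L + sum(gaps > min_separation_s * fs)
  n_events * 30 / window_duration_s(window)
}

#' Preprocess one window and report artifact metrics
#'
#' Runs the cleaning cascade (per-channel z-score, zero-phase band-pass,
#' FastICA with automatic blink/line component flagging) and quantifies
#' line-noise amplitude and blink rate before and after. Post-clean line
#' amplitudes are re-expressed in microvolts via the stored z-score scale.
#' If the ICA fit fails to converge the fit is retried with derived seeds
#' (up to 3 attempts) before erroring.
#'
#' @param window A [preictal_window()] in microvolts.
#' @param zscore,bandpass_filter,ica Logical switches for the three stages.
#' @param low,high,order Band-pass parameters.
#' @param mains_hz Mains frequency for line metrics and flagging.
#' @param ica_seed,ica_max_iter,ica_tol FastICA controls.
#' @param blink_threshold_sigmas Blink detector threshold.
#' @param metrics Compute the artifact report (default TRUE); FALSE skips
#'   the pre/post measurements (the report holds NAs).
#' @return List with `window` (cleaned), `report` (one-row data frame with
#'   pre/post artifact metrics and percent reductions), and `flags` (flagged
#'   component indices).
#' @export
preprocess_window <- function(window, zscore = TRUE, bandpass_filter = TRUE,
                              ica = TRUE, low = 0.5, high = 45, order = 4,
                              mains_hz = 50, ica_seed = 1L,
                              ica_max_iter = 200L, ica_tol = 1e-4,
                              blink_threshold_sigmas = 4, metrics = TRUE) {
  has_frontal <- length(frontal_channel_idx(window$channel_labels)) > 0
  line_pre <- if (metrics) line_noise_amplitude(window, mains_hz) else NA_real_
  blink_pre <- if (metrics && has_frontal) {
    blink_count(window, blink_threshold_sigmas)
  } else NA_real_
  w <- window
  if (zscore) w <- zscore_normalize(w)
  if (bandpass_filter) w <- bandpass(w, low, high, order)
  flags <- list(blink = integer(0), line = integer(0))
  if (ica) {
    dec <- NULL
    for (attempt in 0:2) {
      seed_try <- if (attempt == 0) ica_seed else derive_seed(ica_seed, paste0("retry", attempt))
      dec <- tryCatch(fit_ica(w, seed = seed_try, max_iter = ica_max_iter,
                              tol = ica_tol),
                      error = function(e) e)
      if (!inherits(dec, "error")) break
      warnf("ICA attempt %d failed (%s); retrying with a derived seed",
            attempt + 1, conditionMessage(dec))
    }
    if (inherits(dec, "error")) stop(dec)
    flags <- flag_artifact_components(dec, w, mains_hz = mains_hz)
    w <- remove_components(dec, w, unique(c(flags$blink, flags$line)))
  }
  # express post-clean line metric in microvolts when the data were z-scored
  line_post <- NA_real_
  blink_post <- NA_real_
  if (metrics) {
    post_w <- w
    if (zscore) {
      sds <- w$zscore$sds
      post_w$data <- w$data * ifelse(sds == 0, 1, sds)
    }
    line_post <- line_noise_amplitude(post_w, mains_hz)
    blink_post <- if (has_frontal) blink_count(w, blink_threshold_sigmas) else NA_real_
  }
  report <- data.frame(
    window_id = window$window_id,
    line_noise_uv_pre = line_pre,
    line_noise_uv_post = line_post,
    delta_line_pct = percent_reduction(line_pre, line_post),
    blink_count_per_30s_pre = blink_pre,
    blink_count_per_30s_post = blink_post,
    delta_blink_pct = percent_reduction(blink_pre, blink_post),
    n_blink_components = length(flags$blink),
    n_line_components = length(flags$line),
    stringsAsFactors = FALSE)
  list(window = w, report = report, flags = flags)
}

#' Write artifact reports as TSV
#'
#' @param reports Data frame of rows from [preprocess_window()] reports.
#' @param path Output TSV path.
#' @return `reports`, invisibly.
#' @export
write_artifact_report <- function(reports, path) {
  write_tsv(reports, path)
  invisible(reports)
}
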