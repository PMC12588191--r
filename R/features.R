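# Multimodal per-channel feature extraction: 80 features per channel
# (8 time stats + 3 Hjorth + 18 spectral + 3 entropies + 48 wavelet),
# giving 1,440 dimensions for the default 18-channel montage.

pop_moments <- function(x) {
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  list(mu = mu, m2 = m2, m3 = mean(d^3), m4 = mean(d^4))
}

pop_skewness <- function(x) {
  m <- pop_moments(x)
  if (m$m2 == 0) return(0)
  m$m3 / m$m2^1.5
}

excess_kurtosis <- function(x) {
  m <- pop_moments(x)
  if (m$m2 == 0) return(0)
  m$m4 / m$m2^2 - 3
}

#' Feature-extraction configuration
#'
#' Declares the canonical per-channel feature layout. Band edges are the
#' conventional EEG rhythms; Welch uses 2-s Hamming windows with 50 %
#' overlap; entropies use common EEG defaults (sample entropy m = 2,
#' r = 0.2 SD; permutation entropy order 3, delay 1); wavelets use a
#' 5-level periodized db4 decomposition.
#'
#' @param fs Expected sampling rate (Hz).
#' @param n_channels Expected channel count (18 by default, 80 features
#'   each: 1,440 total).
#' @param bands Named list of band edges in Hz; half-open `[low, high)`
#'   intervals that must be strictly increasing and partition the total
#'   analysis band.
#' @param welch_window_s,welch_overlap Welch segmentation.
#' @param sampen_m,sampen_r_factor Sample-entropy template length and
#'   tolerance as a fraction of the channel SD.
#' @param perm_order,perm_delay Permutation-entropy ordinal pattern size.
#' @param hist_bins Equal-width bins for the histogram (Shannon) entropy.
#' @param wavelet_levels Decomposition depth of the db4 transform.
#' @return A `feature_config` list.
#' @export
feature_config <- function(fs = 256, n_channels = 18,
                           bands = list(delta = c(0.5, 4), theta = c(4, 8),
                                        alpha = c(8, 13), beta = c(13, 30),
                                        gamma = c(30, 45)),
                           welch_window_s = 2, welch_overlap = 0.5,
                           sampen_m = 2, sampen_r_factor = 0.2,
                           perm_order = 3, perm_delay = 1,
                           hist_bins = 10, wavelet_levels = 5) {
  edges <- unlist(bands)
  if (any(diff(unlist(lapply(bands, `[`, 1))) <= 0) ||
      any(vapply(bands, function(b) b[2] <= b[1], TRUE))) {
    stopf("band edges must be strictly increasing")
  }
  if (max(edges) >= fs / 2) stopf("band edges must lie below Nyquist (%g Hz)", fs / 2)
  structure(list(fs = fs, n_channels = n_channels, bands = bands,
                 welch_window_s = welch_window_s, welch_overlap = welch_overlap,
                 sampen_m = sampen_m, sampen_r_factor = sampen_r_factor,
                 perm_order = perm_order, perm_delay = perm_delay,
                 hist_bins = hist_bins, wavelet_levels = wavelet_levels),
            class = "feature_config")
}

#' Time-domain statistics of a single-channel segment
#'
#' @param x Numeric vector (length >= 2).
#' @return Named vector: mean, population variance, Fisher skewness, excess
#'   kurtosis, RMS, peak-to-peak, zero-crossing rate (sign changes over
#'   n - 1), and line length (mean absolute first difference). Skewness and
#'   kurtosis of a constant signal are defined as 0.
#' @export
time_stats <- function(x) {
  if (length(x) < 2) stopf("time_stats needs at least 2 samples")
  m <- pop_moments(x)
  s <- sign(x)
  c(mean = m$mu,
    variance = m$m2,
    skewness = if (m$m2 == 0) 0 else m$m3 / m$m2^1.5,
    kurtosis = if (m$m2 == 0) 0 else m$m4 / m$m2^2 - 3,
    rms = sqrt(mean(x^2)),
    ptp = max(x) - min(x),
    zcr = mean(s[-1] != s[-length(s)]),
    line_length = mean(abs(diff(x))))
}

#' Hjorth parameters
#'
#' @param x Numeric vector (length >= 3).
#' @return Named vector `activity` (variance), `mobility`
#'   (sqrt(var(diff(x)) / var(x))) and `complexity`
#'   (mobility(diff(x)) / mobility(x)); all 0 for a constant signal.
#' @export
hjorth <- function(x) {
  if (length(x) < 3) stopf("hjorth needs at least 3 samples")
  v0 <- mean((x - mean(x))^2)
  if (v0 == 0) {
    return(c(hjorth_activity = 0, hjorth_mobility = 0, hjorth_complexity = 0))
  }
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- mean((d1 - mean(d1))^2)
  v2 <- mean((d2 - mean(d2))^2)
  mob <- sqrt(v1 / v0)
  comp <- if (v1 == 0) 0 else sqrt(v2 / v1) / mob
  c(hjorth_activity = v0, hjorth_mobility = mob, hjorth_complexity = comp)
}

welch_plan <- function(n, config) {
  fs <- config$fs
  nperseg <- round(config$welch_window_s * fs)
  if (n < nperseg) stopf("segment (%d samples) shorter than one Welch window (%d)", n, nperseg)
  step <- max(1L, round(nperseg * (1 - config$welch_overlap)))
  starts <- seq(0L, n - nperseg, by = step)
  idx <- outer(seq_len(nperseg), starts, `+`)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1))  # Hamming
  half <- seq_len(floor(nperseg / 2) + 1L)
  f <- (half - 1) * fs / nperseg
  scale <- 1 / (fs * sum(w^2))
  band_masks <- lapply(config$bands, function(b) f >= b[1] & f < b[2])
  total_mask <- Reduce(`|`, band_masks)
  list(idx = idx, w = w, half = half, f = f, scale = scale,
       band_masks = band_masks, total_mask = total_mask, df = fs / nperseg)
}

welch_psd_channel <- function(x, plan) {
  seg <- matrix(x[plan$idx], nrow = nrow(plan$idx)) * plan$w
  P <- Mod(stats::mvfft(seg))^2
  psd <- rowMeans(P)[plan$half] * plan$scale
  np <- length(plan$w)
  mid <- if (np %% 2 == 0) 2:(length(plan$half) - 1) else 2:length(plan$half)
  psd[mid] <- 2 * psd[mid]                       # one-sided
  psd
}

#' Welch power spectral density
#'
#' Averaged periodogram over Hamming-tapered overlapping windows.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param window_s Window length in seconds (default 2).
#' @param overlap Fractional overlap (default 0.5).
#' @return List with `freq` (Hz) and `psd` (power per Hz, one-sided).
#' @export
welch_psd <- function(x, fs, window_s = 2, overlap = 0.5) {
  cfg <- feature_config(fs = fs, welch_window_s = window_s,
                        welch_overlap = overlap)
  plan <- welch_plan(length(x), cfg)
  list(freq = plan$f, psd = welch_psd_channel(x, plan))
}

# One-sided Welch PSDs for all channels of a segment at once
# (one mvfft over every channel's tapered windows).
welch_psd_matrix <- function(data, plan) {
  np <- nrow(plan$idx); nwin <- ncol(plan$idx); nch <- nrow(data)
  M <- matrix(0, np, nwin * nch)
  for (ch in seq_len(nch)) {
    M[, seq((ch - 1) * nwin + 1, ch * nwin)] <- data[ch, ][plan$idx]
  }
  P <- Mod(stats::mvfft(M * plan$w))^2
  psd <- vapply(seq_len(nch), function(ch) {
    rowMeans(P[plan$half, seq((ch - 1) * nwin + 1, ch * nwin), drop = FALSE])
  }, numeric(length(plan$half))) * plan$scale
  mid <- if (np %% 2 == 0) 2:(length(plan$half) - 1) else 2:length(plan$half)
  psd[mid, ] <- 2 * psd[mid, ]
  psd                                             # bins x channels
}

spectral_from_psd <- function(psd, plan) {
  abs_p <- vapply(plan$band_masks, function(m) sum(psd[m]) * plan$df, 0)
  total <- sum(abs_p)
  names(abs_p) <- paste0("bp_abs_", names(plan$band_masks))
  if (total == 0) {
    rel <- abs_p                                  # zeros
    names(rel) <- paste0("bp_rel_", names(plan$band_masks))
    out <- c(abs_p, rel, total_power = 0, spectral_entropy = 0, edge95 = 0,
             peak_freq = 0, median_freq = 0,
             ratio_theta_alpha = 0, ratio_delta_beta = 0, ratio_slow_fast = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  rel <- abs_p / total
  names(rel) <- paste0("bp_rel_", names(plan$band_masks))
  pin <- psd[plan$total_mask]
  f_in <- plan$f[plan$total_mask]
  p_norm <- pin / sum(pin)
  nz <- p_norm > 0
  spec_ent <- -sum(p_norm[nz] * log(p_norm[nz])) / log(length(p_norm))
  cum <- cumsum(pin) / sum(pin)
  edge95 <- f_in[which(cum >= 0.95)[1]]
  median_freq <- f_in[which(cum >= 0.5)[1]]
  peak_freq <- f_in[which.max(pin)]
  ratio <- function(num, den) if (den == 0) 0 else num / den
  out <- c(abs_p, rel, total_power = total, spectral_entropy = spec_ent,
           edge95 = edge95, peak_freq = peak_freq, median_freq = median_freq,
           ratio_theta_alpha = ratio(abs_p[["bp_abs_theta"]], abs_p[["bp_abs_alpha"]]),
           ratio_delta_beta = ratio(abs_p[["bp_abs_delta"]], abs_p[["bp_abs_beta"]]),
           ratio_slow_fast = ratio(abs_p[["bp_abs_delta"]] + abs_p[["bp_abs_theta"]],
                                   abs_p[["bp_abs_alpha"]] + abs_p[["bp_abs_beta"]]))
  out
}

#' Band powers and spectral summaries of a single channel
#'
#' Welch-PSD-derived descriptors: absolute and relative power in the five
#' canonical bands, total power, normalized spectral entropy, 95 % spectral
#' edge, peak and median frequency, and three slow/fast power ratios.
#'
#' @param x Numeric vector.
#' @param config A [feature_config()] (supplies fs, bands, Welch layout).
#' @return Named vector of 18 values.
#' @export
band_powers <- function(x, config = feature_config()) {
  band_powers_channel(x, welch_plan(length(x), config))
}

band_powers_channel <- function(x, plan) {
  spectral_from_psd(welch_psd_channel(x, plan), plan)
}

#' Sample entropy
#'
#' Negative log conditional probability that templates matching for `m`
#' points (Chebyshev distance <= r, self-matches excluded) still match at
#' `m + 1`. Returns 0 (with a `degenerate` attribute) when either match
#' count is zero.
#'
#' @param x Numeric vector (length >= 10).
#' @param m Template length (default 2).
#' @param r Tolerance; defaults to 0.2 times the population SD of `x`.
#' @return Sample entropy value.
#' @export
sample_entropy <- function(x, m = 2, r = NULL) {
  if (length(x) < 10) stopf("sample_entropy needs at least 10 samples")
  if (is.null(r)) r <- 0.2 * sqrt(mean((x - mean(x))^2))
  counts <- sampen_counts_cpp(as.numeric(x), as.integer(m), r)
  B <- counts[1]; A <- counts[2]
  if (A == 0 || B == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  -log(A / B)
}

#' Permutation entropy
#'
#' Shannon entropy of the ordinal-pattern distribution, normalized by
#' log(order!) to lie in [0, 1]. Ties are broken by first occurrence.
#'
#' @param x Numeric vector (length >= order * delay + 1).
#' @param order Pattern length (default 3).
#' @param delay Lag between pattern elements (default 1).
#' @return Normalized permutation entropy in [0, 1].
#' @export
permutation_entropy <- function(x, order = 3, delay = 1) {
  if (length(x) < order * delay + 1) {
    stopf("permutation_entropy needs at least order * delay + 1 samples")
  }
  counts <- perm_pattern_counts_cpp(as.numeric(x), as.integer(order),
                                    as.integer(delay))
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p)) / log(factorial(order))
}

#' Histogram (Shannon) entropy
#'
#' Shannon entropy of the sample distribution over equal-width amplitude
#' bins, normalized by log(bins). A constant signal returns 0.
#'
#' @param x Numeric vector.
#' @param bins Number of equal-width bins (default 10).
#' @return Normalized histogram entropy in [0, 1].
#' @export
hist_entropy <- function(x, bins = 10) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  cuts <- pmin(pmax(floor((x - rng[1]) / (rng[2] - rng[1]) * bins) + 1, 1), bins)
  p <- tabulate(cuts, bins)
  p <- p[p > 0] / length(x)
  -sum(p * log(p)) / log(bins)
}

#' Wavelet subband descriptors
#'
#' 5-level periodized db4 decomposition into six coefficient sets
#' (cA5, cD5, ..., cD1); for each set: mean, population SD, mean absolute
#' coefficient, energy, relative energy, maximum absolute coefficient,
#' skewness and excess kurtosis (0 for degenerate sets).
#'
#' @param x Numeric vector; length must be divisible by `2^levels`.
#' @param levels Decomposition depth (default 5).
#' @return Named vector of `8 * (levels + 1)` values (48 at the default).
#' @export
wavelet_features <- function(x, levels = 5) {
  coefs <- dwt_db4_per_cpp(as.numeric(x), as.integer(levels))
  set_names <- c(paste0("cA", levels), paste0("cD", seq(levels, 1)))
  energies <- vapply(coefs, function(cc) sum(cc^2), 0)
  total <- sum(energies)
  out <- numeric(0)
  for (i in seq_along(coefs)) {
    cc <- coefs[[i]]
    m <- pop_moments(cc)
    vals <- c(m$mu, sqrt(m$m2), mean(abs(cc)), energies[i],
              if (total == 0) 0 else energies[i] / total, max(abs(cc)),
              if (m$m2 == 0) 0 else m$m3 / m$m2^1.5,
              if (m$m2 == 0) 0 else m$m4 / m$m2^2 - 3)
    names(vals) <- paste0("wl_", set_names[i], "_",
                          c("mean", "sd", "mean_abs", "energy", "rel_energy",
                            "max_abs", "skewness", "kurtosis"))
    out <- c(out, vals)
  }
  out
}

channel_feature_names <- function(config = feature_config()) {
  c("mean", "variance", "skewness", "kurtosis", "rms", "ptp", "zcr", "line_length",
    "hjorth_activity", "hjorth_mobility", "hjorth_complexity",
    paste0("bp_abs_", names(config$bands)), paste0("bp_rel_", names(config$bands)),
    "total_power", "spectral_entropy", "edge95", "peak_freq", "median_freq",
    "ratio_theta_alpha", "ratio_delta_beta", "ratio_slow_fast",
    "sampen", "perm_entropy", "hist_entropy",
    as.vector(outer(c("mean", "sd", "mean_abs", "energy", "rel_energy",
                      "max_abs", "skewness", "kurtosis"),
                    c(paste0("cA", config$wavelet_levels),
                      paste0("cD", seq(config$wavelet_levels, 1))),
                    function(s, l) paste0("wl_", l, "_", s))))
}

extract_channel_features <- function(x, config, plan) {
  c(time_stats(x),
    hjorth(x),
    band_powers_channel(x, plan),
    sampen = as.numeric(sample_entropy(x, config$sampen_m,
                                       config$sampen_r_factor *
                                         sqrt(mean((x - mean(x))^2)))),
    perm_entropy = permutation_entropy(x, config$perm_order, config$perm_delay),
    hist_entropy = hist_entropy(x, config$hist_bins),
    wavelet_features(x, config$wavelet_levels))
}

#' Extract the multimodal feature vector of one segment
#'
#' Computes 80 named features per channel (time stats, Hjorth, band powers
#' and spectral summaries, entropies, wavelet descriptors), concatenated
#' channel-by-channel: 1,440 dimensions for the default 18-channel montage.
#' Names are `"<channel>__<feature>"`. Deterministic, and finite for any
#' finite input (degenerate channels follow the documented zero rules and
#' are reported in the `degenerate_channels` attribute).
#'
#' @param segment An `eeg_segment` (or any object with `data`, `fs`,
#'   `channel_labels`).
#' @param config A [feature_config()]; its fs and channel count must match
#'   the segment.
#' @return Named numeric vector of `80 * n_channels` features.
#' @export
extract_features <- function(segment, config = feature_config()) {
  if (segment$fs != config$fs) {
    stopf("segment fs (%g) does not match config fs (%g)", segment$fs, config$fs)
  }
  if (nrow(segment$data) != config$n_channels) {
    stopf("segment has %d channels but config expects %d",
          nrow(segment$data), config$n_channels)
  }
  plan <- welch_plan(ncol(segment$data), config)
  fnames <- channel_feature_names(config)
  nch <- nrow(segment$data)
  # batched kernel for the non-spectral features; the vectorized Welch stage
  # covers the spectral block. Values agree exactly with the per-channel
  # operations (time_stats, hjorth, band_powers, ...).
  core <- segment_features_cpp(t(segment$data), config$sampen_m,
                               config$sampen_r_factor, config$perm_order,
                               config$perm_delay, config$hist_bins,
                               config$wavelet_levels)
  psd <- welch_psd_matrix(segment$data, plan)
  out <- matrix(0, length(fnames), nch)
  for (ch in seq_len(nch)) {
    spec <- spectral_from_psd(psd[, ch], plan)
    out[, ch] <- c(core[1:11, ch], spec, core[12:nrow(core), ch])
  }
  if (any(!is.finite(out))) out[!is.finite(out)] <- 0
  degenerate <- segment$channel_labels[
    apply(segment$data, 1, function(r) all(r == r[1]))]
  out <- as.vector(out)
  names(out) <- as.vector(vapply(segment$channel_labels,
                                 function(lab) paste0(lab, "__", fnames),
                                 character(length(fnames))))
  if (length(degenerate)) attr(out, "degenerate_channels") <- degenerate
  out
}

#' Extract the feature matrix of a segment set
#'
#' @param segments A `segment_set` from [segment_dataset()] or a plain list
#'   of segments.
#' @param config A [feature_config()].
#' @return A `feature_matrix`: list with `values` (n_segments x n_features),
#'   `feature_names`, `meta` (subject_id, window_id, segment_index per row)
#'   and `config`.
#' @export
extract_feature_matrix <- function(segments, config = feature_config()) {
  segs <- if (inherits(segments, "segment_set")) segments$segments else segments
  if (!length(segs)) stopf("no segments")
  vals <- matrix(0, nrow = length(segs),
                 ncol = 80L * config$n_channels)
  first <- extract_features(segs[[1]], config)
  colnames(vals) <- names(first)
  vals[1, ] <- first
  if (length(segs) > 1) {
    for (i in 2:length(segs)) vals[i, ] <- extract_features(segs[[i]], config)
  }
  meta <- do.call(rbind, lapply(segs, function(s) {
    data.frame(subject_id = s$subject_id, window_id = s$window_id,
               segment_index = s$segment_index, stringsAsFactors = FALSE)
  }))
  structure(list(values = vals, feature_names = colnames(vals), meta = meta,
                 config = config),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d segments x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write a feature matrix as TSV with a JSON sidecar
#'
#' @param fm A `feature_matrix`.
#' @param path Output TSV path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- cbind(fm$meta, as.data.frame(fm$values, check.names = FALSE))
  write_tsv(df, path)
  write_json_sidecar(list(n_segments = nrow(fm$values),
                          n_features = ncol(fm$values),
                          fs = fm$config$fs,
                          n_channels = fm$config$n_channels),
                     paste0(path, ".json"))
  invisible(path)
}
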