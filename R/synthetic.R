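# Synthetic pediatric-EEG generator: latent spectral states switching at
# segment boundaries under a Markov chain, shared band-limited sources with
# channel-specific gains (inter-channel correlation), 1/f background,
# blink templates on frontal channels, and additive mains-frequency noise.
# Everything is driven by one seeded RNG and returns ground truth.

#' Default synthetic-cohort specification
#'
#' Four latent states with distinct band profiles (alpha-dominant,
#' theta-dominant, delta+theta-dominant, beta/gamma-dominant), a structured
#' Markov chain (self-transition 0.5, elevated transitions into the
#' delta+theta state, suppressed escape from the fast state back to the
#' alpha state), and artifact regimes at the pre-clean levels used
#' throughout the package: 3.4 blinks per 30 s and 2.6 uV of mains noise.
#'
#' @param seed Integer seed recorded in the spec and used by the
#'   generators.
#' @return A `synthetic_spec` list.
#' @export
default_spec <- function(seed = 42L) {
  band_weights <- rbind(
    alpha_dom = c(0.08, 0.08, 0.70, 0.09, 0.05),
    theta_dom = c(0.10, 0.70, 0.08, 0.08, 0.04),
    slow_dom  = c(0.60, 0.25, 0.06, 0.06, 0.03),
    fast_dom  = c(0.08, 0.08, 0.09, 0.45, 0.30))
  colnames(band_weights) <- c("delta", "theta", "alpha", "beta", "gamma")
  markov <- rbind(c(0.50, 0.10, 0.30, 0.10),
                  c(0.10, 0.50, 0.30, 0.10),
                  c(0.50 / 3, 0.50 / 3, 0.50, 0.50 / 3),
                  c(0.02, 0.24, 0.24, 0.50))
  structure(list(
    n_states = 4L, n_channels = 18L, fs = 256,
    window_s = 30, seg_len_s = 5,
    channel_labels = default_montage(),
    state_band_weights = band_weights,
    markov = markov,
    state_amplitude_uv = 25,
    background_uv = 18,
    background_1f_exponent = 1,
    envelope_log_sd = 0.2,          # lognormal amplitude modulation (super-Gaussian signals)
    envelope_max_hz = 2,
    blink_rate_per_30s = 3.4,
    blink_amplitude_uv = 120,
    blink_width_s = 0.3,
    line_freq_hz = 50,
    line_amplitude_uv = 2.6,
    gain_jitter = 0.15,
    window_gain_jitter = 0.05,
    seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %d states, %d ch @ %g Hz, blink %.1f/30s, line %.1f uV @ %g Hz (seed %d)\n",
              x$n_states, x$n_channels, x$fs, x$blink_rate_per_30s,
              x$line_amplitude_uv, x$line_freq_hz, x$seed))
  invisible(x)
}

# Band-limited noise by spectral synthesis: white Gaussian spectrum masked
# to [low, high) Hz (zero power outside), optional 1/f^alpha shaping,
# normalized to unit population SD.
spectral_noise <- function(n, fs, low, high, alpha = 0) {
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)                    # two-sided |frequency|
  mask <- f >= low & f < high
  shape <- numeric(n)
  shape[mask] <- if (alpha == 0) 1 else 1 / pmax(f[mask], low)^(alpha / 2)
  x <- Re(stats::fft(Z * shape, inverse = TRUE)) / n
  s <- sqrt(mean(x^2))
  if (s == 0) return(x)
  x / s
}

# Lognormal amplitude envelope (slow, band-limited) with E[envelope^2] = 1.
amplitude_envelope <- function(n, fs, log_sd, max_hz = 2) {
  if (log_sd <= 0) return(rep(1, n))
  z <- spectral_noise(n, fs, 0, max_hz, alpha = 0)
  exp(log_sd * z - log_sd^2)
}

markov_stationary <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

sample_markov_chain <- function(P, n, init = NULL) {
  k <- nrow(P)
  if (is.null(init)) init <- markov_stationary(P)
  s <- integer(n)
  s[1] <- sample.int(k, 1, prob = init)
  for (i in seq_len(n - 1)) s[i + 1] <- sample.int(k, 1, prob = P[s[i], ])
  s
}

# Blink onset times: Poisson count, uniform placement with a 1-s refractory
# separation (rejection sampling) so events remain individually detectable.
sample_blink_times <- function(rate_per_30s, duration_s) {
  n <- stats::rpois(1, rate_per_30s * duration_s / 30)
  n <- min(n, floor(duration_s / 2))
  if (n == 0) return(numeric(0))
  lo <- 0.4; hi <- duration_s - 0.4
  for (try in 1:200) {
    t0 <- sort(stats::runif(n, lo, hi))
    if (n == 1 || min(diff(t0)) >= 1.0) return(t0)
  }
  t0                                       # extremely unlikely fallback
}

blink_template <- function(width_s, fs) {
  n <- round(width_s * fs)
  0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
}

draw_channel_gains <- function(spec) {
  nc <- spec$n_channels
  nb <- ncol(spec$state_band_weights)
  signs <- matrix(sample(c(-1, 1), nc * nb, replace = TRUE), nc, nb)
  g <- signs * (1 + spec$gain_jitter * matrix(stats::rnorm(nc * nb), nc, nb))
  # bipolar frontal derivations of the shared (posterior-dominant) rhythms
  # carry near-cancelling gradients: balance their gains so the frontal mean
  # reflects background and ocular activity, as on a real double-banana
  # montage, rather than the rhythmic sources
  frontal <- frontal_channel_idx(spec$channel_labels)
  if (length(frontal) > 1) {
    g[frontal, ] <- g[frontal, ] -
      matrix(colMeans(g[frontal, , drop = FALSE]), length(frontal), nb,
             byrow = TRUE)
  }
  g
}

#' Generate one synthetic pre-ictal window with ground truth
#'
#' Each 5-s segment is produced in one latent state sampled from the spec's
#' Markov chain (states change only at segment boundaries). Channel signals
#' mix shared band-limited sources with channel-specific gains, plus 1/f
#' background, blink templates on the frontal channels, and a mains-frequency
#' sinusoid. Uses the current RNG state unless `seed` is given.
#'
#' @param spec A `synthetic_spec` from [default_spec()].
#' @param subject_id,seizure_index Provenance fields for the window.
#' @param gains Optional channels x bands gain matrix (drawn fresh when
#'   `NULL`); used by [generate_dataset()] for per-subject structure.
#' @param seed Optional integer seed for a self-contained draw.
#' @return List with `window` (a [preictal_window()] in microvolts) and
#'   `truth` (per-segment states, blink times, planted line amplitude).
#' @export
generate_window <- function(spec, subject_id = "sim", seizure_index = 1L,
                            gains = NULL, seed = NULL) {
  if (!is.null(seed)) {
    return(with_seed(seed, generate_window(spec, subject_id, seizure_index, gains)))
  }
  fs <- spec$fs
  n <- round(spec$window_s * fs)
  n_seg <- floor(spec$window_s / spec$seg_len_s)
  spseg <- round(spec$seg_len_s * fs)
  nc <- spec$n_channels
  bands <- list(c(0.5, 4), c(4, 8), c(8, 13), c(13, 30), c(30, 45))
  nb <- length(bands)
  if (is.null(gains)) gains <- draw_channel_gains(spec)

  states <- sample_markov_chain(spec$markov, n_seg)
  # per-sample sqrt band weight, stepping at segment boundaries; a short
  # raised-cosine crossfade (~0.1 s) smooths the steps so the switches do
  # not leak broadband energy into the spectrum
  wseg <- sqrt(spec$state_band_weights[states, , drop = FALSE])  # n_seg x nb
  wsamp <- wseg[rep(seq_len(n_seg), each = spseg), , drop = FALSE]
  if (n_seg > 1) {
    # band-limit the weight tracks to <= 4 Hz (spectral mask, as for the
    # sources) so modulation cannot spill past the 45 Hz band edge; clamp
    # the negligible Gibbs undershoot
    f <- seq(0, n - 1) * fs / n
    keep <- pmin(f, fs - f) <= 4
    wsamp <- apply(wsamp, 2, function(col) {
      sm <- Re(stats::fft(stats::fft(col) * keep, inverse = TRUE)) / n
      pmax(sm, 0)
    })
  }

  sources <- vapply(seq_len(nb), function(b) {
    spectral_noise(n, fs, bands[[b]][1], bands[[b]][2])
  }, numeric(n))
  weighted <- sources * wsamp                                   # n x nb

  # one shared amplitude envelope for the whole state component: waxing and
  # waning rhythms (super-Gaussian marginals, needed for ICA) without
  # disturbing the relative band-power profile of a segment
  env_state <- amplitude_envelope(n, fs, spec$envelope_log_sd, spec$envelope_max_hz)
  data <- spec$state_amplitude_uv *
    tcrossprod(gains, weighted * env_state)                     # nc x n

  env_bg <- amplitude_envelope(n, fs, spec$envelope_log_sd, spec$envelope_max_hz)
  for (ch in seq_len(nc)) {
    bg <- spectral_noise(n, fs, 0.5, 45, alpha = spec$background_1f_exponent) * env_bg
    bg <- bg / sqrt(mean(bg^2))
    data[ch, ] <- data[ch, ] + spec$background_uv * bg
  }

  if (spec$line_amplitude_uv > 0) {
    tt <- seq(0, n - 1) / fs
    phase <- stats::runif(1, 0, 2 * pi)      # mains couples in a common phase
    line <- spec$line_amplitude_uv * sin(2 * pi * spec$line_freq_hz * tt + phase)
    data <- data + matrix(line, nc, n, byrow = TRUE)
  }

  blink_times <- if (spec$blink_rate_per_30s > 0) {
    sample_blink_times(spec$blink_rate_per_30s, spec$window_s)
  } else numeric(0)
  if (length(blink_times)) {
    tmpl <- blink_template(spec$blink_width_s, fs)
    frontal <- frontal_channel_idx(spec$channel_labels)
    for (t0 in blink_times) {
      i0 <- round(t0 * fs)
      idx <- seq(i0 + 1, min(i0 + length(tmpl), n))
      for (ch in frontal) {
        data[ch, idx] <- data[ch, idx] + spec$blink_amplitude_uv * tmpl[seq_along(idx)]
      }
    }
  }

  window <- preictal_window(data, fs = fs, channel_labels = spec$channel_labels,
                            subject_id = subject_id,
                            seizure_index = seizure_index,
                            start_s = 0, end_s = spec$window_s,
                            window_id = sprintf("%s_w%02d", subject_id, seizure_index))
  truth <- list(states = states, blink_times = blink_times,
                blink_count = length(blink_times),
                line_amplitude_uv = spec$line_amplitude_uv)
  list(window = window, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject channel gains (inter-subject variability) with a small
#' per-window jitter, then generates `windows_per_subject` windows per
#' subject. Fully reproducible from `spec$seed`.
#'
#' @param spec A `synthetic_spec`.
#' @param n_subjects Number of subjects (default 12).
#' @param windows_per_subject Windows per subject (default 8; the defaults
#'   give the 96-window / 576-segment cohort shape).
#' @return A `synthetic_dataset`: list with `windows`, `truths`, `manifest`
#'   (data frame) and `spec`.
#' @export
generate_dataset <- function(spec, n_subjects = 12L, windows_per_subject = 8L) {
  if (n_subjects < 1 || windows_per_subject < 1) stopf("counts must be >= 1")
  with_seed(spec$seed, {
    windows <- list()
    truths <- list()
    for (s in seq_len(n_subjects)) {
      subject_id <- sprintf("S%02d", s)
      base_gains <- draw_channel_gains(spec)
      for (w in seq_len(windows_per_subject)) {
        gains <- base_gains * (1 + spec$window_gain_jitter *
                                 matrix(stats::rnorm(length(base_gains)),
                                        nrow(base_gains)))
        gw <- generate_window(spec, subject_id, w, gains = gains)
        windows[[length(windows) + 1L]] <- gw$window
        truths[[length(truths) + 1L]] <- gw$truth
      }
    }
    manifest <- do.call(rbind, lapply(windows, function(w) {
      data.frame(subject_id = w$subject_id, window_id = w$window_id,
                 seizure_index = w$seizure_index, start_s = w$start_s,
                 end_s = w$end_s, n_samples = ncol(w$data),
                 stringsAsFactors = FALSE)
    }))
    structure(list(windows = windows, truths = truths, manifest = manifest,
                   spec = spec),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d windows across %d subjects (seed %d)\n",
              length(x$windows), length(unique(x$manifest$subject_id)),
              x$spec$seed))
  invisible(x)
}

#' Write ground-truth state assignments as TSV
#'
#' @param dataset A `synthetic_dataset`.
#' @param path Output TSV path.
#' @return The truth data frame, invisibly.
#' @export
write_truth <- function(dataset, path) {
  df <- do.call(rbind, lapply(seq_along(dataset$windows), function(i) {
    data.frame(window_id = dataset$windows[[i]]$window_id,
               segment_index = seq_along(dataset$truths[[i]]$states) - 1L,
               state = dataset$truths[[i]]$states,
               stringsAsFactors = FALSE)
  }))
  write_tsv(df, path)
  invisible(df)
}
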