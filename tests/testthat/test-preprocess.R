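test_that("z-scoring yields per-channel mean 0 and population SD 1", {
  w <- toy_window(c(1, 2, 3), fs = 1)
  z <- zscore_normalize(w)
  expect_equal(as.vector(z$data), c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  set.seed(4)
  w2 <- preictal_window(matrix(rnorm(3 * 512, mean = 5, sd = 12), 3),
                        fs = 256, channel_labels = c("A", "B", "C"),
                        subject_id = "S")
  z2 <- zscore_normalize(w2)
  expect_true(all(abs(rowMeans(z2$data)) < 1e-10))
  expect_true(all(abs(sqrt(rowMeans(z2$data^2)) - 1) < 1e-8))
})

test_that("constant channels are zeroed and flagged instead of NaN", {
  w <- preictal_window(rbind(rep(5, 512), rnorm(512)), fs = 256,
                       channel_labels = c("FLAT", "OK"), subject_id = "S")
  expect_warning(z <- zscore_normalize(w), "FLAT")
  expect_equal(unname(z$data[1, ]), rep(0, 512))
  expect_equal(unname(z$zscore$flagged), 1L)
})

test_that("band-pass has ~unit passband gain and attenuates DC and 60 Hz", {
  fs <- 256
  tt <- seq(0, 30, length.out = 30 * fs + 1)[-1]
  rms <- function(x) sqrt(mean(x^2))
  sine10 <- toy_window(sin(2 * pi * 10 * tt))
  out10 <- bandpass(sine10)
  # oracle: squared Butterworth magnitude response of the HP/LP cascade
  gain <- function(f, low = 0.5, high = 45, ord = 4) {
    (1 / (1 + (low / f)^(2 * ord))) * (1 / (1 + (f / high)^(2 * ord)))
  }
  expect_equal(rms(out10$data) / rms(sine10$data), gain(10), tolerance = 0.02)
  expect_gt(rms(out10$data) / rms(sine10$data), 0.98)

  dc <- toy_window(rep(1, 30 * fs))
  expect_lt(rms(bandpass(dc)$data), 0.01)

  sine60 <- toy_window(sin(2 * pi * 60 * tt))
  r60 <- rms(bandpass(sine60)$data) / rms(sine60$data)
  expect_lt(r60, 0.20)
  expect_equal(r60, gain(60), tolerance = 0.1)

  expect_error(bandpass(sine10, high = 130), "Nyquist")
  expect_error(bandpass(sine10, low = 50, high = 45), "low < high")
})

test_that("band-pass filtering is linear", {
  set.seed(5)
  fs <- 256
  x <- rnorm(5 * fs); y <- rnorm(5 * fs)
  f <- function(v) as.vector(bandpass(toy_window(v))$data)
  expect_equal(f(2 * x + 3 * y), 2 * f(x) + 3 * f(y), tolerance = 1e-8)
})

test_that("FastICA separates planted independent sources", {
  set.seed(6)
  n <- 2048
  s1 <- runif(n, -1, 1)                      # sub-Gaussian
  s2 <- sign(rnorm(n)) * rexp(n)             # super-Gaussian
  A <- matrix(c(1, 0.4, 0.6, 1), 2)
  X <- A %*% rbind(s1, s2)
  w <- preictal_window(X, fs = 256, channel_labels = c("C1", "C2"),
                       subject_id = "S")
  dec <- fit_ica(w, seed = 1)
  expect_equal(unname(apply(dec$sources, 1, var)) * (n - 1) / n, c(1, 1),
               tolerance = 1e-6)
  cors <- abs(cor(t(dec$sources), cbind(s1, s2)))
  expect_true(all(apply(cors, 2, max) > 0.95))
  # mixing %*% unmixing is the identity on the retained (full) subspace
  expect_equal(dec$mixing %*% dec$unmixing, diag(2), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(fit_ica(w, n_components = 3), "exceeds")
})

test_that("ICA non-convergence raises an error carrying the iteration count", {
  set.seed(7)
  w <- preictal_window(matrix(rnorm(2 * 1024), 2), fs = 256,
                       channel_labels = c("C1", "C2"), subject_id = "S")
  err <- tryCatch(fit_ica(w, seed = 1, max_iter = 3L, tol = 1e-14),
                  error = function(e) e)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "did not converge")
  expect_equal(err$iterations, 3L)
})

test_that("planted blink and line components are flagged; nulls are not", {
  spec <- default_spec(42)
  spec$line_amplitude_uv <- 15          # clearly visible planted line source
  gw <- generate_window(spec, seed = 11)
  w <- bandpass(zscore_normalize(gw$window), high = 120)  # keep 50 Hz for the line flag
  dec <- fit_ica(w, seed = 3, tol = 1e-3)
  flags <- flag_artifact_components(dec, w)
  expect_gte(length(flags$blink), 1)
  expect_gte(length(flags$line), 1)
  # determinism: same seed, same flags
  dec2 <- fit_ica(w, seed = 3, tol = 1e-3)
  expect_identical(flags, flag_artifact_components(dec2, w))

  # artifact-free white-noise window: both sets empty
  set.seed(8)
  wn <- preictal_window(matrix(runif(18 * 2560, -1, 1), 18), fs = 256,
                        channel_labels = default_montage(), subject_id = "S")
  decn <- fit_ica(wn, seed = 2, tol = 1e-2, max_iter = 500)
  flagsn <- flag_artifact_components(decn, wn)
  expect_length(flagsn$blink, 0)
  expect_length(flagsn$line, 0)
})

test_that("remove_components is the identity for an empty set and cleans line noise", {
  gw <- fixture_window()
  w <- zscore_normalize(gw$window)
  dec <- fit_ica(w, seed = 5, tol = 1e-3)
  same <- remove_components(dec, w, integer(0))
  expect_equal(same$data, w$data, tolerance = 1e-8)
  all_removed <- remove_components(dec, w, seq_len(dec$n_components))
  expect_lt(max(abs(all_removed$data)), 1e-6)   # z-scored means are ~0
  expect_error(remove_components(dec, w, 99), "out of range")

  # removing the flagged line component halves the line amplitude
  spec15 <- default_spec(42); spec15$line_amplitude_uv <- 15
  gw15 <- generate_window(spec15, seed = 12)
  wb <- bandpass(zscore_normalize(gw15$window), high = 120)
  decb <- fit_ica(wb, seed = 5, tol = 1e-3)
  flags <- flag_artifact_components(decb, wb)
  pre <- line_noise_amplitude(wb)
  post <- line_noise_amplitude(remove_components(decb, wb, flags$line))
  expect_lt(post, 0.5 * pre)
})

test_that("line-noise amplitude matches a direct DFT oracle", {
  fs <- 256
  tt <- seq(0, 30, length.out = 30 * fs + 1)[-1]
  zero <- preictal_window(matrix(0, 2, length(tt)), fs = fs,
                          channel_labels = c("A", "B"), subject_id = "S")
  expect_equal(line_noise_amplitude(zero), 0)

  A <- 3.7
  sine <- preictal_window(rbind(A * sin(2 * pi * 50 * tt),
                                A * sin(2 * pi * 50 * tt + 1)),
                          fs = fs, channel_labels = c("A", "B"),
                          subject_id = "S")
  # 50 Hz falls exactly on a DFT bin of the 30-s window: bin-spread factor 1
  expect_equal(line_noise_amplitude(sine), A, tolerance = 1e-6)
  expect_error(line_noise_amplitude(sine, mains_hz = 127.5), "Nyquist")
  short <- preictal_window(matrix(0, 1, fs), fs = fs, channel_labels = "A",
                           subject_id = "S")
  expect_error(line_noise_amplitude(short), "at least 2 s")
})

test_that("blink counting finds planted templates and needs frontal channels", {
  fs <- 256
  flat <- preictal_window(matrix(rnorm(4 * 30 * fs, sd = 1), 4), fs = fs,
                          channel_labels = c("FP1-F7", "FP1-F3", "FP2-F4", "FP2-F8"),
                          subject_id = "S")
  set.seed(9)
  base <- matrix(rnorm(4 * 30 * fs, sd = 2), 4)
  tmpl <- 0.5 * (1 - cos(2 * pi * seq(0, 76) / 76))
  for (t0 in c(5, 14, 25)) {
    idx <- round(t0 * fs) + seq_along(tmpl)
    base[, idx] <- base[, idx] + 60 * matrix(tmpl, 4, length(tmpl), byrow = TRUE)
  }
  w <- preictal_window(base, fs = fs,
                       channel_labels = c("FP1-F7", "FP1-F3", "FP2-F4", "FP2-F8"),
                       subject_id = "S")
  expect_equal(blink_count(w), 3)
  expect_equal(blink_count(preictal_window(matrix(0, 4, 30 * fs), fs = fs,
                                           channel_labels = w$channel_labels,
                                           subject_id = "S")), 0)
  nof <- preictal_window(matrix(0, 2, 30 * fs), fs = fs,
                         channel_labels = c("C3-P3", "C4-P4"), subject_id = "S")
  expect_error(blink_count(nof), "frontal")
})

test_that("artifact report deltas reproduce the printed worked examples", {
  expect_equal(round(preictal:::percent_reduction(3.4, 0.5)), 85)
  expect_equal(round(preictal:::percent_reduction(2.6, 1.7), 1), 34.6)
})

test_that("preprocessing reports artifact metrics in microvolts", {
  gw <- fixture_window()
  res <- suppressWarnings(preprocess_window(gw$window, ica_seed = 2,
                                            ica_tol = 1e-3))
  rep <- res$report
  expect_equal(rep$line_noise_uv_pre, 2.6, tolerance = 0.2)
  expect_gt(rep$delta_line_pct, 50)
  expect_true(is.finite(rep$blink_count_per_30s_post))
  # cleaned window keeps its shape and finite values
  expect_equal(dim(res$window$data), dim(gw$window$data))
  expect_true(all(is.finite(res$window$data)))
})
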