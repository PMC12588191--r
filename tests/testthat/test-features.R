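test_that("time stats match closed forms and degenerate rules", {
  ts <- time_stats(c(1, -1, 1, -1))
  expect_equal(ts[["mean"]], 0)
  expect_equal(ts[["variance"]], 1)
  expect_equal(ts[["zcr"]], 1)
  cst <- time_stats(rep(7, 100))
  expect_equal(unname(cst[c("variance", "skewness", "kurtosis", "line_length")]),
               c(0, 0, 0, 0))
  set.seed(10)
  mc <- time_stats(rnorm(1280))
  expect_equal(mc[["variance"]], 1, tolerance = 0.15)
  expect_lt(abs(mc[["skewness"]]), 0.2)
})

test_that("Hjorth parameters match the sinusoid closed form", {
  expect_equal(unname(hjorth(rep(3, 100))), c(0, 0, 0))
  fs <- 256
  x <- sin(2 * pi * 10 * seq(0, 20, by = 1 / fs))
  h <- hjorth(x)
  expect_equal(h[["hjorth_mobility"]], 2 * sin(pi * 10 / fs), tolerance = 1e-3)
  expect_equal(h[["hjorth_complexity"]], 1, tolerance = 0.01)
})

test_that("band powers: partition of unity, alpha sine, white-noise entropy", {
  fs <- 256
  cfg <- feature_config()
  set.seed(11)
  x <- rnorm(1280)
  bp <- band_powers(x, cfg)
  expect_equal(sum(bp[grep("bp_rel", names(bp))]), 1, tolerance = 1e-12)
  expect_gte(bp[["spectral_entropy"]], 0.9)

  sine <- sin(2 * pi * 10 * seq_len(1280) / fs)
  bps <- band_powers(sine, cfg)
  expect_gte(bps[["bp_rel_alpha"]], 0.95)
  expect_equal(bps[["peak_freq"]], 10, tolerance = 0.5)

  z <- band_powers(rep(0, 1280), cfg)
  expect_true(all(z[grep("bp_rel", names(z))] == 0))
  expect_equal(z[["spectral_entropy"]], 0)
  expect_true(isTRUE(attr(z, "degenerate")))
})

test_that("sample entropy equals the O(n^2) brute-force oracle", {
  expect_equal(as.numeric(sample_entropy(rep(c(1, -1), 60))), 0)
  set.seed(12)
  for (n in c(60, 120, 200)) {
    x <- rnorm(n)
    expect_equal(as.numeric(sample_entropy(x)), oracle_sampen(x)$value)
  }
  x <- rnorm(1280)
  expect_gte(as.numeric(sample_entropy(x)), 1.5)
  expect_lte(as.numeric(sample_entropy(x)), 3.0)
})

test_that("permutation entropy matches the direct pattern-count oracle", {
  expect_equal(permutation_entropy(seq_len(50)), 0)
  set.seed(13)
  for (n in c(20, 35, 50)) {
    x <- runif(n)
    expect_equal(permutation_entropy(x), oracle_perm_entropy(x),
                 tolerance = 1e-12)
  }
  expect_gte(permutation_entropy(runif(1280)), 0.99)
})

test_that("wavelet features satisfy Parseval and localize low frequencies", {
  set.seed(14)
  x <- rnorm(1280)
  wf <- wavelet_features(x)
  energies <- wf[grep("^wl_c[AD][0-9]_energy$", names(wf))]
  expect_equal(sum(energies), sum(x^2), tolerance = 1e-6)
  rel <- wf[grep("rel_energy", names(wf))]
  expect_equal(sum(rel), 1, tolerance = 1e-12)

  sine1 <- sin(2 * pi * 1 * seq_len(1280) / 256)
  w1 <- wavelet_features(sine1)
  expect_gt(w1[["wl_cA5_rel_energy"]], 0.9)

  expect_error(wavelet_features(rnorm(24), levels = 5), "max feasible: 3")
})

test_that("the default extractor yields 1,440 named, finite, deterministic features", {
  gw <- fixture_window()
  segs <- segment_window(gw$window)
  cfg <- feature_config()
  v <- extract_features(segs[[1]], cfg)
  expect_length(v, 1440)
  expect_equal(length(unique(names(v))), 1440)
  expect_true(all(grepl("^[A-Z0-9-]+__", names(v))))
  expect_identical(v, extract_features(segs[[1]], cfg))
  expect_true(all(is.finite(v)))

  zero_seg <- segs[[1]]
  zero_seg$data[] <- 0
  vz <- extract_features(zero_seg, cfg)
  expect_true(all(is.finite(vz)))
  expect_length(attr(vz, "degenerate_channels"), 18)

  bad <- segs[[1]]; bad$data <- bad$data[1:4, ]
  bad$channel_labels <- bad$channel_labels[1:4]
  expect_error(extract_features(bad, cfg), "channels")
  # vector length scales as channels x 80
  v4 <- extract_features(bad, feature_config(n_channels = 4))
  expect_length(v4, 4 * 80)
})

test_that("the batched path agrees with the single-channel operations", {
  gw <- fixture_window()
  seg <- segment_window(gw$window)[[2]]
  cfg <- feature_config()
  v <- extract_features(seg, cfg)
  for (ch in c(1, 7, 18)) {
    x <- seg$data[ch, ]
    manual <- c(time_stats(x), hjorth(x), band_powers(x, cfg),
                sampen = as.numeric(sample_entropy(x)),
                perm_entropy = permutation_entropy(x),
                hist_entropy = hist_entropy(x),
                wavelet_features(x))
    got <- unname(v[paste0(seg$channel_labels[ch], "__",
                           preictal:::channel_feature_names(cfg))])
    expect_equal(got, unname(manual), tolerance = 1e-8)
  }
})

test_that("documented scale behavior holds under x -> c x", {
  gw <- fixture_window()
  seg <- segment_window(gw$window)[[1]]
  x <- seg$data[5, ]
  c0 <- 3.7
  cfg <- feature_config()
  bp1 <- band_powers(x, cfg); bp2 <- band_powers(c0 * x, cfg)
  expect_equal(bp2[grep("bp_rel", names(bp2))], bp1[grep("bp_rel", names(bp1))],
               tolerance = 1e-10)
  expect_equal(bp2[["spectral_entropy"]], bp1[["spectral_entropy"]],
               tolerance = 1e-10)
  expect_equal(permutation_entropy(c0 * x), permutation_entropy(x))
  expect_equal(time_stats(c0 * x)[["zcr"]], time_stats(x)[["zcr"]])
  expect_equal(time_stats(c0 * x)[["variance"]], c0^2 * time_stats(x)[["variance"]])
  expect_equal(as.numeric(sample_entropy(c0 * x)), as.numeric(sample_entropy(x)))
})

test_that("feature matrices align metadata with rows", {
  gw <- fixture_window()
  ss <- segment_dataset(list(gw$window))
  fm <- extract_feature_matrix(ss, feature_config())
  expect_equal(dim(fm$values), c(6, 1440))
  expect_equal(fm$meta$segment_index, 0:5)
  expect_equal(fm$meta$window_id, rep(gw$window$window_id, 6))
  path <- tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  expect_true(file.exists(path) && file.exists(paste0(path, ".json")))
  unlink(c(path, paste0(path, ".json")))
})
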