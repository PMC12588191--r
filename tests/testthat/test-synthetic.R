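test_that("the default spec encodes four states with stochastic structure", {
  spec <- default_spec(42)
  expect_equal(spec$n_states, 4L)
  expect_equal(rowSums(spec$markov), rep(1, 4))
  expect_equal(rowSums(spec$state_band_weights), rep(1, 4),
               ignore_attr = TRUE)
  expect_true(all(spec$state_band_weights >= 0))
  expect_identical(default_spec(42), default_spec(42))
  expect_equal(spec$blink_rate_per_30s, 3.4)
  expect_equal(spec$line_amplitude_uv, 2.6)
})

test_that("windows carry their planted states, blinks and line noise", {
  spec <- default_spec(42)
  gw <- generate_window(spec, seed = 33)
  expect_equal(dim(gw$window$data), c(18, 7680))
  expect_length(gw$truth$states, 6)
  expect_true(all(gw$truth$states %in% 1:4))

  clean_spec <- spec
  clean_spec$blink_rate_per_30s <- 0
  clean_spec$line_amplitude_uv <- 0
  gwc <- generate_window(clean_spec, seed = 34)
  expect_equal(blink_count(gwc$window), 0)
  expect_lt(line_noise_amplitude(gwc$window), 0.05)
})

test_that("alpha-dominant segments show alpha as the largest relative band", {
  spec <- default_spec(42)
  cfg <- feature_config()
  set.seed(35)
  fracs <- c()
  while (length(fracs) < 25) {
    gw <- generate_window(spec)
    segs <- segment_window(gw$window)
    for (j in which(gw$truth$states == 1)) {
      frac <- mean(vapply(seq_len(18), function(ch) {
        rel <- band_powers(segs[[j]]$data[ch, ], cfg)[
          paste0("bp_rel_", c("delta", "theta", "alpha", "beta", "gamma"))]
        names(which.max(rel)) == "bp_rel_alpha"
      }, TRUE))
      fracs <- c(fracs, frac)
    }
  }
  expect_gte(mean(fracs), 0.8)
})

test_that("realized blink counts and measured artifact levels match the plant", {
  wins <- fixture_recovery_windows()
  planted <- vapply(wins, function(g) g$truth$blink_count, 0)
  expect_equal(mean(planted), 3.4, tolerance = 0.3 / 3.4)

  detected <- vapply(wins[1:100], function(g) blink_count(g$window), 0)
  expect_equal(mean(detected), mean(planted[1:100]), tolerance = 0.1)

  lines <- vapply(wins[1:50], function(g) line_noise_amplitude(g$window), 0)
  expect_equal(median(lines), 2.6, tolerance = 0.2)   # within +/-20 % of plant
})

test_that("the planted Markov chain is recovered from 200 windows", {
  wins <- fixture_recovery_windows()
  seqs <- lapply(wins, function(g) g$truth$states)
  tm <- transition_matrix(seqs)
  expect_lte(max(abs(tm$probs - default_spec(42)$markov)), 0.1)
})

test_that("cohorts are reproducible and mirror the 96-window shape", {
  spec <- default_spec(7)
  ds <- generate_dataset(spec, 3, 2)
  ds2 <- generate_dataset(spec, 3, 2)
  expect_identical(ds$windows[[5]]$data, ds2$windows[[5]]$data)
  expect_equal(nrow(ds$manifest), 6)
  expect_true(all(vapply(ds$truths, function(t) length(t$states), 0L) == 6))
  expect_equal(length(unique(ds$manifest$subject_id)), 3)
  expect_error(generate_dataset(spec, 0, 5), ">= 1")

  df <- write_truth(ds, tempfile(fileext = ".tsv"))
  expect_equal(nrow(df), 6 * 6)
})

test_that("the full pipeline recovers the planted states end to end", {
  cfg <- pipeline_config(seed = 42L,
                         simulate = list(n_subjects = 25L),
                         preprocess = list(bandpass = FALSE, ica = FALSE,
                                           artifact_metrics = FALSE),
                         cluster = list(baselines = FALSE))
  state <- list()
  for (stage in c("simulate", "preprocess", "segment", "features", "reduce",
                  "cluster")) {
    state <- suppressMessages(suppressWarnings(
      preictal:::run_one_stage(stage, state, cfg)))
  }
  expect_equal(state$selection$k, 4L)
  truth <- unlist(lapply(state$dataset$truths, function(t) t$states))
  ari <- mclust::adjustedRandIndex(truth, state$clustering$result$labels)
  expect_gte(ari, 0.7)
})
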