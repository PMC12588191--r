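# Pipeline orchestration: validated configuration, staged execution with
# persisted artifacts, and deterministic reruns (fixed seeds, hashed outputs).

pipeline_defaults <- function() {
  list(
    seed = 42L,
    simulate = list(n_subjects = 12L, windows_per_subject = 8L),
    window_s = 30, seg_len_s = 5,
    preprocess = list(zscore = TRUE, bandpass = TRUE, ica = TRUE,
                      low = 0.5, high = 45, order = 4, mains_hz = 50,
                      blink_threshold_sigmas = 4, artifact_metrics = TRUE,
                      ica_max_iter = 200L, ica_tol = 1e-3),
    features = list(fs = 256, n_channels = 18L),
    reduce = list(var_threshold = 0.95, n_neighbors = 15, min_dist = 0.1,
                  n_epochs = 200L),
    cluster = list(k_min = 2L, k_max = 10L, n_init = 10L,
                   min_cluster_size = 20L, baselines = TRUE),
    dynamics = list(smooth_window = 2, exclude_noise = TRUE))
}

validation_error <- function(msg) {
  stop(structure(class = c("validation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

missing_upstream <- function(msg) {
  stop(structure(class = c("missing_upstream", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Pipeline configuration
#'
#' Builds the full pipeline configuration from the defaults (30-s windows,
#' 5-s segments, 0.5-45 Hz band, 95 % PCA variance, n_neighbors 15,
#' min_dist 0.1, k scanned over 2-10, minimum cluster size 20, smoothing
#' window 2), overridden by any supplied values. Unknown keys are rejected.
#'
#' @param ... Named overrides; nested sections (e.g.
#'   `preprocess = list(ica = FALSE)`) are merged key-wise.
#' @param file Optional YAML file of overrides, applied before `...`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- pipeline_defaults()
  merge_section <- function(cfg, over, path = "") {
    for (key in names(over)) {
      full <- if (nzchar(path)) paste0(path, ".", key) else key
      if (!key %in% names(cfg)) validation_error(sprintf("unknown config key: %s", full))
      if (is.list(cfg[[key]]) && is.list(over[[key]])) {
        cfg[[key]] <- merge_section(cfg[[key]], over[[key]], full)
      } else {
        cfg[[key]] <- over[[key]]
      }
    }
    cfg
  }
  if (!is.null(file)) {
    if (!file.exists(file)) validation_error(sprintf("config file not found: %s", file))
    cfg <- merge_section(cfg, yaml::read_yaml(file))
  }
  cfg <- merge_section(cfg, list(...))
  if (cfg$seg_len_s <= 0 || cfg$window_s < cfg$seg_len_s) {
    validation_error("need 0 < seg_len_s <= window_s")
  }
  if (cfg$preprocess$low <= 0 || cfg$preprocess$low >= cfg$preprocess$high) {
    validation_error("need 0 < preprocess.low < preprocess.high")
  }
  if (cfg$cluster$k_min < 2 || cfg$cluster$k_max < cfg$cluster$k_min) {
    validation_error("need 2 <= cluster.k_min <= cluster.k_max")
  }
  structure(cfg, class = "pipeline_config")
}

pipeline_stages <- function() {
  c("simulate", "preprocess", "segment", "features", "reduce", "cluster",
    "dynamics")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

stage_simulate <- function(state, cfg) {
  spec <- default_spec(cfg$seed)
  spec$window_s <- cfg$window_s
  spec$seg_len_s <- cfg$seg_len_s
  spec$fs <- cfg$features$fs
  state$dataset <- generate_dataset(spec, cfg$simulate$n_subjects,
                                    cfg$simulate$windows_per_subject)
  state$windows <- state$dataset$windows
  state
}

stage_preprocess <- function(state, cfg) {
  if (is.null(state$windows)) missing_upstream("no windows: run 'simulate' (or ingest) first")
  p <- cfg$preprocess
  cleaned <- vector("list", length(state$windows))
  reports <- vector("list", length(state$windows))
  for (i in seq_along(state$windows)) {
    w <- state$windows[[i]]
    res <- suppressWarnings(preprocess_window(
      w, zscore = p$zscore, bandpass_filter = p$bandpass, ica = p$ica,
      low = p$low, high = p$high, order = p$order, mains_hz = p$mains_hz,
      ica_seed = derive_seed(cfg$seed, w$window_id),
      ica_max_iter = p$ica_max_iter, ica_tol = p$ica_tol,
      blink_threshold_sigmas = p$blink_threshold_sigmas,
      metrics = p$artifact_metrics))
    cleaned[[i]] <- res$window
    reports[[i]] <- res$report
  }
  state$clean_windows <- cleaned
  state$artifact_report <- do.call(rbind, reports)
  state
}

stage_segment <- function(state, cfg) {
  windows <- state$clean_windows %||% state$windows
  if (is.null(windows)) missing_upstream("no windows: run 'simulate' first")
  state$segments <- segment_dataset(windows, cfg$seg_len_s)
  state
}

stage_features <- function(state, cfg) {
  if (is.null(state$segments)) missing_upstream("no segments: run 'segment' first")
  fc <- feature_config(fs = cfg$features$fs, n_channels = cfg$features$n_channels)
  state$features <- extract_feature_matrix(state$segments, fc)
  state
}

stage_reduce <- function(state, cfg) {
  if (is.null(state$features)) missing_upstream("no feature matrix: run 'features' first")
  r <- cfg$reduce
  state$reduction <- suppressWarnings(reduce_features(
    state$features, var_threshold = r$var_threshold,
    n_neighbors = r$n_neighbors, min_dist = r$min_dist,
    seed = derive_seed(cfg$seed, "embedding"), n_epochs = r$n_epochs))
  state
}

stage_cluster <- function(state, cfg) {
  if (is.null(state$reduction)) missing_upstream("no embedding: run 'reduce' first")
  cl <- cfg$cluster
  E <- state$reduction$embedding
  sel <- suppressWarnings(select_k(E, seq(cl$k_min, cl$k_max),
                                   seed = derive_seed(cfg$seed, "kmeans"),
                                   n_init = cl$n_init))
  nf <- noise_filter(sel$best_fit, E, min_size = cl$min_cluster_size)
  state$selection <- sel
  state$clustering <- nf
  if (isTRUE(cl$baselines)) {
    state$baselines <- suppressWarnings(
      baseline_comparison(E, sel$k, seed = derive_seed(cfg$seed, "baseline")))
  }
  state
}

stage_dynamics <- function(state, cfg) {
  if (is.null(state$clustering)) missing_upstream("no cluster labels: run 'cluster' first")
  seqs <- build_sequences(state$features$meta, state$clustering$result$labels)
  tm <- transition_matrix(seqs, exclude_noise = cfg$dynamics$exclude_noise)
  state$transitions <- tm
  state$dynamics <- dynamics_report(tm, seqs, cfg$dynamics$smooth_window)
  state
}

write_stage_outputs <- function(stage, state, cfg, out_dir) {
  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)
  switch(stage,
    simulate = {
      write_window_manifest(state$windows, file.path(out_dir, "windows.tsv"))
      add(file.path(out_dir, "windows.tsv"))
      write_truth(state$dataset, file.path(out_dir, "truth.tsv"))
      add(file.path(out_dir, "truth.tsv"))
    },
    preprocess = {
      write_artifact_report(state$artifact_report,
                            file.path(out_dir, "artifacts.tsv"))
      add(file.path(out_dir, "artifacts.tsv"))
    },
    segment = {
      write_segment_manifest(state$segments, file.path(out_dir, "segments.tsv"))
      add(file.path(out_dir, "segments.tsv"))
    },
    features = {
      add(write_feature_matrix(state$features, file.path(out_dir, "features.tsv")))
    },
    reduce = {
      add(write_embedding(state$reduction, file.path(out_dir, "embedding.tsv"),
                          row_ids = paste0(state$features$meta$window_id, "_",
                                           state$features$meta$segment_index)))
    },
    cluster = {
      add(write_labels(state$clustering$result, file.path(out_dir, "labels.tsv"),
                       removed_mask = state$clustering$removed_mask))
      write_tsv(state$selection$diagnostics, file.path(out_dir, "k_scan.tsv"))
      add(file.path(out_dir, "k_scan.tsv"))
      metrics <- list(
        selected_k = state$selection$k,
        elbow_k = state$selection$elbow_k,
        silhouette_k = state$selection$silhouette_k,
        pre_filter = unclass(state$clustering$report_pre)[
          c("silhouette", "davies_bouldin", "calinski_harabasz")],
        post_filter = unclass(state$clustering$report_post)[
          c("silhouette", "davies_bouldin", "calinski_harabasz")],
        cluster_sizes_pre = as.list(state$clustering$report_pre$cluster_sizes),
        cluster_sizes_post = as.list(state$clustering$report_post$cluster_sizes))
      if (!is.null(state$baselines)) metrics$baselines <- state$baselines
      write_json_sidecar(metrics, file.path(out_dir, "metrics.json"))
      add(file.path(out_dir, "metrics.json"))
    },
    dynamics = {
      write_transition_matrix(state$transitions, file.path(out_dir, "transitions"))
      add(file.path(out_dir, "transitions_counts.tsv"))
      add(file.path(out_dir, "transitions_probs.tsv"))
      dyn <- state$dynamics
      write_json_sidecar(list(top_destinations = dyn$top_destinations,
                              most_frequent = as.list(dyn$most_frequent),
                              least_frequent = as.list(dyn$least_frequent),
                              changes_before = dyn$changes_before,
                              changes_after = dyn$changes_after,
                              smooth_window = dyn$smooth_window),
                         file.path(out_dir, "dynamics.json"))
      add(file.path(out_dir, "dynamics.json"))
    })
  unique(paths)
}

run_one_stage <- function(stage, state, cfg) {
  fn <- switch(stage,
               simulate = stage_simulate, preprocess = stage_preprocess,
               segment = stage_segment, features = stage_features,
               reduce = stage_reduce, cluster = stage_cluster,
               dynamics = stage_dynamics,
               validation_error(sprintf("unknown stage: %s", stage)))
  t0 <- proc.time()[["elapsed"]]
  state <- fn(state, cfg)
  message(sprintf("[preictal] stage %-10s done in %.1f s", stage,
                  proc.time()[["elapsed"]] - t0))
  state
}

#' Run one pipeline stage against a working directory
#'
#' Loads the persisted pipeline state from `out_dir`, runs `stage`, writes
#' the stage outputs (with a manifest of content hashes, the effective
#' configuration and the seed), and persists the updated state.
#'
#' @param stage One of `simulate`, `preprocess`, `segment`, `features`,
#'   `reduce`, `cluster`, `dynamics`.
#' @param config A [pipeline_config()].
#' @param out_dir Working/output directory.
#' @return The updated state, invisibly.
#' @export
run_stage <- function(stage, config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state_path <- file.path(out_dir, "state.rds")
  state <- if (file.exists(state_path)) readRDS(state_path) else list()
  state <- run_one_stage(stage, state, config)
  saveRDS(state, state_path)
  paths <- write_stage_outputs(stage, state, config, out_dir)
  update_manifest(out_dir, stage, paths, config)
  invisible(state)
}

update_manifest <- function(out_dir, stage, paths, config) {
  writeLines(yaml::as.yaml(unclass(config)), file.path(out_dir, "config.yaml"))
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else list(seed = config$seed, config_hash = config_hash(config), stages = list())
  hashes <- as.list(tools::md5sum(paths))
  names(hashes) <- basename(paths)
  manifest$stages[[stage]] <- hashes
  manifest$seed <- config$seed
  manifest$config_hash <- config_hash(config)
  write_json_sidecar(manifest, manifest_path)
}

#' Run the full pipeline
#'
#' Executes simulate -> preprocess -> segment -> features -> reduce ->
#' cluster -> dynamics in memory, optionally persisting every stage's
#' artifacts (TSV/JSON plus a hash manifest) to `out_dir`. Deterministic:
#' rerunning with the same configuration yields hash-identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return The final pipeline state (a list with dataset, cleaned windows,
#'   segments, features, reduction, selection, clustering, transitions,
#'   dynamics).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  state <- list()
  for (stage in pipeline_stages()) {
    state <- run_one_stage(stage, state, config)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      paths <- write_stage_outputs(stage, state, config, out_dir)
      update_manifest(out_dir, stage, paths, config)
    }
  }
  if (!is.null(out_dir)) saveRDS(state, file.path(out_dir, "state.rds"))
  state
}
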