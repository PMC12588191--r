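Package: preictal
Title: Unsupervised Discovery of Pre-Ictal EEG Microstates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: CPU-only pipeline for discovering quasi-stable microstates in the
    30 seconds of scalp EEG preceding pediatric seizure onsets. Covers EDF
    ingest and seizure-annotation parsing, artifact-aware preprocessing
    (per-channel z-scoring, zero-phase Butterworth band-pass filtering,
    seeded independent component analysis with quantitative blink and
    mains-noise reports), a multimodal per-channel feature extractor
    (time-domain statistics, Hjorth parameters, Welch band powers, entropy
    measures, wavelet subband descriptors), variance-thresholded principal
    component analysis followed by a two-dimensional neighbor embedding,
    K-Means clustering with elbow and silhouette model selection, internal
    validity indices with minimum-size noise filtering, and within-window
    cluster-transition dynamics. A seeded synthetic EEG generator with
    planted latent spectral states, blink artifacts and mains noise makes
    every stage testable without clinical recordings.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
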