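---
title: "Discovering pre-ictal EEG microstates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering pre-ictal EEG microstates: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In the half minute before a pediatric seizure, scalp EEG is thought to pass
through a sequence of quasi-stable activity patterns — *microstates* —
rather than drifting continuously. `preictal` implements an unsupervised,
CPU-only pipeline that tries to discover such states without labels: cut
the 30 s before each annotated onset into six 5-s segments, describe every
segment by a rich multimodal feature vector, compress that description, and
cluster it. Everything downstream of the clustering (validity indices,
minimum-size noise filtering, transition matrices) exists to answer two
questions: *are the clusters real*, and *do they follow each other in a
structured way*?

The pipeline is deliberately modest in its claims: it is a pattern-mining
tool, not a seizure predictor.

## Pipeline and model assumptions

1. **Ingest** — EDF recordings restricted to an 18-channel longitudinal
   bipolar montage; seizure onsets from plain-text annotation summaries.
   30-s windows end at the onset (configurable gap, default 0 s).
2. **Preprocess** — per-channel z-scoring (population SD over the window),
   zero-phase Butterworth band-pass 0.5–45 Hz, and symmetric FastICA with
   automatic flagging of ocular and mains components. Blink rate and
   49–51 Hz line amplitude are quantified before and after cleaning.
3. **Segment** — non-overlapping 5-s segments, 0-based half-open sample
   indexing; a 30-s window yields exactly six.
4. **Features** — 80 features per channel (below), 1,440 per segment at the
   default montage.
5. **Reduce** — column-standardized PCA keeping the smallest number of
   components with cumulative explained variance ≥ 95 %, then a 2-D
   fuzzy-neighbor embedding (`n_neighbors = 15`, `min_dist = 0.1`,
   Euclidean metric, fixed seed).
6. **Cluster** — K-Means (k-means++ starts, best of 10 by inertia) scanned
   over k = 2..10; the elbow (inertia second difference) and the mean
   silhouette are both computed and the silhouette choice is returned.
   DBSCAN and Ward baselines are fitted for comparison. Clusters with
   fewer than 20 members are relabelled as noise (−1) and the validity
   indices are recomputed on the retained points.
7. **Dynamics** — within-window label sequences, a trailing moving-average
   smoother (window 2), and row-stochastic transition matrices. Pairs never
   span window boundaries, and noise labels break adjacency.

The key modelling assumptions are that 5 s is long enough to estimate a
segment's spectral profile yet short enough to be state-pure, and that a
microstate is expressed simultaneously across channels, so per-channel
features concatenated across the montage characterize it.

## The 80-feature layout

The per-channel feature budget is a declared composition (the literature
rarely enumerates such vectors exactly); every block is driven by
`feature_config()` so alternative layouts remain possible:

| block | count | contents |
|---|---|---|
| time statistics | 8 | mean, population variance, skewness, excess kurtosis, RMS, peak-to-peak, zero-crossing rate, line length |
| Hjorth | 3 | activity, mobility, complexity |
| band powers | 10 | absolute and relative power in δ 0.5–4, θ 4–8, α 8–13, β 13–30, γ 30–45 Hz |
| spectral summaries | 5 | total power, normalized spectral entropy, 95 % spectral edge, peak frequency, median frequency |
| power ratios | 3 | θ/α, δ/β, (δ+θ)/(α+β) |
| entropies | 3 | sample entropy (m = 2, r = 0.2 SD), permutation entropy (order 3, delay 1, normalized), histogram entropy (10 bins) |
| wavelet | 48 | 5-level periodized db4: per coefficient set (cA5, cD5…cD1) mean, SD, mean |c|, energy, relative energy, max |c|, skewness, kurtosis |

Spectral estimates use Welch's method with 2-s Hamming windows and 50 %
overlap; bands are half-open `[low, high)` intervals so the five rhythms
partition the analysis range exactly and relative powers sum to one.
Degenerate inputs follow explicit zero rules (a constant channel has
skewness, kurtosis and entropies equal to 0) so the feature matrix is
finite for any finite input.

Two implementation paths exist — readable single-channel R functions
(`time_stats()`, `hjorth()`, `band_powers()`, …) and a batched C++ kernel
used by `extract_features()` — and the test suite checks they agree to
round-off on real segments. Sample entropy uses a sorted-sweep counter that
enumerates only first-coordinate matches; it is exact (the suite compares
it against the O(n²) definition) but roughly an order of magnitude faster
on 1,280-sample segments.

## Numerical choices

* **Filtering.** The 0.5–45 Hz band-pass is implemented as a 4th-order
  high-pass at 0.5 Hz cascaded with a 4th-order low-pass at 45 Hz, each
  applied forward–backward with odd-reflection padding. A single band-pass
  recursion over such an asymmetric band is numerically fragile; the
  cascade is stable and the zero-phase response is the squared Butterworth
  magnitude, which the tests verify against the analytic response.
* **ICA.** Symmetric FastICA (logcosh), PCA whitening, seeded random
  orthogonal initialization, tolerance 10⁻³ in the pipeline. Blink
  components are flagged by frontal loading fraction > 0.6, excess
  kurtosis > 5 and low-frequency (< 5 Hz) power fraction > 0.5; line
  components by > 30 % of power within ±1 Hz of the mains frequency. These
  thresholds are declared defaults, not literature claims. Non-convergence
  is an error carrying the iteration count; the pipeline retries a window
  with derived seeds before giving up.
* **Line-noise metric.** The 49–51 Hz amplitude is reported as the
  sinusoid-equivalent amplitude `sqrt(2 × band power)` from a
  rectangular-window DFT of the whole window (2/N single-sided
  normalization), the median across channels. An on-bin sinusoid of
  amplitude A yields exactly A, which is what makes the metric comparable
  with a planted amplitude; a per-bin mean would divide the same
  information by the number of bins in the band.
* **Blink counter.** The 0.5–5 Hz-filtered frontal mean is compared
  one-sided against 4× its MAD-based robust SD (blinks are positive
  deflections of frontal derivations), with 0.5 s minimum event
  separation, normalized per 30 s.
* **Mains frequency.** The default is 50 Hz to match the 49–51 Hz band of
  the artifact report; it is configurable to 60 Hz for North American
  recordings.
* **PCA.** Features are column-standardized (they mix units spanning many
  orders of magnitude); zero-variance columns are dropped with a warning.
  The eigendecomposition runs on whichever of the Gram or covariance
  matrix is smaller, so 576×1,440 cohorts are cheap.
* **Embedding.** The 2-D layout is a UMAP-style fuzzy-neighbor embedding
  implemented in the package:
  per-point smoothed-kNN bandwidths calibrated to log₂(k), fuzzy-union
  symmetrization, PCA initialization scaled to a ±10 box, and SGD with
  negative sampling over 200 epochs using an internal deterministic RNG.
  Identical seeds give byte-identical embeddings.
* **k selection.** Inertia is also computed at k = 1 (total sum of
  squares) so the elbow — the maximizer of the inertia curve's second
  difference — is defined at the smallest scanned k. When elbow and
  silhouette disagree the silhouette wins, with a warning; ties go to the
  smaller k.
* **Validity space.** Silhouette, Davies–Bouldin and Calinski–Harabasz are
  computed in the 2-D embedding, where the clustering itself lives.
* **Label smoothing.** A "moving average" of categorical labels is
  undefined as stated, so the package one-hot encodes the labels, averages
  over a trailing window of 2 segments, and re-discretizes by argmax with
  ties resolved in favor of the previous smoothed label; the first element
  is unchanged. Under this rule smoothing never increases the number of
  label changes, which the suite checks property-style.

## The synthetic cohort generator

Because the clinical recordings cannot ship with the package, every claim
is exercised against `default_spec()` / `generate_dataset()`, a seeded
generator that emulates the structure the pipeline is meant to find:

* **Latent states.** Four states with distinct band-power profiles
  (α-dominant; θ-dominant; δ+θ-dominant; β/γ-dominant), switching only at
  5-s segment boundaries under a Markov chain with self-transition 0.5,
  elevated transitions into the slow δ+θ state and a suppressed fast→α
  escape. Initial states are drawn from the chain's stationary
  distribution.
* **Signals.** Shared band-limited Gaussian sources (spectral synthesis
  with hard band masks) mixed into 18 channels with signed, jittered
  channel gains (inter-channel correlation, per-subject structure), plus
  per-channel 1/f background limited to 0.5–45 Hz, all modulated by one
  slow lognormal amplitude envelope. The shared envelope provides the
  super-Gaussian marginals ICA needs without disturbing a segment's
  relative band-power profile; the state-weight tracks are band-limited to
  ≤ 4 Hz so switching cannot leak energy past the 45 Hz band edge.
  Frontal-channel gains are balanced to zero mean per band: bipolar
  frontal derivations of shared posterior-dominant rhythms carry
  near-cancelling gradients, so the frontal mean reflects background and
  ocular activity, as on a real double-banana montage.
* **Artifacts.** Blinks are 300-ms raised-cosine bumps of 120 µV added in
  phase to the four fronto-polar channels at a Poisson rate of 3.4 per
  30 s (with a 1-s refractory separation so events remain countable), and
  mains noise is a common-phase 50 Hz sinusoid of 2.6 µV — the pre-clean
  artifact regime the package's reports are benchmarked against.
* **Amplitudes.** State component 25 µV, background 18 µV. These were
  chosen once so that the four states form well-separated clusters after
  reduction — the regime the method is designed to detect — while the
  artifact metrics remain honest (the blink detector recovers the planted
  rate within a few percent; the line metric recovers 2.6 µV almost
  exactly).

The default cohort is 12 subjects × 8 windows (96 windows, 576 segments);
the k-recovery experiment uses 25 subjects × 8 windows (200 windows, 1,200
segments) and 20 replicate seeds. For that experiment preprocessing is
z-scoring only: the generator's signals are band-limited by construction,
so filtering is a near-no-op there, and ICA cleaning is evaluated
separately by the artifact tests. These problem sizes keep a full
replicate around half a minute on one CPU core.

**What passing these tests does and does not show.** The generator's
states are genuinely latent (the pipeline never sees the truth), but they
are cleaner than real EEG: state changes are segment-aligned, the montage
is fixed, there are no electrode pops, movement or muscle artifact, and
between-subject variability is a gain jitter rather than true anatomical
difference. Success on the synthetic cohort demonstrates that the
machinery is correct and sensitive at realistic SNR — not that four
microstates exist in any particular clinical recording.

## Known limitations

* No EDF+ annotation channels; seizure times come from the plain-text
  summary dialect.
* No cross-channel features (coherence, phase-locking) and no
  time-resolved features inside a segment.
* The ICA flags target blinks and mains only; muscle and electrode
  artifacts pass through.
* Transition analysis is first-order and within-window; no hidden-Markov
  or state-space modelling.
* Validity indices in the 2-D embedding inherit the embedding's
  distortions; the space is configurable but the defaults follow the
  pipeline's design.
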