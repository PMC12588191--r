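# preictal

Unsupervised discovery of **pre-ictal EEG microstates** in pediatric scalp
recordings, on one CPU core, without labels.

Scalp EEG in the 30 seconds before a seizure is hypothesized to pass
through a small number of quasi-stable activity patterns. `preictal`
implements the full discovery pipeline: it cuts the 30-s pre-onset window
of each annotated seizure into six non-overlapping 5-s segments, converts
every segment into a 1,440-dimensional multimodal feature vector
(80 features × 18 bipolar channels: time-domain statistics, Hjorth
parameters, Welch band powers and spectral summaries, sample/permutation/
histogram entropies, and db4 wavelet subband descriptors), compresses the
matrix with variance-thresholded PCA (≥ 95 % retained) followed by a 2-D
neighbor embedding (`n_neighbors = 15`, `min_dist = 0.1`), and clusters the
embedding with K-Means, choosing k by the elbow and silhouette criteria.
Cluster quality is audited with the Silhouette, Davies–Bouldin and
Calinski–Harabasz indices; clusters with fewer than 20 members are
relabelled as noise; and within-window label sequences are summarized as
row-stochastic transition matrices with an optional categorical smoother.

Preprocessing is artifact-aware: per-channel z-scoring, zero-phase
0.5–45 Hz Butterworth filtering, and seeded FastICA with automatic flagging
of blink and mains-line components, quantified before and after cleaning
(blink count per 30 s; median 49–51 Hz sinusoid-equivalent amplitude).

Because clinical recordings cannot ship with a package, `preictal`
includes a first-class synthetic cohort generator (`default_spec()`,
`generate_dataset()`): 18-channel, 256 Hz recordings with four latent
spectral states switching under a Markov chain at segment boundaries,
planted blinks (3.4 per 30 s), 50 Hz mains noise (2.6 µV) and 1/f
background — with ground truth, so every stage of the pipeline is testable
end to end.

## A worked example

```r
library(preictal)

state <- run_pipeline(pipeline_config(), out_dir = "runs/demo")
#> [preictal] stage simulate   done in 8.5 s
#> [preictal] stage preprocess done in 62.0 s
#> [preictal] stage features   done in 10.5 s
#> ...

state$segments
#> <segment_set> 96 windows -> 576 segments across 12 subjects
state$features
#> <feature_matrix> 576 segments x 1440 features
state$reduction
#> <reduction_result> 576 points: 234 PCs (95.0% variance) -> 2-D embedding

state$clustering$report_pre
#> <validation_report> [pre_filter] silhouette 0.846 | DB 0.180 | CH 9512.1 | sizes 103/89/154/215/15
state$clustering$report_post
#> <validation_report> [post_filter] silhouette 0.859 | DB 0.189 | CH 11875.5 | sizes 103/89/154/215

state$transitions
#> <transition_matrix> 4 states, 462 transitions
#>       1     2     3     4
#> 1 0.524 0.000 0.232 0.244
#> 2 0.075 0.433 0.149 0.343
#> 3 0.088 0.096 0.512 0.304
#> 4 0.170 0.176 0.170 0.484

state$dynamics
#> <dynamics_report> label changes 246 -> 135 after smoothing (window 2)
```

Reading the output: the simulated 12-subject cohort (96 pre-ictal windows,
576 segments) passes through cleaning, feature extraction and reduction;
the silhouette scan settles on five clusters, one of which is a 15-segment
outlier group that the minimum-size filter relabels as noise — leaving
four well-separated microstates (silhouette 0.859) whose transition matrix
shows strong self-persistence (diagonal ≈ 0.43–0.52) and structured
off-diagonal flow. The artifact report for the same run shows the planted
2.6 µV mains line reduced to ~0.67 µV and planted blinks essentially
eliminated.

Every stage writes TSV/JSON artifacts plus a hash manifest into
`out_dir`; reruns with the same configuration are hash-identical.

Clinical EDF data enter through the same surface:

```r
rec    <- read_recording("chb01_03.edf", montage = default_montage())
events <- parse_seizure_summary(readLines("chb01-summary.txt"))
w      <- extract_preictal_windows(rec, events[["chb01_03.edf"]])
```

A thin command-line front end (`inst/exec/preictal`) exposes the stages as
subcommands (`simulate`, `preprocess`, …, `run-all`) with `--config`,
`--seed` and `--out`.

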