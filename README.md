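# fmriqc

Quality control for FMRI time series: per-subject metrics, artifact
detectors, a portable HTML QC report, and group-level triage tables — all
computable offline and testable against a deterministic synthetic phantom
generator.

## Who this is for

Anyone processing 4D echo-planar imaging (EPI) data who needs to answer,
per subject and per study: how much did this person move, and how much data
does censoring cost? Is the temporal signal-to-noise ratio (TSNR) adequate,
and where? Are there scanner artifacts (bad coils, through-plane variance
lines), left-right flipped datasets, pre-steady-state volumes, or degenerate
regression models? The package computes the standard quantitative review
values, renders them into a self-contained static HTML page with graded
warning colors and persisted ratings/comments, and tabulates them across
subjects with a small filtering language for exclusion decisions.

## The quantities it computes

* **enorm** — per-volume motion size: the Euclidean norm of the forward
  differences of the six rigid-body motion parameters,
  `e_t = sqrt(sum_i (p[t,i] - p[t-1,i])^2)`, with `e = 0` at each run start.
* **Outlier fraction** — per volume, the share of in-mask voxels whose
  linearly detrended value exceeds `k * 1.4826 * MAD` of their own series
  (`k = qnorm(1 - alpha/2)`, `alpha = 0.01` by default).
* **Censoring** — volumes with `enorm > 0.3` or outlier fraction `> 0.1`
  (defaults) are censored; an enorm trigger also censors the preceding
  volume in the same run. Summaries are reported before (BC) and after (AC)
  censoring.
* **TSNR** — per voxel, `mean(signal) / sd(noise)`, at the volume-registered
  stage (noise = the series' own polynomial-detrend residual) or the
  regression stage (noise = supplied residuals).
* **GCOR** — global correlation: the average of all pairwise temporal
  correlations among in-mask voxels, computed as the squared norm of the
  mean of the unit-normalized series.
* **corr_brain** — each voxel's residual correlation with the brain-average
  residual series.
* **radcor** — radial correlation: each voxel against a Gaussian-weighted
  (FWHM 20 mm) average of its large neighborhood; coil artifacts and motion
  show up as large coherent patches.
* **Grayplot / carpet plot** — Z-scored voxel series as a voxels-by-time
  matrix, rows ordered by similarity to the first principal component,
  clipped at the two-sided normal p = 0.001 quantile (3.29).
* **DF ledger** — degrees of freedom consumed by censoring, drift, motion
  and bandpass regressors. Bandpassing to 0.01–0.1 Hz removes ~64% of DFs
  at TR = 2 s and ~82% at TR = 1 s.
* **Left-right flip check** — local Pearson correlation (LPC) cost of
  EPI vs. anatomical, as-is against left-right mirrored; `DO_FLIP` when the
  mirrored cost is clearly lower.
* **Variance lines** — narrow through-plane columns of artifactually high
  temporal variance, detected by comparing each in-plane column's
  90th-percentile scaled standard deviation to its neighborhood median.
* **ROI table** — per-ROI TSNR quartiles, voxel counts, zero counts, and
  maximum erosion depth, each cell graded none/mild/medium/severe.

## Worked example

Generate a phantom with a planted motion spike and a planted variance line,
then run the individual detectors:

```r
library(fmriqc)

spec <- phantom_spec(run_lengths = 150L, seed = 42L,
  motion_spikes  = list(times = 60L, magnitudes = 1.0),
  variance_lines = list(ij = rbind(c(12L, 7L)), gain = 6))
ph <- make_phantom(spec)

enorm   <- compute_enorm(ph$motion)
outfrac <- outlier_fractions(ph$vol, ph$mask)
cens    <- make_censor(enorm, outfrac, enorm_limit = 0.3, outlier_limit = 0.1)
cens
#> <censor_vector> 3 / 150 volumes censored (enorm > 0.3, outlier > 0.1)
#>   censored: 59 60 61
```

The spike at volume 60 censors 60 and 61 (both forward differences exceed
the limit) plus 59 via the neighbor rule. The other metrics:

```r
gcor(ph$vol, ph$mask)
#> 0.535975            # drift + spike shared variance, uncorrected series
mean(tsnr_volreg(ph$vol, ph$mask)$data[ph$mask])
#> 100.64              # baseline 1000 over noise sd ~10
variance_lines(ph$vol, ph$mask)
#> # A tibble: 1 x 6
#>       i     j score     x     y     z
#>    12     7  5.97    33    18    21   # the planted line, ~6x neighborhood
flip_check(ph$epi_ref, ph$anat, ph$mask)$guess
#> "NO_FLIP"           # cost as-is -1.000 vs flipped -0.819
```

A full report — montages, grayplot, DF ledger, warning colors, ratings
JSON, review dictionary — comes from the pipeline driver:

```r
write_fixture_bundle(ph, "bundle/")
qc_run("bundle/", "qc_subj/", subject = "p001")
# qc_subj/index.html, qc_subj/out.ss_review.p001.txt, apqc_p001.rate.json, ...
```

Thin command-line wrappers live in `inst/cli/`: `qc-phantom` (spec JSON to
bundle), `qc-run` (bundle to QC directory), and `qc-table`
(`-write_table`, `-report_outliers 'censor fraction' GE 0.1`,
`-show_keepers`, `-gtkyd` for raw-dataset consistency scans).

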