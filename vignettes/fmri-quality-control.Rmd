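---
title: "Methods: FMRI quality-control metrics, detectors and phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FMRI quality-control metrics, detectors and phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmriqc)
```

This vignette records the models behind each quality-control (QC) quantity,
the tunable parameters and their defaults, the numerical conventions, the
design decisions taken where the underlying procedures are conventionally
described only loosely, and what the synthetic phantom tests do and do not
demonstrate about real data.

## Motion and censoring

The six rigid-body motion parameters (roll, pitch, yaw in degrees; three
translations in mm) summarize volume registration. Per-volume motion is the
Euclidean norm of their forward differences (`compute_enorm()`), combining
degrees and millimeters unweighted — the conventional scalar, interpretable
as roughly "mm-deg of movement between consecutive volumes". The first
volume of each run is assigned 0: runs are acquired separately, so a
cross-run difference is meaningless.

The outlier fraction (`outlier_fractions()`) asks, per volume, what share
of in-mask voxels look like temporal outliers of their own series. The
detector is: remove a linear trend per run (the cheapest model that keeps
slow drift from inflating the spread estimate), then flag time points where
the absolute residual exceeds `k * 1.4826 * MAD` of the voxel's residuals,
with `k = qnorm(1 - alpha/2)` and `alpha = 0.01` by default. The MAD base
makes the spread estimate itself robust to the outliers being sought. A
numerically-constant series (MAD at rounding level) is never flagged: the
threshold has a floor of `1e-8` relative to the series magnitude.

Censoring (`make_censor()`) excludes a volume when `enorm > 0.3` or the
outlier fraction exceeds `0.1` (both configurable; the defaults are the
values in common use for task FMRI at 3 T). Because an enorm excursion at
volume *t* reflects movement somewhere between *t−1* and *t*, the preceding
volume in the same run is censored too (`censor_prev = TRUE`). Outlier
triggers do not censor the neighbor: the outlier statistic localizes the
corruption to the flagged volume itself. Summaries report five-number
statistics before censoring (all volumes) and after (kept volumes only),
plus per-run censored fractions. In review files, overall fractions are
rounded to 6 decimals and per-run fractions to 6 significant digits,
matching the conventional formatting of review dictionaries.

## Voxelwise quality maps

**TSNR.** `mean(signal)/sd(noise)` per voxel. At the volume-registered
stage the signal is the full series and the noise its own residual after
per-run polynomial detrending (order 2 by default); at the regression stage
the noise is the supplied residual series. Voxels whose noise has zero
variance are set to 0 and counted rather than propagating `Inf`.

**GCOR.** The mean of all pairwise correlations among in-mask voxels,
including self-pairs, computed via the identity that this equals the
squared norm of the mean of the demeaned, unit-normalized series — O(VT)
instead of O(V²T). Including self-pairs is what makes the identity exact;
with thousands of mask voxels the self-term adds at most 1/V. Zero-variance
voxels are excluded. GCOR is computed on the series as given: slow drift
and any global artifact count toward it, which is precisely what makes it a
useful scalar alarm.

**corr_brain.** Pearson correlation of each voxel's residual series with
the mask-average residual. The result carries the customary display
defaults (transparent threshold |r| = 0.3, color range 0.6).

**Radial correlation.** Each voxel against a Gaussian-weighted average of
its neighborhood, FWHM 20 mm by default (`sigma = FWHM/2.3548`). The weight
of a neighbor is the product of per-axis Gaussians, each truncated at
3 sigma and normalized over in-mask voxels, with the center voxel included.
Per-axis truncation (a cube, not a ball) is what makes the computation
exactly separable, so the implementation — three banded matrix contractions
per volume — agrees with a brute-force definition to machine precision
rather than approximately. As the FWHM grows the neighborhood average tends
to the mask average and the map approaches the corr_brain pattern; the test
suite asserts this at 10 times the grid extent with tolerance 0.05.

**Seed correlation.** The seed series is the mean over in-mask voxels
within a given radius (mm; radius 0 selects the seed voxel alone), and the
map is each voxel's correlation with it.

**Grayplot.** Each in-mask series is detrended (order 2 per run), Z-scored,
and clipped at the two-sided normal quantile for p = 0.001 (3.2905). The
detrend-then-Z order means the rows display residual structure rather than
drift. In similarity mode, rows are ordered by decreasing |r| with the
first principal component of the standardized data (ties broken by voxel
index), the PC sign fixed so its correlation with the mean series is
nonnegative — a reproducible concretization of "ordered by similarity".
Zero-variance voxels render as zero rows.

## Regression bookkeeping

`bandpass_df()` counts discrete Fourier bins `k/(n*TR)`, `k = 0..floor(n/2)`,
outside the passband; interior bins cost 2 degrees of freedom, the DC and
(even *n*) Nyquist bins 1, so the total over all bins is exactly *n*. The
popular 0.01–0.1 Hz band removes 154/242 = 63.6% of DFs for 242 volumes at
TR = 2 s, and 81.8% at TR = 1 s, converging to the continuum fraction
`1 - (f_high - f_low)/f_Nyquist` as *n* grows.

`df_ledger()` enforces the identity
`df_used = n_censored + df_drift + df_motion + df_bandpass + df_other`,
`df_left = n_total - df_used`. An overdrawn model (negative `df_left`) is a
severe warning, not an exception — the report must still build. When a
bandpass is requested its bins are counted on the censored series length.

`collinearity_check()` computes pairwise |r| between regressors on kept
time points only (a regressor may be innocuous overall yet degenerate after
censoring), grading at 0.4 / 0.6 / 0.8 — configurable defaults chosen to
give the usual mild/medium/severe progression; no canonical printed values
exist for these. Zero-variance columns get their own severe warning, and
the condition number of the column-normalized matrix is reported, severe on
numerical rank deficiency. The constant baseline term is exempted by the
pipeline driver (it is accounted in the ledger's drift slot instead).

`stim_censor_fraction()` defines a stimulus's response interval as the time
points where its idealized regressor is nonzero; the reported fraction is
censored-within-interval over interval size, rounded to 3 decimals. An
all-zero regressor yields NA with an `empty_regressor` flag.

`pre_steady_check()` flags leading volumes of each run whose mask-mean
intensity strictly exceeds `(1 + 0.02)` times the run's median mask-mean,
scanning until the first steady volume, at most 4 per run. The rule is an
original concretization: mask-mean against run median with a 2% relative
excess is robust to noise but deliberately simple. A slow drift of size
comparable to the excess shifts the run median and can mask marginal
pre-steady elevation — the phantom tests therefore isolate this check with
drift disabled, and real-data use should expect reduced sensitivity when
drift is strong and the excess is near threshold.

## Artifact detectors

**LPC flip check.** The local Pearson correlation cost partitions the mask
into non-overlapping 5³-voxel blocks (at least 8 in-mask voxels each) and
averages the signed within-block correlation between the two images,
weighted by block size, negated so lower is better. Identical images score
−1. `flip_check()` compares the cost of EPI vs. anatomical as-is against
the cost after mirroring the anatomical across the left-right axis
(identified from the orientation code); `DO_FLIP` requires the mirrored
cost to win by more than `tie_tol = 0.01`, otherwise ties are `ambiguous`.
No registration is performed — inputs must share a grid. This keeps the
check deterministic and desk-scale, at the price of requiring pre-aligned
inputs; data that would need re-registration per candidate is out of scope.

**Variance lines.** Through-plane scanner artifacts appear as single
in-plane columns of high temporal variance. Per voxel, the temporal
standard deviation of the detrended series is scaled to percent of the
voxel mean; per in-plane column, the score is the 90th percentile of those
values along the slice axis (the 90th percentile, rather than the mean,
keeps short bright segments detectable). A column is a detection when its
score is at least 3 times the median score in its 11×11 in-plane
neighborhood — median normalization suppresses global noise-level
differences. Adjacent detections merge, reporting the peak. All parameters
are exposed; the defaults give zero false positives on clean phantoms while
recovering 6×-amplitude planted lines essentially always.

**Intensity range.** The stored-unit (unscaled) min/max are retained at
read time precisely so these checks see on-disk values: a negative minimum
suggests conversion problems, a maximum of exactly 4095 suggests 12-bit
saturation.

**Warning levels.** All checks grade onto the ordered scale
none < undecided < mild < medium < severe; a block's level is the maximum
of its items, and the report menu colors each block by it. The default
mapping (flip `DO_FLIP` severe, any variance line medium, pre-steady
volumes medium, range flags mild) lives in `qc_warn_config()`.

## ROI statistics

`roi_depth()` computes the erosion depth of each ROI voxel — the pass at
which repeated 6-neighbor erosion removes it, with out-of-grid counting as
background. This equals the city-block distance to the nearest background
voxel, so it is implemented as an exact L1 distance transform (sequential
per-axis sweeps) and validated against a literal erosion loop. The maximum
depth `Dvox` shrinks as an ROI thins — a sensitive indicator of coverage
loss. The ROI table reports, per atlas label, voxel count, zero-statistic
count, TSNR quartiles over nonzero voxels (linear interpolation), `Dvox`,
and the coordinates of a maximum-depth voxel (ties broken by smallest
i, j, k), with graded warnings per cell; `Nzer` counts zeros of the
supplied statistic volume, not of the underlying EPI. Mask agreement uses
the Dice coefficient, with two empty masks defined as 1.

## Report and ratings

The report is a single static directory: `index.html`, PNG media, a
ratings JSON, and an `extra_info/` JSON copy of the review dictionary for
group tools. Montage slices are chosen evenly within the bounding range of
a light automask (voxels above 10% of the robust maximum); overlays use
transparent thresholding, where sub-threshold voxels keep a quadratically
decaying opacity `(|v|/thr)^2` and suprathreshold regions are outlined.
Display windows default to the 90th (threshold) and 99th (maximum)
percentiles of absolute in-mask values; t-statistic thresholds use the
two-sided tail at p = 0.001. Slice coordinates are annotated in HTML
captions beneath each montage rather than burned into the raster, which
keeps rendering free of font dependencies and byte-reproducible. Rebuilding
from identical inputs yields a byte-identical directory (no timestamps
unless requested) — determinism is part of the contract and tested.

Ratings are `+` (good), `x` (bad), `?` (other), or unset, per block plus an
overall FINAL; comments require a rating, so commenting on an unrated block
auto-applies `?`, and clearing a rating clears its comment. Repeated
rating clicks cycle `+`, `x`, `?`, back to `+`. The store is file-backed
JSON only; `×` is normalized to `x` on load.

## Group tables and filters

`build_group_table()` unions review labels across subjects in first-seen
order, keeping cells typed (number, vector, string, missing).
`report_outliers()` implements the filter operators VARY / EQ / GT / LT /
GE / LE; vector cells flag when ANY element satisfies the comparison (a
per-stimulus censor fraction exceeding a limit should flag the subject —
a compatibility assumption, documented as such). Missing cells never
satisfy an ordering comparison but always count as "varying"; surfacing
missing data is the point of a triage table. EQ uses exact matching for
strings and integers and a 1e−9 relative tolerance for floats.
`gtkyd_scan()` builds per-dataset property dictionaries (dimensions, voxel
sizes, TR, volume count, datum type, orientation, stored range with the
saturation flag, slice-timing presence) and reports every property that
varies across the set.

## The phantom generator

`phantom_spec()` describes a deterministic 4D phantom; its defaults are the
study conditions under which every detector is validated: a 24×24×16 grid
at 3 mm isotropic, TR 2 s, one 200-volume run, an ellipsoidal brain of
baseline 1000 with an asymmetric internal structure (radial falloff,
left-right gradient, one off-center blob — the asymmetry is what gives the
flip check something to detect), Gaussian noise of sd 10 (1% of baseline),
and a slow drift of roughly ±1.7% — values a 3 T EPI acquisition would not
find surprising. A dim positive "air" floor (8% of baseline) keeps stored
intensities positive, as magnitude reconstruction does.

Artifacts are planted with exact ground truth: motion spikes appear both as
one-TR steps in the parameter table and as integer-voxel in-plane shifts of
the affected volume — no interpolation, so the enorm truth and the image
effect are exactly consistent; variance lines add noise of `gain × sd`
along a full in-plane column; a coil patch adds one latent series to an
octant; a global signal of sd `s` makes the expected GCOR
`s²/(s² + noise_sd²)` (one common factor against independent noise); task
blocks add boxcar percent-signal change in a spherical region, with the
boxcar emitted as the ideal regressor; pre-steady volumes are scaled up;
`lr_flip` mirrors the anatomical. Identical spec + seed gives byte-identical
bundles (uncompressed NIfTI, for byte-stable fixtures).

What the phantom does *not* emulate: hemodynamic response shape (the ideal
regressor is the boxcar itself), physiological noise spectra, spatial
autocorrelation of thermal noise, susceptibility distortion, ghosting,
k-space artifacts, multi-echo acquisition, or real registration error.
Passing the recovery suites therefore demonstrates that the detectors
implement their definitions correctly and are sensitive at the planted
effect sizes — not that those effect sizes, thresholds, or false-positive
rates transfer unchanged to any particular scanner or population.

## Problem sizes and numerical conventions

The test and acceptance suites run phantoms of 24×24×16 voxels with 20–200
volumes, oracle comparisons on grids up to 16³, 20-seed recovery batches
for spikes, lines and flips, and 10-seed batches for GCOR — sizes chosen so
the whole suite completes in a few minutes on one CPU while leaving each
statistic comfortably powered. Voxel indices are 1-based everywhere, the
native R convention; world coordinates come only from the NIfTI affine, and
nothing is ever resampled (paired volumes must share a grid —
registration is out of scope). Quantiles are linear-interpolation type 7
throughout. Zero-variance series follow explicit conventions (TSNR 0 with
a counter, correlation 0, grayplot zero rows) rather than NaN propagation.
GCOR's estimate of a planted shared-variance fraction fluctuates with the
realized variance of the common factor (relative sd `sqrt(2/(T-1))`, about
±0.02 at one sigma for T = 200), which is why recovery is judged across
seeds rather than per seed.
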