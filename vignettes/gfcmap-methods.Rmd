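---
title: "Global functional connectivity mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global functional connectivity mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gfcmap)
```

This vignette is the package's own account of the science it implements:
the statistic, the preprocessing model, the inference procedure, what the
synthetic cohort generator does and does not emulate, and the choices made
where the design was genuinely open.

## The GFC statistic

Global functional connectivity assigns each gray-matter voxel the mean
Fisher-z-transformed Pearson correlation between its preprocessed BOLD
series and the series of every *other* voxel in the mask:

$$\mathrm{GFC}(i) = \frac{1}{N-1}\sum_{j\neq i} \operatorname{atanh}(r_{ij}).$$

Two consequences of taking the transform before the mean drive the
implementation:

* the popular shortcut — correlate each voxel with the normalized mask-mean
  series — is *not* equivalent, because $\operatorname{atanh}$ is nonlinear;
  `gfc_map()` therefore evaluates genuine pairwise correlation blocks,
  chunked so that peak memory is $O(N\cdot\text{chunk\_size} + Nt)$ rather
  than $O(N^2)$.  `gfc_map_bruteforce()` materializes the full matrix and is
  the oracle the chunked path is tested against (agreement to $10^{-10}$ on
  seeded instances; the result is independent of `chunk_size`).
* $\operatorname{atanh}$ diverges at $|r|=1$, so correlations are clipped to
  $|r|\le 1-10^{-7}$ first; a voxel pair that is numerically perfectly
  correlated contributes a large finite z ($\approx 8.1$) rather than
  infinity.

Negative correlations enter the mean as-is (signed z).  Whether to clip,
weight or drop them is a genuinely open convention in the literature; the
signed mean is the literal reading of "mean coefficient with all the other
voxels", and is what this package computes.

Zero-variance voxels carry no correlation information.  They are excluded
from both the numerator and the denominator of every other voxel's mean —
so a dead voxel does not bias its neighbours — and their own GFC is
reported as `NaN` with a warning, never silently zeroed.

The gray-matter mask is `probability > 0.2`, *strictly*: a voxel at exactly
0.2 is excluded.

## Preprocessing model

The default chain is: discard the first 10 volumes → per-voxel linear
detrend → band-pass 0.01–0.08 Hz → nuisance regression.  The field's
toolboxes disagree on the order of detrending, filtering and regression;
the order here is one consistent reading, it is recorded in the run log,
and each stage is exported separately so any other order can be composed.
All stages preserve shape after the discard, and produce no non-finite
values from finite input.

* **Band-pass.** The default is an ideal (rectangular) frequency-domain
  filter: demean, FFT, zero every bin whose two-sided frequency lies
  strictly outside [0.01, 0.08] Hz, inverse FFT.  This matches the behavior
  of the widely used resting-state toolboxes and has exactly zero gain
  outside the band; the trade-off is ringing for signals that do not align
  with FFT bins.  A zero-phase 2nd-order Butterworth (`signal::filtfilt`)
  is available via `method = "butterworth"` for users who prefer smooth
  roll-off.  The high edge must stay below Nyquist $1/(2\,\mathrm{TR})$.
* **Nuisance regressors.** Friston-24 motion expansion ($R(t)$, $R(t-1)$
  zero-padded at the first frame, and both squared), plus the mean series
  of the white-matter and ventricular compartments, plus an intercept:
  27 columns.  The global (whole-brain mean) signal is deliberately not
  offered.  Constant non-intercept columns (e.g. from an all-zero motion
  trace) are dropped with a warning; genuinely collinear designs are an
  error naming the columns.
* **Motion QC** fails a subject iff any translation exceeds 2 mm or any
  rotation exceeds 2°, strictly, measured relative to the first frame (the
  reference frame is a convention; frame 0 is ours).  **FD** is the
  Power-style sum of absolute backward differences, rotations converted to
  arc length on a 50 mm sphere; `fd[1] = 0`.  QC and FD operate on the
  trimmed trace, aligned with the retained volumes.

## Group inference

Per voxel, the three-group test is a linear-model comparison: full model
(intercept + two group dummies + age + gender + education years + mean FD)
against the model without the group dummies,
$F = \frac{(RSS_0 - RSS_1)/2}{RSS_1/(n-k)}$, df $(2,\,n-k)$.  Post hoc
contrasts fit the same covariates in the two-group subset and test the
group indicator's coefficient (t, df $n-k$, two-sided).  Covariates are
mean-centred for conditioning only; F and t are unchanged by this.
Without covariates the F reduces exactly to the textbook one-way ANOVA and
the t to the pooled two-sample t — both identities are tested to $10^{-8}$,
with `stats::lm`/`aov` as the independent reference.

Multiplicity is handled by the Benjamini–Hochberg step-up at voxel level
within the mask (the literal reading of "FDR corrected at p < 0.05");
cluster-level familywise methods (TFCE, random-field theory) are out of
scope.  Post hoc maps are corrected over the whole mask by default, with a
config switch (`posthoc_mask = "ancova"`) to restrict them to
ANCOVA-surviving voxels — published reports are often ambiguous on this
point, so it is a switch, not a guess baked in.

Clusters are connected components of surviving voxels (26-connectivity by
default, 18 and 6 available), split by sign for t maps, with no extent
threshold by default (`min_extent = 1`), since small-sample studies rarely
print the threshold they used.  Peaks are the member voxel with maximal
|statistic|, ties broken toward the lowest linear voxel index, reported in
world mm through the stored affine (voxel indices are 0-based in that
conversion).

## Clinical statistics

`anova_from_summary()` reconstructs the one-way F from printed per-group
mean ± SD and n:
$SS_b=\sum n_g(\bar x_g-\bar x)^2$, $SS_w=\sum(n_g-1)s_g^2$.  This is exact
up to the rounding of the printed summaries, which is why reconstructed
statistics are compared at 1–5% relative tolerance rather than equality.
The two-sample t is the pooled (Student) form — the printed statistics this
package reconstructs are consistent with pooling, not Welch — and the
gender test is Pearson's χ² without continuity correction (the correction
does not apply beyond 2×2 tables).  Correlation families for BH correction
are explicit user input (`subset_label`, region × variable pairs): published
corrected p-values rarely state their family size, so the package refuses to
guess silently.

## Classification

Leave-one-out SVM via libsvm (e1071): for each subject, the model is
trained on the remaining $n-1$ and predicts the held-out one.  Feature
z-scoring is computed on the training fold only and applied to the held-out
row; the test suite contains a constructed instance where whole-table
("leaky") scaling changes the predictions, so the guard is behavioral, not
aspirational.  Kernel and parameters default to the library's (RBF,
cost 1, $\gamma = 1/\text{n\_features}$) because studies that name the
library usually do not name the parameters; a linear kernel is one switch
away, and there is no nested hyperparameter tuning.  Metrics are exact
integer-count ratios rounded to two decimals at the end.

A note on permutation nulls: mean LOOCV accuracy under permuted labels sits
*below* 50% (≈0.44 in our measurements) with balanced classes.  This is the
well-known anti-learning bias of leave-one-out — removing one subject tips
the training majority toward the opposite class.  The test suite therefore
checks that permuted-label accuracy does not systematically exceed chance,
rather than demanding symmetry around 50%.

## The synthetic cohort generator

`generate_cohort()` emulates a three-group resting-state study: by default
35/17/28 subjects (S1/S0/HC), TR 2 s, 250 volumes, 3 mm isotropic voxels on
a 12³ desk-scale grid standing in for a whole-brain matrix.

Each voxel's BOLD series follows a latent-network model:
$y_v(t) = a_v\, s(t) + \varepsilon_v(t) + \text{drift}_v \cdot t$,
where $s(t)$ is a band-limited (0.01–0.08 Hz) unit-SD Gaussian latent shared
by all gray-matter voxels, $a_v$ is the network loading, and
$\varepsilon_v$ is white noise.  Inside a planted effect region, subjects of
the target group have $a_v$ scaled by $1+\delta$; $\delta>0$ raises and
$\delta<0$ lowers that region's mean connectivity with the rest of the
mask.  White-matter and ventricle compartments follow their own independent
latents (so nuisance regression has real work to do), and the linear drift
gives detrending real work.

Design constants, chosen once for realism and then left alone:

* loading 0.4, noise SD 1.0 — after band-passing, voxel-pair correlations
  come out near $r \approx 0.35$ (Fisher z ≈ 0.37), a typical magnitude for
  within-gray-matter resting-state data;
* per-subject log-normal loading jitter (SD 0.1), providing
  between-subject variance in overall connectivity strength;
* motion as a 6-parameter random walk (steps 0.02 mm, 4×10⁻⁴ rad),
  giving mean FD ≈ 0.1 mm, with optional injected spikes for QC tests;
* the tissue template is a spherical "brain" (probability 0.85, soft edge)
  covering ≈40% of the grid, with the innermost voxels designated
  ventricle (0.05) and the shell around them white matter (0.3 — above the
  0.2 mask threshold, as tissue boundaries are in real probabilistic
  segmentations);
* default planted effects: two spherical regions (radius 2.2 voxels,
  ≈30 voxels each) with $\delta = -0.5$ and $+0.5$ for group S1 — one
  connectivity reduction and one elevation, mirroring the mixed direction
  of findings in depression cohorts.

Clinical scores are drawn from truncated normals with the reference
per-group moments (see `reference_group_summaries()`), rounded to integers
and clipped to each scale's item-sum range; the controls' weight-loss and
cognitive factors are the constant 0, as printed.  The HRSD-17 total and
its five factors are drawn independently — no item-level or covariance
information is available to do better — so the synthetic total does not
equal the sum of the synthetic factors.  Gender is Bernoulli with the
reference per-group male proportions; age is truncated to the study's 18–55
inclusion range.

Every random draw flows from the single configured seed through
`substream_seed(seed, stage, subject)`, so any piece of the cohort can be
regenerated alone, and the whole bundle is byte-reproducible.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: hemodynamic response shape, physiological
(cardiac/respiratory) noise, scanner drift and artifacts, spatial
autocorrelation beyond the shared latent, registration error, and
anatomically realistic network topology.  The generator's job is to give
the GFC statistic the covariance structure the analysis assumes, with known
ground truth; it is not a biophysical simulator.

## Calibration conditions and problem sizes

The calibration checks run the full chain (generate → preprocess → GFC →
ANCOVA → FDR → clusters → post hoc signs) at these conditions:

* **Null:** 20 cohorts, 10/10/10 subjects, no planted effects, 250
  volumes.  The fraction with any FDR discovery must stay ≤ 0.20 (under the
  global null, BH's expected any-discovery rate is ≤ q = 0.05; the 0.20
  ceiling leaves Monte-Carlo room at 20 runs).
* **Effect:** 20 cohorts, 15/15/15 subjects, both default regions at
  |δ| = 0.5, 250 volumes.  In ≥ 80% of runs, every planted region must be
  overlapped by a surviving cluster whose in-region post hoc peak t has the
  planted sign.

Other tests use smaller sizes (60–120 volumes, 4–15 subjects per group,
12³ or 8³ grids) chosen so the whole suite stays desk-scale; each test
states its own size.  Nuisance regression needs more retained frames than
design columns (27), so any run with the default discard must have more
than 37 volumes.

## Known limitations

* GFC here is the dense signed-z mean; sparse/thresholded degree
  centrality, frequency-specific variants and surface-based computation are
  out of scope.
* The ANCOVA assumes a common covariate slope across groups (no
  group × covariate interactions).
* Rank-deficient designs abort rather than pseudo-inverting; a covariate
  that is constant within a two-group subset (e.g. single-gender subsets)
  must be dropped by the caller.
* The pipeline consumes motion parameters; it does not perform rigid-body
  realignment, slice timing, spatial normalization or smoothing, and does
  not scrub high-FD frames (FD is a covariate, as in the emulated design).
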