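---
title: "Simulating and analysing closed-loop network neurofeedback"
author: "rtnf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing closed-loop network neurofeedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtnf)
```

## The problem

Mindfulness-based real-time fMRI neurofeedback (mbNF) aims to teach
participants to down-regulate default mode network (DMN) activity relative to
the central executive network (CEN). A participant watches a white dot on a
vertical axis between a target circle above and a mirror circle below; every
repetition time (TR) the dot moves by the *positive diametric activity*
(PDA) — the CEN activation estimate minus the DMN activation estimate — so
mindful states (DMN below CEN) push the dot upward. Offline, the intervention
is evaluated through seed-based resting-state connectivity before and after
feedback, and through the behavioral chain *feedback performance →
connectivity change → state-mindfulness change*.

`rtnf` implements this full computational chain — personalized network
localization, the closed-loop engine, the staircase display, the
connectivity analysis and the mediation statistics — and, because no raw
data from such studies is deposited, pairs every stage with a synthetic-data
generator so that the whole pipeline is testable end to end.

## The closed-loop engine

**Incremental GLM.** Per voxel, the engine maintains running sums
$(n, \sum t, \sum t^2, \sum y, \sum ty, \sum y^2)$ sufficient to solve the
ordinary least squares of signal on an intercept and a linear drift at every
TR. The invariant — checked against a brute-force batch OLS oracle at every
TR — is that the accumulator solution equals the batch fit on all volumes
seen so far to better than $10^{-8}$.

**Scoring order.** An incoming volume is *scored* against the model fitted
to the previous volumes, then folded into the accumulators. Scoring against
a fit that already contains the new volume would shrink a fresh activation
by its endpoint leverage (about 27% one TR after onset at a 25-volume
baseline); prediction scoring reports it at full amplitude, which is what a
feedback display should do.

**Baseline scale.** The first `ceiling(30 / tr)` volumes (25 at TR 1.2 s)
form a rest baseline. When it ends, the per-voxel residual standard
deviation is frozen and becomes the activation unit; activations are
`(signal - fitted trend) / baseline SD`, averaged with uniform weights over
the binary network mask (voxels in both masks are excluded from both, with a
warning; voxels with numerically zero baseline SD contribute 0). `PDA = CEN
estimate − DMN estimate`; time in target is the fraction of post-baseline
TRs with PDA > 0.

**What the nuisance fit does to sustained signals.** Because the drift
model refits on all data, a *sustained* activation step is progressively
absorbed: the fitted line overshoots at the series end and the residual of a
constant step turns negative mid-run (we measure time-in-target ≈ 0.12 for a
pure step). This is a property of the specified estimator, not a bug — only
moment-to-moment deviations from the running baseline are fed back. The
synthetic feedback generator therefore models engagement as *episodic*
(Bernoulli per TR, or a fixed blocked schedule): bursts of mindful noting
separated by lapses. The calibration tests use the blocked 60%-duty schedule
at 2 baseline-SD differential amplitude, a clearly supra-threshold planted
effect; the generator's default (random engagement, 65% duty, 1.5 SD) is the
realistic condition and produces cohort-level time-in-target near 0.55 with
a one-tailed group test against chance around p ≈ 0.04 at n = 9.

**Staircase.** The display starts with a 12-px dot between two 56-px
circles whose centers are 472 px apart; ordinates are expressed in
circle-center units (half the center distance = one unit). The dot is
"within or beyond" a circle when its center passes the circle's near edge
(the dot's own radius is ignored — the simplest geometric reading, recorded
here as a convention). Five qualifying TRs — cumulative, not necessarily
consecutive, since that circle's last shrink — shrink the circle by 10%
(`radius = 56 · 0.9^k` exactly), reposition the dot to 0 and reset the
counter; each circle shrinks at most 5 times per run, independently. At the
cap nothing changes. The display gain (PDA → circle-center units per TR)
is not a physical constant of the paradigm; it defaults to 0.1 and is
configurable, and time-in-target is provably invariant to it. A configurable
integer TR lag between estimate and display update is available
(default 0).

## The localizer

Concatenated localizer runs are detrended per voxel and decomposed with
PCA whitening followed by symmetric FastICA (logcosh contrast, seeded random
orthogonal initialisation, deterministic sign fixed by positive skewness and
deterministic ordering by explained variance). Dimensionality is a plain
parameter (default 30, the conventional resting-state choice); no automatic
model-order selection is attempted. Components are matched to template
network maps by the absolute Pearson spatial correlation over in-brain
voxels, flipping a component's sign when its best match is negative (source
separation is sign-ambiguous). If one component wins two templates, the
template with the larger |r| keeps it and the other takes its runner-up, so
the two selected networks are always distinct. The winning map is
thresholded at its upper 10% of loadings *relative to in-brain voxels* —
exactly `ceiling(0.10 · n)` voxels, ties broken by voxel index for
determinism — and binarized into the network-of-interest mask.

## Connectivity analysis

* **Framewise displacement** is the sum of absolute frame-to-frame changes
  in the three translations plus the three rotations converted to arc
  length on a 50-mm sphere; the first frame is 0.
* **Outliers** follow the artifact-detection rule: |global-signal z| above
  threshold OR FD above threshold, with a lenient preset (5 / 0.9 mm) and a
  stringent one (3 / 0.5 mm). We take the absolute z because artifact
  detection flags deviations in both directions.
* **aCompCor**: top-5 principal components of the detrended, variance-
  normalized white-matter and CSF voxel series, per tissue.
* **Denoising** residualizes every voxel against 12 realignment regressors
  (6 parameters + first derivatives), 5 + 5 aCompCor components, linear
  drift and its first difference, and one spike regressor per outlier
  frame, then band-passes 0.008–0.09 Hz. Data *and* regressors are filtered
  to the same band before the regression: this band-limited residualization
  is equivalent to simultaneous spectral regression and makes the operation
  exactly idempotent, which a regress-then-filter ordering with unfiltered
  regressors is not. Collinear columns (the derivative of a linear drift is
  constant) are dropped with a warning. Note that the pass band holds only
  `2·T·tr·(0.09 − 0.008)` real degrees of freedom; short runs with the full
  confound set can exhaust them, so rest runs should have on the order of
  250+ volumes, which is also their real length (5 min at TR 1.2 s).
* **Seed connectivity** correlates the mean timecourse over a seed voxel
  set (e.g. an 8-mm sphere in world coordinates under the volume's affine;
  no template registration is performed) with every voxel and applies the
  Fisher z transform, capped just inside ±1; zero-variance voxels are
  zeroed and flagged. Seed voxels are not masked out of their own map.
* **Pre/post change** fits, per voxel in an a-priori search region, the
  subject-wise change on an intercept plus a centered motion covariate,
  tests the intercept, applies Benjamini–Hochberg within the region
  (small-volume correction) at q = 0.05, and reports 26-connected clusters
  — 26-connectivity being the common volumetric reporting choice.
* **Brain-behavior maps** are voxelwise partial correlations with a score,
  controlling a covariate, thresholded at uncorrected p < 0.001.
* **Reliability** uses the two-way mixed-effects, single-rater,
  absolute-agreement ICC (the standard test–retest variant, stated here as
  an assumption) with the F-test of ICC = 0.

## Behavioral statistics

Correlation, paired and one-sample t tests are implemented with explicit
degenerate-input handling (zero variance, |r| = 1) and both tails always
available; tailing is an explicit argument, never inferred. The mediation
follows Baron–Kenny: total effect c (Y ~ X), path a (M ~ X), paths b and c′
(Y ~ X + M), each with unstandardized and standardized coefficients, and the
classical Sobel test `z = ab / sqrt(b²SE_a² + a²SE_b²)` on the
unstandardized paths with a two-tailed normal p — no Aroian or Goodman
correction, which reproduces the conventional printed value from a table of
coefficients and t statistics. The exact identity
`β_c = β_a·β_b + β_c′` holds to numerical precision and is tested, as is
the agreement between the regression route and the closed-form
correlation-matrix route. A percentile bootstrap for the indirect effect is
available but off by default.

One wrinkle worth knowing: a paired t of 1.90 on 8 degrees of freedom has a
one-tailed p of 0.047 and a two-tailed p of 0.094. Reports that print
p = 0.047 while describing two-tailed tests are therefore using the
one-tailed value; both are always computed here and the caller chooses.

## The synthetic generator

Spatial maps are sums of Gaussian blobs confined to disjoint slabs of the
grid, so network supports never overlap — no anatomical template is needed
and everything stays download-free. Voxel signal is loading × timecourse
plus linear drift plus Gaussian noise, optionally AR(1) with coefficient 0.3
to mimic BOLD autocorrelation. Timecourses can be white, band-limited
("lowfreq", matching where spontaneous BOLD power actually lives — use this
for anything that will be band-pass denoised), or box-car. A helper rescales
maps so that two in-network voxels correlate at a requested level
(`amplitude = noiseSd·sqrt(r/(1−r))`). Motion is a random walk (0.01 mm
step SD) with sparse planted spikes; rotations are stored in radians and
converted to millimetres only inside the FD computation. The behavioral
generator draws X standard normal, M = aX + ε, Y = bM + c′X + ε with noise
SDs chosen so M and Y have unit variance, making a, b, c′ standardized
paths; its defaults (a = −0.67, b = −0.76, c′ = 0.18, n = 9) are the
standardized path values of the mediation model this package targets.

What the generator does *not* emulate: hemodynamic convolution,
physiological noise, k-space artifacts, spatial autocorrelation of noise,
or registration error. Passing tests therefore demonstrate the correctness
and calibration of the *computational chain*, not robustness to every
property of real scanner data.

## Problem sizes, tolerances and seeds

All tests run on small grids (8–20 voxels per axis) with runs of 40–900
volumes, chosen so the full suite completes in about a minute on one CPU:

* engine oracle: 125-volume runs, agreement < 1e−8 (observed ~1e−14);
* staircase: exact identities;
* null calibration: 1000 seeded runs, mean time-in-target within ±0.01 of
  0.5 (the Monte-Carlo standard error is ~0.0015);
* planted engagement: 200 seeds, above chance in ≥95% (observed 100%, with
  a minimum time-in-target of ~0.58);
* localizer: Dice ≥ 0.8 against the planted top-10% voxels (observed
  ≥ 0.92) on 20×20×10 grids;
* small-volume FDR: a planted Δz = −0.3 over the search region with 0.1
  noise SD at n = 9 must survive in ≥90% of 100 replicates (observed
  100%); 100 pure-noise replicates are compared against the binomial 97.5%
  envelope of the nominal 5% any-discovery rate (10/100), because the
  any-discovery probability of a correctly controlled procedure at the
  global null *equals* q, so the observed fraction is itself a
  Binomial(100, 0.05) draw;
* mediation recovery: n = 5000, each standardized path within 0.05
  (observed ~0.004).

The cohort session (`runSession`) uses 20×20×10 grids, 120-volume
localizer runs, 250-volume rest runs and a shared network geometry across
subjects (subjects are analysed in a common space, as after spatial
normalization); these are the package's scaled study conditions and are
stated in the function's documentation.

## Known limitations

* The decomposition is a compact FastICA; it recovers well-separated
  planted networks but is not a replacement for a full ICA toolbox
  (no automatic dimensionality estimation, no multi-session tensor modes).
* Seed spheres assume the volume's affine maps voxels to the seed's world
  coordinate frame; no registration is performed.
* The feedback delay of a real scanner chain (reconstruction + transfer) is
  modelled only as an optional integer TR lag.
* FDR cluster reporting uses hard 26-connectivity on the surviving voxel
  set; no cluster-extent inference is implemented.

## A short tour

```{r tour, eval = FALSE}
maps <- makeNetworkMaps(c(20, 20, 10), 2, 3, seed = 7)
tc <- networkTimecourses(120, 2, betweenR = -0.3, seed = 1)
run <- simulateRun(lapply(maps, function(m) 3 * m), tc,
                   driftSlope = 0.02, noiseSd = 1, seed = 2)
masks <- localizeNetworks(run$series,
                          templates = list(DMN = maps[[1]],
                                           CEN = maps[[2]]),
                          nComponents = 5, seed = 3)
fb <- simulateFeedbackSeries(masks$DMN, masks$CEN, seed = 4)
eng <- initEngine(masks$DMN, masks$CEN, tr = 1.2)
res <- runFeedbackRun(eng, fb$series)
timeInTarget(res)

sess <- runSession(seed = 42)
sess$mediation
```
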