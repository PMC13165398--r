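---
title: "Methods: from keypoint tracks to life stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from keypoint tracks to life stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behaviorome)
```

This vignette is the package's own account of its models and the choices
behind them: what each stage assumes, which parameters matter (with units
and defaults), what the synthetic world does and does not emulate, and
how degenerate inputs are handled. It states no empirical result that the
test suite and acceptance script do not themselves compute.

## 1. The recording world

The package is built for continuous overhead recordings of individually
housed fish: 20 frames per second, 24 h per day, a 12 h light / 12 h dark
cycle, seven feedings at fixed clock times during the light phase, and a
tracker that reports six body keypoints (snout, midbody, endbody, tail,
fan, sidebody) in tank coordinates with the origin at the bottom-left
corner. These constants live in `simConfig()`: one day is 1,728,000
frames, divided into 144 ten-minute bins of 12,000 frames each. All other
stages inherit them.

## 2. Pose features (57 per frame)

`assembleFeatures()` computes 39 base features per frame and expands them
to 57 columns by trailing rolling statistics over 10 frames: a rolling
mean of all 39 plus a rolling standard deviation of the 18 kinematic and
shape features (five keypoint speeds, snout acceleration, dispersion,
bounding area, normalized body length, tail–fan proportion, the four
interior body angles, the three tangent curvature angles, and the
heading–velocity dot product). The base list: ten coordinates (the five
reliably visible keypoints), five speeds, snout acceleration, dispersion,
bounding area, day-normalized body length, tail–fan proportion, six
visibility counts, snout distance to the nearest wall, heading angle,
four interior angles, three signed curvature angles, the reversal triple
(dot product, backward-speed magnitude, binary flag), and behavioral
sleep. The 57-column total is a fixed contract of the
feature schema; the mean/SD allocation itself is a package decision, held
in one config table (`BASE_FEATURES` / `SD_FEATURES`) so it can be
swapped without touching any other code.

Parameter notes, with defaults from `poseConfig()`:

* **Jitter filter** (`filterB`, default a 5-tap causal moving average
  summing to 1). Keypoint jitter would otherwise dominate frame-to-frame
  differences. The filter treats pre-recording history as the first
  observed value, so a stationary animal has exactly zero velocity — a
  zero-padded causal filter would invent a startup transient.
* **Velocities** are differentiated against timestamps, not frame
  counts, so units are px/s and dropped frames do not corrupt speeds.
* **Dispersion** (`dispersionWindow` = 40 frames = 2 s) is the area of
  the circle whose diameter is the diagonal of the axis-aligned bounding
  box of recent snout positions: area = pi((dx^2 + dy^2)/4). This
  box-extremes rule upper-bounds the exact minimum enclosing circle (a brute-force minimum-enclosing-circle
  implementation exists in the test suite as an oracle, and coincides for
  collinear and rectangular point sets). Windows are trailing and
  truncated at the recording start rather than dropped.
* **Sleep** (`sleepDispersionThreshold` = 50 area units,
  `sleepMinDuration` = 60 s): frames below the dispersion threshold are
  inactive; a maximal inactive run lasting at least one minute (>= fps x
  60 frames, so a 90 s bout labels exactly 1800 frames at 20 fps) is
  sleep in its entirety. The threshold is
  interpreted in the same units the dispersion is computed in, and it is
  config-exposed.
* **Curvature sign**: tangent angles at midbody/endbody/tail are
  measured against heading (midbody to snout) and are positive when the
  tangent points to the animal's left, i.e. counterclockwise in tank
  coordinates. The sign flips under mirror reflection, which the tests
  assert against a cross-product oracle.
* **Missing keypoints**: any feature needing an invisible keypoint is
  missing for that frame; rolling statistics ignore missing values when
  at least half the window is present, else they are missing. The
  sidebody keypoint contributes only a visibility count — its annotation
  rate in overhead recordings is too low to support geometry.
* **Day-level normalization** (bounding area, body length) uses the
  calendar recording day; a degenerate day (zero mean) skips
  normalization and is flagged rather than producing NaNs.

`reduceToPCs()` z-scores the features (constant columns dropped with a
warning and recorded in the model), projects onto the top 15 components,
and smooths scores with a 10-frame trailing moving average.
`linearSeparability()` scores day/night or age separability as stratified
5-fold cross-validated accuracy of a linear max-margin classifier
(squared hinge loss fit by L-BFGS — no SVM library is assumed) on the top
five PCs.

## 3. Behavioral syllables: Gaussian HMM by stochastic EM

`stochasticEMFit()` fits the K-state Gaussian HMM (default K = 100 at
full scale; tests use small K) to the smoothed PC sequence. Design
choices, each config-exposed because more than one reasonable option
exists:

* **Blending space.** The Robbins–Monro convex combination is applied to
  expected sufficient statistics (normalized per frame), not to the
  constrained parameters; the M-step then re-derives parameters, so
  transition rows remain stochastic and covariances remain PSD by
  construction.
* **Step sizes.** rho_1 = 1 (the first update adopts the first batch's
  statistics — required for the single-batch equivalence below), then
  rho_t = (t + 2)^(-0.6), which satisfies the Robbins–Monro conditions.
* **Initialization.** k-means on a subsample (default 10,000 frames,
  5 restarts) for means, shared diagonal covariance from the pooled
  data, uniform start distribution, sticky (0.95) transitions. The seed
  is recorded in the fitted model's metadata.
* **Numerics.** Forward–backward uses per-frame scaling plus a per-frame
  max shift of the log emission densities, so million-frame streams do
  not underflow. Covariances carry a ridge (default 1e-6); a state whose
  expected count falls below one frame is "starved" and its covariance
  is reset to the global covariance, with a logged message.
* **Equivalence anchor.** With one batch covering all data and rho = 1
  throughout, the iterates coincide with full-batch Baum–Welch; the test
  suite asserts this against an independent log-space implementation.
* **Decoding** is by posterior mode per frame (streaming-friendly), with
  Viterbi as an option.

`selectNumStates()` scores held-out animals (train/validation animal sets
must be disjoint) and selects the smallest K within a tolerance (default
0.02 nats/frame) of the maximum — the plateau rule.
`clusterSyllables()` orders syllables by average-linkage agglomerative
clustering of the closed-form symmetrized Gaussian Kullback–Leibler
divergences between emission distributions.

## 4. The behaviorome tensor and its decomposition

`binUsage()` counts decoded syllables in 10-minute bins;
`normalizeUsage()` rescales each syllable's usage to [0, 1] across the
whole dataset (empirical min by default; a flag can force the minimum to 0 — the
choice only shifts constant offsets into the factors). `fitNonnegCP()` minimizes masked
squared error by HALS with random non-negative restarts (default 3;
500-sweep cap, relative tolerance 1e-7); held-out entries are handled by
expectation-style imputation — each sweep replaces them with the current
reconstruction — so they provably never influence the fitted factors
(asserted by perturbing held-out entries in the tests). Time and
syllable factor columns are unit-normalized with all magnitude absorbed
into the age factors, making age-factor amplitudes comparable across
days; components are ordered by reconstruction contribution. The error
metric is the squared-Frobenius residual over the squared-Frobenius data
— a fraction-of-unexplained-variance analogue in [0, 1].

`crossValidateRank()` holds out 50% of (time-bin, animal-day) fibers and
selects the smallest rank whose *relative* test-error improvement falls
below 10%. The improvement tolerance is relative, not absolute, because
the error metric is itself normalized: an absolute tolerance would track
the noise floor, not the "improvement becomes marginal" reading the rule
formalizes. One decomposition is shared across all animals (animal-days
concatenated on the third mode); full runs default to R = 45 components,
tests use small R.

## 5. Clocks, forecasts, survival

All supervised analyses are leave-one-fish-out: every day of the held-out
animal is predicted by a model that saw none of that animal's days, and
the per-fold training sets are recorded so the property is auditable.
With no tree-ensemble package assumed present, the package carries a
small bagged CART implementation (variance impurity, per-node feature
subsampling, bootstrap aggregation, mean-decrease-in-impurity
importances). For 0/1 labels variance impurity equals Gini/2, so the
same trees serve the classifier as a probability forest. Defaults: 100
trees in tests, 500 for full-scale runs; mtry = p/3 for regression,
sqrt(p) for classification.

* `fitBehaviorClock()` reports pooled Pearson R over held-out
  (true, estimated) pairs, per-age median absolute error, and
  importances from an all-animal model. `agingRate()` fits per-animal
  OLS slopes of estimated on true age; groups are compared by a
  two-sided Mann–Whitney test.
* `forecastLifespan()` builds one classifier per prediction age.
  Features are the mean age factors over ages in (age - 5, age] — days
  with no recording are dropped, not imputed; animals dead before the
  prediction age, or with no day in the window, are excluded, as are
  extreme agers (> 300 days). Long-lived means lifespan >= 200 days
  (inclusive). Features are z-scored by each fold's training statistics,
  which makes predictions exactly invariant to feature rescaling.
* `survivalCompare()` delegates Kaplan–Meier estimation and the log-rank
  test to the survival package; removal before natural death is
  right-censoring, and an all-censored comparison is reported as
  undefined rather than silently dropped. `differentialUsage()` applies
  Mann–Whitney per (age, factor) with Bonferroni correction over the
  factors tested at that age (m = R per age, matching the per-age
  testing loop, not factors x ages).

## 6. Life stages

`dailyUsage()` / `dailyUsageFromTensor()` build the 200-element daily
vector: time in each of 100 syllables in the light period, then in the
dark period. Divergences between days use the discrete symmetrized
Kullback–Leibler divergence with a pseudocount of 1 frame per cell before
normalization — without smoothing, any syllable used on one day and not
another would make the divergence infinite; the pseudocount is config.
The day-matrix route normalizes to probability distributions first
(entropy on unnormalized totals is ill-defined).

`detectChangePoints()` smooths the daily vectors along age (Gaussian,
sigma = 1 day), z-scores per dimension, and segments by exact dynamic
programming on the Gaussian-kernel scatter cost with penalty c·ln(L) per
segment (L = recorded days), so the penalty scales identically with
log-lifespan across animals. The kernel bandwidth is the median pairwise
squared distance. The constant c is calibrated on synthetic cohorts:
because the RBF kernel is bounded by 1, the
attainable cost reduction from a true split grows like a bounded
fraction of the segment length, and a large c (e.g. 10) would reject
real transitions at realistic lifespans. On seeded staged and stationary
cohorts, c = 1 recovers ~94% of true transitions within +/-2 days with
zero spurious detections on stationary lives; c is config-exposed, and
the change-point count is monotone non-increasing in it (asserted in the
tests).

`fitStageModel()` fits a full-covariance Gaussian HMM (default six
stages; diagonal covariance would change the supported stage count, so
covariance structure is config) to smoothed (sigma = 1 day), globally
z-scored age factors, each animal one sequence, with k-means
initialization and a fixed 20 EM iterations. Stages are renumbered by
the mean age of their member days, so "forward" is well-defined;
animals with fewer than two days are excluded with a warning.
`selectNumStages()` applies the plateau rule on held-out animals with a
tolerance of 0.1 nats/day — deliberately above the small held-out gains
that extra states earn by modeling smoothing-induced boundary days, and
well below the gain of a genuine stage. `stageSummaries()` reports the
empirical transition matrix (self-transitions included; rows of
unvisited stages are missing, not zero), bout durations in days,
per-stage median binned usage profiles, and the closed-form emission
divergence matrix.

## 7. The synthetic world

`simulateTrack()` scripts swim bouts from six kinematic modes (rest,
drift, cruise, burst, reversal, glass-surfing along a wall), lays a
rigid-segment body behind the snout along the heading, adds i.i.d.
isotropic Gaussian keypoint jitter (default 0.5 px — small relative to
the sleep dispersion threshold, so resting frames score below it), and
makes the sidebody keypoint rarely visible to exercise missing-data
paths. Tracker error
distributions vary by rig and model, so jitter is a free knob, not a
calibrated quantity.

`simulateSyllableCohort()` draws lifespans from a two-component Gaussian
mixture (means 250 and 150 days, SD 30, equal weights, truncated at 30
days — a bimodal long/short world, not a claim about any empirical
lifespan distribution), assigns days to forward-only stages with
shifted-geometric dwells (mean 60 days by default — the simplest
forward-only semi-Markov structure consistent with long stable stages),
and draws each bin's syllable counts multinomially from integer
per-stage templates whose columns sum exactly to the frames per bin, so
conservation is exact and the zero-noise limit reproduces the template
verbatim. Templates have circadian structure (rest-dominated dark phase,
seven Gaussian feeding bumps at fixed light-phase bins), decline in
activity across stages, rotate preferred syllables per stage, and differ
between the long- and short-lived groups in light-phase inactivity and
peak-activity weights.

What the generator does **not** emulate — and hence what a green test
does not establish: tracker error beyond i.i.d. jitter and missingness
(no identity swaps, no autocorrelated drift), within-stage behavioral
drift (days within a stage are exchangeable draws), individual
variability beyond the two groups, and any coupling between the
keypoint-level and tensor-level worlds (they are generated at their own
levels). Recovery rates measured on it are statements about the
estimators under the stated model, not about biological recordings.

## 8. Known limitations

* Full-scale runs (100 states over hundreds of millions of frames,
  45 components over tens of thousands of animal-days) are exercised at
  reduced scale only; defaults keep the full-scale constants, but all
  large fits in the tests use small K and R.
* HALS for the non-negative decomposition is locally convergent;
  restarts mitigate but do not eliminate local minima (the full-rank
  reconstruction test allows a small residual for this reason).
* The stochastic-EM held-in likelihood trace is per batch and is not
  monotone when batches are shuffled; monotonicity is only guaranteed
  (and only asserted) on the single-batch rho = 1 path.
* Serialization uses CSV/JSON rather than a binary store; at full scale
  a hierarchical binary format would be preferable, but the text formats
  keep every artifact inspectable and diffable.
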