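# behaviorome

Lifelong behavioral aging analysis from 2-D keypoint tracks, for
researchers who continuously record individually housed animals (the
package's stated world is the African turquoise killifish, filmed from
above at 20 frames per second on a 12 h light / 12 h dark cycle) and want
to turn those recordings into quantitative statements about aging:
behavioral syllables, daily "behaviorome" summaries, behavioral clocks of
age, forecasts of future lifespan, and discrete life stages.

## The models at the core

**Pose features and syllables.** Six body keypoints per frame (snout,
midbody, endbody, tail, fan, sidebody) are turned into a 57-dimensional
per-frame pose feature vector (coordinates, velocities, dispersion, body
angles and curvature, reversal scores, behavioral sleep, and their
10-frame rolling statistics), z-scored, reduced to 15 principal
components, and smoothed. A K-state Gaussian hidden Markov model over
these PCs defines the behavioral syllables: emission
x_t | z_t = k ~ N(mu_k, Sigma_k) with transition matrix A. Because whole
lifespans produce billions of frames, the HMM is fit by *stochastic EM*:
expected sufficient statistics from contiguous batches of B frames are
blended by a Robbins–Monro schedule rho_t, bounding memory by the batch
size rather than the stream length; with one batch and rho = 1 the
iterates equal full-batch Baum–Welch exactly.

**The behaviorome tensor.** Decoded syllables are counted in 144
ten-minute bins per day (12,000 frames per bin at 20 fps), min–max
normalized per syllable, and arranged as an N x T x K tensor
(syllables x time-of-day x animal-days). Non-negative canonical polyadic
decomposition approximates it as a sum of R rank-1 outer products of
time-of-day factors, syllable factors, and *age factors* — the per-day
amplitude of each joint circadian-behavioral pattern. Rank is chosen by
cross-validation on 50% held-out time bins.

**Clocks, forecasts, life stages.** Leave-one-fish-out tree ensembles
regress age on the daily age factors (the behavioral clock; per-animal
slopes of estimated vs. true age measure the rate of aging) and, at fixed
prediction ages, classify animals as short- or long-lived (threshold 200
days; >300-day extreme agers excluded), validated by ROC AUC and
Kaplan–Meier / log-rank separation of the predicted groups. Day-to-day
change is quantified by the symmetrized Kullback–Leibler divergence of
200-element light/dark syllable-usage vectors; penalized Gaussian-kernel
change-point detection (penalty c·ln L for an L-day life) finds discrete
behavioral transitions, and a forward-ordered Gaussian HMM over smoothed,
z-scored age factors assigns each day to one of six life stages.

A fully seeded synthetic generator produces keypoint tracks with scripted
swim modes and lifelong usage cohorts with known lifespans, stage
sequences, and transition days, so every estimator is testable against
ground truth without any recordings.

## Worked example

Simulate a 12-animal lifelong cohort with 3 life stages, factorize its
usage tensor, fit the behavioral clock, and detect one animal's life-stage
transitions:

```r
library(behaviorome)

cohort <- simulateSyllableCohort(
  nAnimals = 12,
  spec   = cohortSpec(nStages = 3, separation = 2),
  config = simConfig(seed = 1, nSyllables = 30, nBinsPerDay = 48))
tensor <- normalizeUsage(cohort$tensor)
model  <- fitNonnegCP(tensor, R = 5, seed = 1, nRestarts = 2, maxIter = 150)

series <- ageFactorSeriesFromCP(
  model, tensor, setNames(cohort$truth$lifespans, cohort$truth$animals))
clock  <- fitBehaviorClock(series, nTrees = 100, seed = 1)

usage <- dailyUsageFromTensor(cohort$tensor)
ad    <- animalDays(cohort$tensor)
rows  <- which(ad$animal == "fish001")
cp    <- detectChangePoints(usage[rows[order(ad$age[rows])], ])
```

Output:

```
UsageTensor: 30 syllables x 48 bins x 2478 animal-days; 36000 frames/bin (normalized)
CPModel: rank 5 ; train error 0.0369 (not converged)
behavioral clock: held-out Pearson R = 0.749
median absolute error = 31.0 days
fish001 change points (days): 27 72
fish001 true transitions    : 29 70
```

Reading the numbers: the rank-5 decomposition leaves ~3.7% of the usage
variance unexplained ("not converged" means the HALS solver hit its sweep
cap, not that the fit is unusable); the leave-one-fish-out clock estimates
a held-out animal's age with Pearson R = 0.75 and a median error of ~31
days on this small noisy cohort; and the kernel change-point detector
places fish001's two stage transitions within two days of the generator's
ground truth (days 29 and 70).

## Acceptance script

`scripts/acceptance.R` re-runs the complete pipeline from scratch on a
seeded synthetic cohort — track simulation, the 57-feature assembly and
PC reduction, stochastic-EM syllable fitting and decoding, usage-tensor
construction and non-negative CP factorization, change-point detection,
and life-stage modeling — verifies that every stage produced its
artifact, and writes the results manifest:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Further reading

The methods vignette (`vignettes/behaviorome-methods.Rmd`) documents the
model assumptions, every tunable parameter with its unit and default, what
the synthetic world does and does not emulate, and the numerical choices
(tolerances, initialization, tie-breaking, degenerate inputs).
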