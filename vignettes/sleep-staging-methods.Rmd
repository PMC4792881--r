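---
title: "Unsupervised sleep staging with sleepHMM: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised sleep staging with sleepHMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepHMM)
```

## Overview

`sleepHMM` segments rodent EEG/EMG recordings into Wake, NREM and REM
without scored training data. The pipeline has four stages — per-epoch
band-power features, two-stage k-means clustering into the three vigilance
states, vector quantization of the feature space onto a small codebook, and
a discretized-observation hidden Markov model decoded by the Viterbi
algorithm. This vignette explains each model, its assumptions, the tunable
parameters, and the design decisions taken where reasonable alternatives
existed.

## Feature extraction

Three features are computed in every scoring epoch (4 s by default), after
isolating each frequency band with a zero-phase 3rd-order Butterworth
filter applied to the whole channel before epoching:

| feature    | definition                                       | role |
|------------|--------------------------------------------------|------|
| `emg_rms`  | r.m.s. of EMG filtered to 80–100 Hz              | muscle tone: high in Wake |
| `dt_ratio` | mean-squared EEG power, 0.5–4 Hz over 6–9 Hz     | delta vs theta: high in NREM, low in REM |
| `hl_ratio` | mean-squared EEG power, 9–45 Hz over 0.5–9 Hz    | separates REM further |

Filtering once per channel, rather than per epoch, avoids filter transients
at every epoch boundary. Zero-phase (forward–backward) application means
the effective magnitude response is the squared single-pass response; the
package's analytic tests account for this. A trailing partial epoch is
discarded, never padded, so the epoch count is always
`floor(N / (fs * epochS))`.

Each feature series is then smoothed with a trailing moving average over
`smoothWindow = 4` epochs (16 s) and natural-log transformed
(`smoothAndLog()`). Three decisions deserve comment:

* **Trailing, not centered, smoothing.** A 4-point window has no symmetric
  center, and a causal window permits online scoring; the first
  `window - 1` epochs use shrinking windows so output length equals input
  length.
* **Smooth-then-log order.** Averaging raw powers before the log is the
  default; the reverse order is available via `smoothFirst = FALSE` and
  changes results only marginally since both are monotone.
* **Flooring.** Band powers and pre-log values are floored at 1e-12
  (squared microvolts), so silent channels yield finite features rather
  than divisions by zero. The floor only engages on degenerate input.

Two useful invariances follow from the construction and are verified in the
test suite: rescaling the EMG channel by k shifts the smoothed-log
`emg_rms` by exactly ln(k) and leaves the EEG ratios unchanged, and the
two EEG ratios are invariant to rescaling of the EEG channel. (The latter
holds to roughly 1e-6 relative precision rather than machine epsilon: the
0.5 Hz band edge puts filter poles very close to the unit circle, which
amplifies rounding differences in the IIR recursion.)

## Two-stage clustering

Rather than clustering all three features jointly, the state partition is
built in two 1-D stages, each a k-means (k = 2) with k-means++ seeding:

1. on `emg_rms`: the cluster with the **higher** centroid is Wake (muscle
   tone), the other is sleep;
2. on `dt_ratio`, within sleep only: the **higher** centroid is NREM
   (delta-dominant), the lower REM.

The mapping is data-driven (by centroid order), never by cluster index, so
it is invariant under monotone rescaling of an axis. The two-stage design
matches how a human scorer works (EMG first, then EEG within sleep) and is
much harder to derail than a free 3-D clustering, which can split along an
uninformative direction.

For out-of-sample scoring, per-state centroids are computed in
*standardized* 3-D space (per-feature z-scores with the training sample's
mean and standard deviation) and new epochs are labeled by the nearest
centroid (`assignStates()`). Standardization is needed because log-EMG
power and log-ratios are not commensurate; the training constants are
stored in the model so scoring is reproducible. Ties go to the state
earliest in the fixed (WAKE, NREM, REM) order.

k-means itself (`kmeansFit()`) is Lloyd's algorithm from k-means++ seeds,
best of 10 restarts by within-cluster sum of squares, at most 300
iterations, deterministic given its seed. Empty clusters are re-seeded at
the point farthest from its nearest centroid. The implementation is checked
in the tests against direct-summation oracles and against the
nearest-of-true-means rule on separated Gaussians.

## Codebook and variance criterion

The observation space of the HMM is a vector-quantization codebook: k-means
with M clusters in standardized feature space, for M = 3…15, keeping the
smallest M whose **variance criterion** reaches 0.90. We define VC as
explained variance,

$$\mathrm{VC} = \frac{\mathrm{SSB}}{\mathrm{SST}} = 1 - \frac{\mathrm{SSW}}{\mathrm{SST}},$$

which increases toward 1 as clusters tighten; a threshold of 0.90 reads as
"the partition explains 90% of the feature variance". If no M ≤ 15 reaches
the threshold — which happens when within-state noise is large — the
largest M is returned with `thresholdMet = FALSE` and a warning; the
pipeline proceeds normally, since a capped codebook still quantizes the
space usefully. The codebook k-means runs on all three features;
restricting it to a subset is possible in principle but was not needed.

## The discretized-observation HMM

The HMM has the three vigilance states as latent states and the M codebook
symbols as observations:

* `A` (3×3) — transition probabilities, initialized from relative
  frequencies of transitions in the two-stage k-means labels;
* `B` (3×M) — per-state symbol distributions, initialized from symbol
  counts within each state;
* `pi` — initial distribution. The choice is essentially inconsequential
  for long recordings; the default is the stationary distribution of `A`,
  with an empirical first-state indicator available via
  `piMode = "first"`.

All probabilities are floored at `floorProb = 1e-6` and rows renormalized,
after initialization and after every Baum–Welch M-step. Without the floor,
a symbol never seen in some state during fitting would receive probability
zero and could make an out-of-sample sequence impossible to decode; with
it, novel symbols merely become very unlikely. A state entirely absent from
the training labels gets uniform rows and a warning.

Baum–Welch refinement (`baumWelch()`, on by default, mirroring the
user-facing on/off option) uses the scaled (normalized) forward–backward
recursions for the E-step — numerically stable without leaving probability
space — and closed-form M-steps; `pi`, `A` and `B` are all re-estimated.
Iteration stops when the relative log-likelihood improvement falls below
`tol = 1e-6` or after `maxIter = 500` iterations. The log-likelihood trace
is non-decreasing (the EM guarantee; asserted in the tests with 1e-9
slack — the flooring step can in principle perturb it, but in practice the
floored entries are far below the scale of EM's improvements). Viterbi
decoding runs in log space with backtracking; ties break toward the
earliest state. The forward, backward, E-step and Viterbi inner loops are
implemented in C++ (Rcpp), as is usual for HMM code, since they are
inherently sequential in time.

The initializer is always the two-stage k-means guess; multiple random
restarts of Baum–Welch are deliberately not offered, as the structured
initial guess makes the EM landscape benign and random restarts add run
time without benefit here.

## Sleep metrics and scorer comparison

A **bout** is a maximal run of consecutive epochs in one state; bouts tile
the hypnogram exactly, and boundary runs count as full bouts (no
truncation or merging across brief interruptions is performed). Per state,
`sleepMetrics()` reports percent time, bout count and mean bout duration in
seconds; a state with no bouts gets `NA` duration — "no bouts" must remain
distinguishable from "zero-length bouts" in downstream plots.

`agreement()` computes the reference-by-predicted confusion matrix, overall
percent agreement, and one-vs-rest sensitivity and specificity per state.
`compareScorers()` assembles, across a cohort, the signed errors of both
scorers (nearest-centroid k-means and HMM) in each metric and state, with a
Wilcoxon signed-rank test of each error distribution against zero
(`stats::wilcox.test`: exact null distribution for small cohorts without
ties, mid-ranks otherwise) and the Spearman rank correlation between
predicted and reference metric values.

## Synthetic data: what it emulates, and what it does not

The generators produce ground-truthed data with exactly the statistical
structure the method assumes:

* `simulateHypnogram()` — a 3-state Markov chain. The Light-period preset
  (`lightChain()`) has diagonal-dominant rows with stationary distribution
  ≈ 35/55/10% for Wake/NREM/REM and mean dwell times of roughly 85/108/39 s
  at 4-s epochs; the Dark preset (`darkChain()`) spends ~72% awake with
  REM under 2%, reproducing the REM-scarcity regime in which unsupervised
  models struggle to estimate the REM distribution.
* `simulateFeatures()` — per-state Gaussian features with diagonal
  covariance on the smoothed-log scale. The default preset separates the
  state means by about 8.6 within-state standard deviations on their
  discriminating axes (Wake vs sleep on EMG; NREM vs REM on delta/theta):
  clearly separable clusters with overlapping tails, matching the cluster
  geometry of good-quality real recordings. `noiseScale` rescales all
  standard deviations; at 2.5 the separation drops to ~3.4 sd and
  per-epoch misclassification by nearest centroid becomes frequent enough
  to fragment bouts — the regime used to demonstrate the value of modeling
  dynamics.
* `simulateRaw()` — state-conditioned signals realizing the spectral
  contrasts the features measure: EEG sinusoids at 2 Hz (NREM, amplitude
  3), 7 Hz (REM, amplitude 2) and 12 Hz (Wake, amplitude 1) plus white
  noise (sd 0.5), and band-limited (10–100 Hz) white-noise EMG with
  amplitude 2.0 in Wake versus 0.3 in sleep. Fixed mid-band sinusoid
  frequencies were chosen over stochastic narrowband processes because
  they make the expected band-power ratios analytically predictable.
* `simulateCohort()` — per-subject generators jittered multiplicatively
  (each transition, mean and sd entry scaled by an independent
  `1 + U(-jitter, jitter)`, default 5%), emulating inter-animal
  variability; 18 subjects is the default cohort size.

Passing tests on these fixtures shows the algorithmic machinery is correct
and that the pipeline solves the problem class it assumes: Markovian state
dynamics and roughly Gaussian, stationary state-conditional features. Real
recordings violate these assumptions in known ways — non-geometric dwell
times, drift in electrode contact, spindles/K-complexes and 1/f background,
movement artifacts — so synthetic accuracy is an upper bound, not a
forecast, of field performance.

## Numerical choices and degenerate inputs

* Probability floor 1e-6; power/log floor 1e-12; both configurable only
  where it matters (`floorProb`).
* All stochastic steps take explicit seeds and run on a private RNG stream,
  leaving the caller's RNG state untouched; equal seeds give bit-identical
  results.
* Nearest-centroid distances are computed by direct differencing (not the
  expanded quadratic form), so symmetric configurations tie exactly; ties
  always resolve to the lowest index / earliest state.
* Degenerate inputs fail loudly and early: fewer distinct points than
  clusters, recordings shorter than one epoch, bands outside Nyquist,
  symbol indices outside the codebook, misaligned hypnograms.
* Problem sizes in the tests and the acceptance script — e.g. a 12600-epoch
  (14-h) recording for pipeline recovery, 20000 symbols for parameter
  recovery, an 18-subject × 5400-epoch cohort for the scorer comparison —
  were chosen as the smallest sizes at which sampling error is comfortably
  below the quantities being measured.

## Known limitations

* Exactly three states; brief arousals and prolonged Wake share one state,
  so genuine micro-arousals may be absorbed into sleep by the HMM's
  smoothing — the flip side of suppressing false arousals.
* Geometric dwell-time distributions are implied by the first-order Markov
  assumption; explicitly modeled dwell times are out of scope.
* Features are fixed band-power ratios; no artifact rejection or multi-EEG
  montages.
* Cross-animal transfer is not supported by design: EMG power depends
  strongly on electrode placement, and centroids fitted to one animal need
  not transfer to another.
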