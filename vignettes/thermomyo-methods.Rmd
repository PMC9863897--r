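---
title: "Estimating EMG activity and fatigue metrics from skin-temperature features: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating EMG activity and fatigue metrics from skin-temperature features: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermomyo)
```

## The problem

Surface electromyography (sEMG) is the standard way to quantify muscle
activation and fatigue, but it needs gelled skin electrodes. Two scalar
summaries carry most of the physiological meaning:

* **ARV** (average rectified value), $\mathrm{ARV} = \frac{1}{N}\sum_n |EMG[n]|$,
  an amplitude descriptor tracking activation level; and
* **MDF** (median frequency), the frequency splitting the EMG power spectrum
  into equal-power halves, which drifts downwards as the muscle fatigues.

Skin temperature above a working muscle co-varies with its activity through
superficial perfusion. `thermomyo` implements a contactless estimation
pipeline: nine features of the infrared-imaged skin-temperature time course
of regions of interest (ROIs) over the muscle predict per-series ARV and
MDF through cross-validated regression, with subject-level generalization
enforced by leave-one-subject-out (LOSO) folds. Because the reference
human recordings are not publicly deposited, the package also ships a
synthetic cohort generator with a known, tunable EMG–thermal coupling;
every statistical claim the test suite makes is made against that stated
world.

## EMG measurement path

The raw trace (250 Hz) is high-pass filtered at 20 Hz with a 3rd-order
Butterworth filter applied forward and backward (zero phase lag). We design
the filter by bilinear transform and initialize each pass at its step
steady state, so a constant input produces no startup transient; edges are
protected by odd-reflection padding of three filter lengths. ARV is the
mean of the rectified filtered trace over the whole series — series length
varies with the subject's endurance, and each series is averaged over its
own length. MDF is computed from the *unrectified* filtered trace:
rectification halves-and-folds the spectrum, and the amplitude path is the
only place rectification is meaningful. The spectrum is estimated by
Welch's method (Hamming window, segments of `min(N, 1024)` samples, 50%
overlap) with the FFT length set to the next power of two at or above the
trace length; the reported MDF is the first frequency bin at which the
cumulative power reaches half the total. The lowest-index rule matters: on
a discrete spectrum the textbook equal-halves equality is generically
unattainable, so a deterministic tie-break is required for reproducibility,
and tests assert the half-power property directly on the returned bin.

## Thermal features

Features are extracted from a 10 s window (100 samples at 10 Hz) starting
at the end of each exercise series — immediately post-exercise, where the
subject is still and motion artifacts are minimal. Per window:

| feature | definition | notes |
|---|---|---|
| `mean_temp` | mean of the window, °C | level descriptor |
| `std` | SD with $1/(N-1)$ | |
| `mean_psd` | mean one-sided periodogram over positive-frequency bins | DC excluded so the feature reflects oscillation, not level; a 100-sample window leaves no room for Welch segmenting |
| `kurt`, `skew` | non-excess standardized moments, $1/N$ central moments over $\mathrm{STD}^{4,3}$ | undefined on constant windows (flagged) |
| `p90` | empirical 90th percentile, linear interpolation between order statistics | interpolation rule fixed so oracle tests are exact |
| `sampen` | sample entropy, $m=2$, $r=0.2\,\mathrm{SD}$, $\tau=1$, Chebyshev metric, self-matches excluded | tying $r$ to the window SD makes it amplitude-invariant |
| `grad` | mean central-difference gradient magnitude over interior pixels of an 8×8 patch, averaged over window frames, °C/pixel | the temporal aggregation (per-frame mean, then window mean) is our choice; the spatial operator alone does not define a scalar per series |
| `delta` | mean of first 2 s − mean of last 2 s | post-exercise trend; for a linear ramp of slope $s$ °C/s it equals $-8s$ |

Undefined features (constant window, missing patches, no entropy matches)
are flagged `NA`; rows carrying flagged values are excluded from modeling
with a logged count rather than imputed — silent imputation would corrupt
the recovery experiments. A feature column that is unavailable for the
whole cohort (e.g. `grad` without pixel patches) is dropped from the
candidate set instead of invalidating every row.

## Feature selection and nested cross-validation

Each feature is scored against a target by the univariate linear F test,
$F = r^2(n-2)/(1-r^2)$ on $(1, n-2)$ degrees of freedom — the squared t
statistic of the Pearson correlation, verified in tests against an
ANOVA oracle. The three largest-F features enter the regression.

Where selection happens is a real design decision. Scoring features once
on the pooled table before cross-validation leaks test information into
the model choice. The package therefore defaults to selection *inside each
outer training fold*; a `replicate_paper`/`"global"` mode performs it once
globally for comparability with pre-CV scoring. Both are logged per fold.

The CV is nested and subject-level throughout: the outer loop holds out
one subject entirely; the inner loop runs LOSO over the remaining subjects
to choose the hyperparameter grid point with minimal validation RMSE; the
model is refit on all outer-training rows and predicts the held-out
subject. Features and targets are standardized with outer-training
statistics only. A sentinel-injection test asserts that perturbing a
held-out subject's rows leaves its fold's training data bit-identical.

Five regressor families are registered: ordinary linear regression;
ε-insensitive support vector regression with linear and Gaussian kernels;
bagged CART regression trees ("ensemble"); and Gaussian process regression
with a squared-exponential kernel. The grids are deliberately small and
logged: SVR $C \in 10^{-1..2}$, $\varepsilon \in \{0.01, 0.1\}$, Gaussian
length scale $\in \{0.3, 1, 3\}$ on standardized features; trees
$\in \{50, 200\}$ with minimum leaf $\in \{1, 5\}$; GP marginal-likelihood
optimization with $\{1, 5\}$ restarts. "Gaussian model" in the source
study's results is read as the Gaussian process regressor, distinct from
Gaussian-kernel SVR.

Implementation notes, since no SVM/tree/GP package is assumed: the SVR is
trained by dual coordinate descent with the bias absorbed into the kernel
($K + 1$, i.e. a regularized intercept), which removes the dual equality
constraint and gives closed-form coordinate updates; tests compare its
predictions against a `quadprog` solve of the ridge-stabilized dual. The
trees split on variance reduction with exhaustive threshold search; bagging
draws bootstrap indices from R's RNG so runs are seed-reproducible. The GP
optimizes log-parameters by L-BFGS-B with analytic gradients of the
marginal likelihood; its posterior mean is checked against the kernel-ridge
identity.

The reported `rmse_z` is the RMSE of pooled out-of-fold predictions on the
z scale, with z-scoring by outer-training statistics (the only statistics
legitimately available at prediction time). Pooled $r$ is computed on the
raw scale. Whether the reference analysis z-scored by training or pooled
statistics is unknowable from the text; the choice is recorded here and in
the fold log.

## Agreement battery

For the best (family, ROI) per target, `evaluate_agreement()` reports:
Pearson $r$ with two-sided p; `rmse_z` (differences divided by the gold
SD); Bland–Altman bias with $\pm 1.96\,\mathrm{SD}$ limits of agreement
(sign convention: predicted − gold, recorded in the report); a paired
t test on the differences; and the calibration line from OLS of gold on
predicted — slope near 1 and intercept near 0 indicate an unbiased
estimator. Which variable the reference study regressed on which is not
stated; gold ~ predicted is adopted and labelled. Every field is a pure
function of the pooled pairs and is tested against formula-by-formula
recomputation at $10^{-10}$ relative tolerance.

## The synthetic cohort: what it emulates, what it does not

`generate_cohort()` draws 10 subjects × 5 squat series by default (so 50
(ARV, MDF) pairs, the design size of the reference protocol), at 250 Hz
EMG and 10 Hz thermal sampling with 3 ROIs per series.

**EMG.** Each series is Gaussian noise spectrally shaped by a Gaussian
band (SD 15 Hz) centered at $f_c = f_0(1 - \text{fatigue\_slope}\,(s-1))$
with $f_0 \approx 80$ Hz per subject, under a 3 s per-repetition burst
envelope whose amplitude grows by `arv_growth` (default 0.15) per series.
Spectral shaping rather than a time-domain band-pass makes the true median
frequency exactly the band center by symmetry. The defaults (f0 80 Hz,
~20% spectral compression and ~60% amplitude growth over five series,
series durations shrinking from ~60 s to ~30 s) are stated assumptions
in the range physiology reports for fatiguing knee-extensor protocols —
the reference text gives no per-series durations or repetition counts.
The latent `true_arv`/`true_mdf` are the generator's own analytic
computation on the realized trace (mean rectified value; periodogram
spectral median), so the package's Butterworth + Welch measurement path is
a genuinely different route; self-consistency within 5% is a tested
invariant.

**Thermal.** Each ROI record keeps 5 s of late-exercise context plus 15 s
post-exercise. Within the feature window, the level (driving `mean_temp`,
`p90`), the planted 8×8-pixel left-right gradient (driving `grad`) and the
linear trend (driving `delta`) mix a $\sqrt{c}$-weighted map of the
standardized true ARV/MDF with $\sqrt{1-c}$-weighted subject/series noise,
where $c$ is the `coupling` parameter — so $c$ is approximately the
fraction of informative-feature variance explained by the truth, $c = 0$
is an exact null, and $c = 1$ with `noise_sd = 0` makes `mean_temp` track
true ARV deterministically. Temperature noise is AR(1) with coefficient
0.9 at 10 Hz (stationary SD 0.1 °C by default, a realistic frame-to-frame
skin fluctuation; white noise would make `sampen` and `delta` degenerate,
since skin temperature is slowly varying). ARV drives level features and
MDF drives the trend, deliberately disjointly, so recovery tests can
attribute what was learned.

What the generator does **not** emulate: thermoregulatory drift, motion
artifacts, ROI-tracking failures, electrode-shadow effects, or any
biophysics linking perfusion to temperature. A green recovery test
establishes that the pipeline recovers a planted statistical coupling at
the study's design size — not that real skin temperature carries the
information.

## Numerical and policy choices

* Butterworth design by bilinear transform; zero-phase passes initialized
  at step steady state; odd-reflection padding of `3 * filter length`.
* Welch `NFFT` = next power of two ≥ trace length; segments zero-padded to
  `NFFT`; Hamming window; 50% overlap. Detrending beyond the 20 Hz
  high-pass is not applied; the choice is recorded here.
* Median-frequency and top-k ties break to the lowest index / feature
  declaration order.
* Percentiles interpolate linearly between order statistics (R type 7).
* Cohorts serialize to plain CSV + JSON manifest with `%.17g` formatting
  and `strtod` parsing, so the disk round trip is bit-exact and
  seed-identical cohorts are byte-identical on disk.
* All stochastic model families draw from R's RNG only, so a single seed
  reproduces an entire `run_all()` grid.

## Desk-scale test budget

Two acceptance experiments are scaled to stay inside a desktop CPU budget,
and are one-sided or reduced in a direction that cannot manufacture a
pass: the positive recovery control certifies "best pooled r ≥ 0.8" via
the linear family only (the full-grid best is bounded below by any single
family), and the 20-seed null calibration runs the full five-family ×
three-ROI battery for the ARV target rather than both targets. The
permutation-null check runs all five families on one ROI.

## The LOSO correlation artifact

One behavior of this design deserves its own section, because the test
suite measures it and deliberately leaves two null-calibration checks
failing rather than hide it. When targets are subject-clustered (every
subject contributes 5 series whose ARV share that subject's amplitude),
a model fitted to *pure noise* features predicts approximately the
training fold's target mean $\mu_{-s}$. Under leave-one-subject-out,
$\mu_{-s} = (T - 5 m_s)/45$ is an exactly decreasing function of the
held-out subject's own mean $m_s$, so pooled out-of-fold predictions are
systematically *anti*-correlated with the gold standard: with the
generator's between-subject variance share (~0.4) the pooled r converges
to about $-\sqrt{0.4} \approx -0.6$ for strongly shrinking models (the
Gaussian process is the extreme case). Pearson r is invariant to common
affine maps, so no z-scoring convention removes this. Consequences
measured by the acceptance tests:

* on zero-coupling cohorts, nearly every seed produces some (family, ROI)
  whose pooled r is "significant" at two-sided p < 0.01 — always with
  negative r;
* target permutations (which destroy subject clustering but keep finite-n
  grouping) inflate mean |r| to ~0.15–0.32 per family, above an idealized
  $E|r| \approx 1/\sqrt{50} \cdot \sqrt{2/\pi} \approx 0.11$.

Neither effect is leakage — the sentinel-injection test shows training
data are bit-identical under held-out-subject perturbation, and no family
shows positive mean r under the null. It is a property of cross-validated
correlation with grouped data that equally affects any implementation of
this design, and it implies that a *negative* pooled r in a results table
of this kind should be read as "no signal", not as signal. The two checks
are kept at their stated bounds and fail honestly.

## Known limitations

* With 10 subjects the pooled out-of-fold correlation has wide sampling
  variability; single-seed comparisons between families are not meaningful
  and the package intentionally reports fold logs alongside pooled scores.
* The LOSO correlation artifact above: pooled r is negatively biased under
  the null, so small positive r values are conservative but negative ones
  are uninterpretable as anything but absence of signal.
* The ε-SVR's intercept is regularized (kernel-absorbed), which can differ
  slightly from the equality-constrained formulation near tiny C.
* Sample entropy on 100-sample windows is undefined when no template pair
  matches; such rows are excluded, which slightly biases cohorts with very
  low noise.
* The generator's coupling is linear by construction; nonlinear families
  can at best match the linear one on it, so relative family rankings on
  synthetic cohorts say nothing about real data.
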