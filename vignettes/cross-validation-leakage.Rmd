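---
title: "Measuring temporal-correlation leakage in cross-validation of trial-structured time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring temporal-correlation leakage in cross-validation of trial-structured time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trialcv)
```

## Scope

`trialcv` studies a specific failure mode of offline classifier
evaluation: when several epochs are cut from each long trial of a
physiological recording, epochs of the same trial are mutually correlated,
and sample-level k-fold cross-validation lets that correlation leak across
the train/test boundary.  The package provides a synthetic generator whose
correlation and separability are explicit knobs, the standard
pBCI-style feature/selection/classification pipeline, both CV schemes with
label-randomization diagnostics, and the statistical report comparing
everything against a ground-truth condition and against chance.  All
empirical statements below are the ones computed by the package's test
suite and `scripts/acceptance.R`; nothing else is claimed.

## The generative model

A session consists of `2 * minutes_per_class * 60 / trial_duration_s`
trials, balanced between two classes and presented in a uniformly random
order.  Channel `ch` of a trial of class `c` is

    x_ch(t) = sum_b a[c, b, ch] * g * u_b(t) + sigma * w(t)

with

* `u_b`: band-limited, unit-variance Gaussian noise in band `b` (defaults:
  delta 1–4, theta 4–8, alpha 8–12, beta 12–30, gamma 30–50 Hz);
* `a[c, b, ch]`: per-class gain.  The convenience constructor
  `make_class_gains()` sets class 1 to 1 everywhere and class 2 to
  `1 + delta` in the effect bands (default: alpha, all channels), so
  `delta` is a relative amplitude difference — the **separability knob**;
* `g ~ Normal(1, tau^2)`, truncated below at 0.05 and drawn **once per
  trial**: the **correlation knob**.  Epochs of one trial share `g`, so
  their band powers co-fluctuate; `tau = 0` gives i.i.d. epochs;
* `sigma * w(t)`: broadband white noise, `sigma > 0`.

Two implementation details matter and were chosen deliberately:

1. **Band noise is synthesized by frequency-domain masking** (zeroing DFT
   bins outside the band and scaling so the variance is 1 in expectation).
   This gives exact band confinement with no filter-design choices, keeps
   the noise Gaussian, and makes every epoch's in-band power an exactly
   Gamma-distributed quantity — which the Bayes oracle (below) exploits.
   Scaling is by the population constant, not per realization: empirical
   re-standardization would distort the power distribution the oracle
   models.
2. **Band noise is realized in independent epoch-length blocks** within
   each trial.  A single trial-long realization would fix the trial's
   realized spectrum and give epochs of that trial a shared power
   signature *even at* `tau = 0`, contaminating the i.i.d. baseline that
   the calibration checks rely on.  With block-wise realization the shared
   gain `g` is provably the only source of within-trial dependence.
   (Signal continuity at block boundaries is irrelevant for the features
   used, which are all computed within epochs.)

What the generator emulates: the trial/epoch structure, balanced binary
designs, band-structured spectra, a controllable class effect, and
trial-level autocorrelation of adjustable strength.  What it does not
emulate: volume conduction or any realistic spatial mixing (channels are
independent given `g`), artifacts (blinks, EMG), non-stationarity within
trials, 1/f spectral shape, or baseline (eyes-open/closed) segments.
Consequently, passing tests show that the *procedures* behave as claimed
under trial-level correlation; they do not certify effect sizes on real
EEG, where trial signatures are richer (and leakage plausibly stronger —
a single scalar gain is close to a worst case for detecting it).

## The Bayes-rate oracle

`bayes_rate_oracle()` estimates the best achievable accuracy on
independent single-epoch samples by Monte Carlo.  Under the model, the
vector of in-band powers is a sufficient statistic; conditional on `g`,
the power of band `b` on channel `ch` is
`(a^2 g^2 + sigma^2 * 2 k_b / N) * Gamma(k_b) / k_b`, with `k_b` DFT bins
in the band and `N` samples per epoch.  The oracle draws samples directly
from this spectral representation and classifies by the exact likelihood
ratio, integrating the truncated-Normal prior over `g` by quantile
quadrature (61 nodes by default).  Because generator and oracle share the
same closed form, the oracle is generator-optimal by construction, not an
approximation; a test cross-checks the analytic power distribution against
powers measured from generated time series.

The two default separability levels in `study_config()` were calibrated
once against this oracle: `delta = 0.215` gives a best achievable accuracy
near 93% ("high separability") and `delta = 0.05` near 64% ("low
separability") under the default generator (4 channels, 128 Hz, tau 0.3,
sigma 1, alpha-band effect).  They are frozen constants, not fits to any
external data.

## Features and their estimators

All features are computed per epoch and channel.  Band power integrates a
mean periodogram over rectangular 1-s windows with 50% overlap — the
windowing scheme is pinned so results are reproducible, and the
rectangular taper makes an on-bin sinusoid's power exact (`A^2/2`), giving
clean closed-form tests.  Differential entropy is `0.5 * ln(2*pi*e*P)`
nats with `P` the band power (the Gaussian form); spectral entropy is the
Shannon entropy of in-band periodogram bins normalized by `ln(#bins)`
(delta band in the feature table); RMS and variance use the population
denominator `n` so `RMS^2 = variance + mean^2` holds to machine precision.
Known estimator behaviour, quantified in the tests rather than hidden: the
1-s-window periodogram is mildly biased for DE of narrowband noise
(spectral leakage at band edges plus Jensen's inequality, about −0.1 nat
in the tested configuration); with `window_s` equal to the epoch length
the bins align with the generator's grid and the bias shrinks by an order
of magnitude.

Preprocessing mirrors common practice: anti-aliased decimation, a
zero-phase Butterworth bandpass, and common-average re-referencing.  The
bandpass is a cascade of a 2nd-order high-pass (low order keeps the
forward-backward filter numerically safe at a 0.5 Hz edge) and a
10th-order low-pass; the order was chosen so that a 60 Hz mains tone is
suppressed by more than 20 dB after forward-backward filtering with the
0.5–55 Hz passband left intact — a 4th-order design, a common default,
only reaches about 14 dB there.  Synthetic sessions are generated already
band-structured and referenced, so `run_study()` does not preprocess them;
the stage exists (and is tested) for imported data.

## Selection, classifiers, normalization

mRMR uses discrete mutual information on 3-bin discretization at ±0.5 SD
of each z-scored feature, with the difference (MID) criterion: pick the
max-relevance feature first, then greedily maximize relevance minus mean
redundancy with the selected set.  Ties break to the lowest column index,
making selection deterministic given input order; an independent
brute-force implementation of the same recursion serves as the test
oracle.  When `m >= n_features` all features are returned in relevance
order.

LDA is the pooled-covariance linear discriminant with optional shrinkage
of the covariance toward its average-variance diagonal (implemented
in-package because the established implementation exposes no shrinkage
parameter; it is cross-checked against `MASS::lda` at shrinkage 0).  The
linear SVM delegates to `e1071::svm` (C = 1 by default).  KNN is
implemented in-package to honour deterministic tie rules — neighbours
ordered by (distance, training index), a voting tie resolved by the
nearest single neighbour, an exact distance tie there by the lowest class
id — and is cross-checked against `class::knn` on tie-free data.
Hyperparameters are fixed defaults; an optional deterministic inner
3-fold grid (`inner_tuning = "small_grid"`) replaces the irreproducible
automatic optimizer sometimes used in this literature, and every report
records which was used.

Two per-fold normalization variants exist because both appear in
practice: `train_fitted` (test scaled by training statistics; the
fold-safe default) and `separate` (each side scaled by its own
statistics).  The engine treats the variant as an explicit, logged
parameter rather than resolving which is canonical.

## The CV engine and its seed discipline

`run_cv()` repeats, per run: re-randomize labels (if requested), partition
samples (k-fold) or trials (block-wise) with class stratification, then
per fold z-score, select on the training half only, train and score.  The
aggregate is the unweighted mean over `runs x k` fold accuracies (fold
sizes are equal by construction).  Non-divisible designs are hard errors,
never silently rebalanced — the supported designs divide exactly, and
near-balance would weaken the invariant tests.  Labels are re-randomized
every run because the diagnostic is defined as part of the repeated
procedure; a single fixed relabeling would confound run-to-run variance
with one arbitrary draw.

Seeds form a recorded hierarchy: a master seed per scheme yields per-run
seeds, each yielding (randomization, partition) sub-seeds; all are stored
in the result together with the fold memberships, so any single fold can
be replayed exactly.  Derived seeds stay below 2^31.

## Statistics and the report grid

True-label k-fold and block-wise accuracies are compared to the scenario's
ground truth — the 1-epoch-per-trial section, where no within-class
temporal correlation can exist — by two-sided paired t-tests across
replicates; randomized-label accuracies are compared to 50% by two-sided
one-sample t-tests.  Two-sidedness is an assumption (the direction of
leakage is known, but under-estimation is equally of interest), and
degenerate inputs follow the convention `t = 0, p = 1` when all
differences vanish.  No multiple-testing correction is applied by default,
matching the per-scenario individual-test convention in this literature; a
Holm option exists for users who prefer family-wise control.  Replicate
synthetic sessions play the role of participants; the default count of 12
mirrors a typical single-site cohort.

## Demonstration conditions and problem sizes

The leakage demonstrations (tests and acceptance script) fix, at design
time: `delta = 0.05` (the calibrated low-separability level — leakage is
most consequential when true separability is modest), `tau = 0.5` (the
"high correlation" regime; it induces a within-trial correlation of
band-power features of about 0.8 versus about 0.7 at the default
`tau = 0.3`), 4 channels at 128 Hz (the class effect is identical across
channels, so montage size is a cost knob, not a fidelity knob; 128 Hz
comfortably covers the 50 Hz gamma edge), 6 minutes per class, band-power
features, and KNN — the classifier whose nearest-neighbour prediction
exploits within-trial proximity most directly, making it the natural
demonstration case.  Replicate counts (12 for the t-tests and coverage
checks, 10 for the inflation ladder, 24 where a mean must be located
inside a ±1.6-point band) were sized so that estimator noise is small
against the effects being demonstrated.

The ground-truth recovery check compares both CV modes against the oracle
under `tau = 0`, 2 channels, 30 minutes per class, `delta = 0.1`, with
full-epoch periodogram windows.  Rationale: with one epoch per trial the
trial gain is pure class-overlapping noise (there is no within-trial
correlation to model), and at `tau = 0` the generator-optimal decision
rule is *linear in the band powers* — inside the hypothesis class the
pipeline's LDA fits — while the full-epoch window makes the feature vector
the exact sufficient statistic.  The longer session makes estimator
variance, not finite-sample learning bias, the dominant error term.  Under
these conditions agreement with the oracle is a genuine consistency check
of the whole pipeline; under a nuisance-laden nonlinear regime no trained
linear classifier could reach the Bayes bound and the comparison would
only measure that gap.

## Known limitations

* The trial effect is a single multiplicative scalar; real trial
  signatures are multivariate and non-stationary.  The package's
  autocorrelation model is one plausible surrogate, not a claim about any
  particular dataset's correlation structure (AR order, decay).
* Only binary, exactly balanced designs are supported; unbalanced or
  multiclass settings error out rather than approximating.
* The artifact-removal stage of real pipelines is a pass-through here;
  artifact-driven leakage is out of scope.
* Block-wise CV's own pessimistic bias (training-set shrinkage by whole
  trials) is visible in the report grids but not modelled analytically.
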