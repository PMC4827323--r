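---
title: "Optical myography: models, validation schemes, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical myography: models, validation schemes, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optomyo)
```

## The problem

Optical myography infers intended finger movements from the deformation of
the forearm surface, observed as the 6-DOF poses (x, y, z in meters; yaw,
pitch, roll in radians, all in the camera frame) of fiducial markers stuck
to the skin. A visual stimulus drives the subject through a fixed session:
four movements (thumb rotation, thumb flexion, index flexion, and a combined
little/ring/middle flexion), each ramped from rest (0) to full activation
(1), held, and released — 5 s of flexion followed by 3 s of rest, the
four-movement sequence repeated five times at 15 frames/s. The regression
task is to map the marker pose time series back onto the per-movement
activation in [0, 1].

`optomyo` implements the full pipeline — preprocessing, two regression
models, five validation schemes with hyperparameter grid search, NRMSE
scoring, cross-subject aggregation and significance testing, plus robustness
procedures — together with a synthetic forearm-deformation generator, so the
whole chain is testable without any recording.

## Preprocessing

Undetected markers are conservatively replaced by their last known pose
(`impute_last_known()`; a leading undetected run copies the first detected
pose backwards). Each of the `6 * M` channels is then passed through a
second-order Butterworth bandpass (0.01–0.5 Hz), which removes the DC and
high-frequency content and centers every signal around zero
(`bandpass_filter()`, `build_features()`).

Numerical choices that matter here:

* **Zero-phase filtering.** The default is a forward–backward pass, because
  the regression compares filtered features against an *unshifted* stimulus;
  a causal filter would introduce phase lag that nothing downstream
  compensates. A `causal = TRUE` switch applies a single forward pass for
  comparison.
* **Initial conditions.** Both passes use steady-state initialization: since
  a bandpass has zero DC gain, the state-initialized response to `x` equals
  the zero-state response to `x - x[1]`. Without this the ~100 s settle time
  of the 0.01 Hz corner leaks a large startup transient from each channel's
  DC offset. In addition, odd-reflection padding of length `3 * (2 * order +
  1)` samples conditions the record edges. The first and last few seconds of
  output still depend on these conventions, which is why they are documented
  and fixed.
* **Centering.** After filtering, each column is centered exactly, so the
  feature matrix has numerically zero column means; targets are *not*
  centered, and the regression carries a bias term instead (below).
* No further standardization is applied; the regularization grid spans
  enough orders of magnitude to absorb scale.

## Regression models

**Ridge Regression (RR).** On the bias-augmented design
(a column of ones appended to the filtered features), the weights solve the
regularized normal equations `w = (X'X + lambda I)^{-1} X'y` in closed form
via a Cholesky factorization — never an explicit inverse. The bias column is
penalized with the same `lambda`, which keeps the closed form unchanged; it
is required because the activation targets sit in [0, 1] while the features
are centered, so the "on" plateau is unreachable without an intercept. When
the feature dimension exceeds the sample count the solver switches to the
algebraically exact dual identity `w = X'(XX' + lambda I)^{-1} y`.

**Random-Fourier-Feature ridge (RR-RFF).** Inputs are mapped through
`phi(x) = sqrt(2 / D) cos(x' Omega + beta)` with frequencies
`Omega ~ N(0, sigma^2)` entrywise and phases `beta ~ U(-pi, pi)`, then fitted
exactly as RR on the bias-augmented feature matrix. `D = 500` by default. In
expectation the feature inner products reproduce the Gaussian kernel
`exp(-sigma^2 ||x - y||^2 / 2)`, so as `D` grows the predictions approach
exact Gaussian-kernel ridge regression (with the bias adding a constant to
the kernel); the test suite checks this convergence against an exact
kernel-ridge oracle. The standard-normal part of the draw depends only on
`(P, D, seed)` and is scaled by `sigma`, so a grid search over `sigma` at a
fixed seed reuses one underlying draw and `lambda` comparisons are not
confounded by resampling noise. One independent model is fitted per degree
of freedom.

## Validation schemes and grid search

Frames are labelled per DOF as *plateau* ("on–off": stimulus within `eps =
1e-6` of 0 or 1) or *intermediate* (the ramps). A frame can be "on" for the
active DOF and "off" for the others; all masks, split plans and grid
searches operate per DOF. The five schemes (`make_split_plan()`):

1. 10-fold CV, shuffled, over all frames;
2. 10-fold CV, shuffled, over plateau frames only;
3. a single split — train on all plateau frames, predict all intermediate
   frames (no CV);
4. 5-fold CV over all frames, folds contiguous in time (one repetition per
   fold under the default protocol);
5. 5 contiguous folds — train on the plateau frames of four folds, predict
   *all* frames of the held-out fold.

Hyperparameters come from log-spaced grids: ten `lambda` values with
exponents equally spaced in [-6, 0], and for RR-RFF additionally ten `sigma`
values with exponents in [-3, 3] — a Cartesian grid of 100 pairs. Every grid
point is fitted on each training fold and scored by NRMSE
(`sqrt(mean((y_hat - y)^2))` over the test-target range, which equals the
RMSE whenever the target spans [0, 1]) on the matching test fold; the
fold-mean argmin wins, ties resolving to the first point in (lambda, sigma)
order. The fit counter (`fit_count()`) makes the evaluation arithmetic
observable: 10 x 10 = 100 solves for RR under 10-fold CV, 50 under 5-fold,
10 for scheme 3, and ten times as many for RR-RFF.

Selection and error reporting share the same folds (no nesting), because a
single per-scheme error of the grid-searched optimum is reported; that
estimate therefore carries the usual optimistic selection bias, which is
deliberate and documented. Aggregation across subjects reports mean, SD
(n − 1 denominator) and SEM = SD / sqrt(n); method comparisons use the
classical pooled-variance two-tailed Student t-test (`ttest_two_tailed()`;
Welch and paired variants behind flags), with `p = 1` by convention when
both samples are constant and equal.

## The synthetic generator

`generate_stimulus()` renders the session profile as a raised-cosine ramped
trapezoid ("square–sinusoidal": square-like plateaus with sinusoidal
transitions), one DOF active at a time. The ramp duration `ramp_s` is not
fixed by the experimental protocol; the default is 1.0 s, kept configurable.
Frames are sampled at frame centers, `t_k = (k - 0.5) / fps`: with boundary
sampling, both endpoints of the hold would land on the grid and a continuous
profile would carry one extra exactly-at-1 frame; center sampling makes the
count of frames exactly at 1 equal the closed form
`round(fps * (flexion_s - 2 * ramp_s))` (45 per activation at the defaults)
for every ramp choice.

`simulate_forearm()` produces each pose channel as
`baseline + gain %*% activation + drift + noise`, with per-(frame, marker)
dropout flagged undetected:

| parameter         | default | units  | rationale |
|-------------------|---------|--------|-----------|
| `mixing_gain`     | drawn   | m or rad per unit activation | per DOF, disjoint dominant markers (~5 mm position gains) plus 10% cross-talk: markers respond mainly to nearby muscle bulging. Dominant markers are assigned round-robin so every DOF keeps one in the proximal rows. |
| `noise_sd`        | 2e-4    | m, rad | sub-millimeter fiducial-pose jitter |
| `drift_amplitude` | 5e-4    | m, rad | slow postural drift |
| `drift_period_s`  | 200     | s      | below the 0.01 Hz high-pass corner, so filtering removes it |
| `dropout_rate`    | 0.02    | —      | occasional missed detections |

The generator emulates the *statistical* structure of the recordings —
quasi-linear marker response, slow drift, white tracking noise, dropout —
but none of the things that make real data hard: no image formation or
detection failure modes correlated with pose, no muscle co-contraction or
fatigue, no inter-subject anatomical variability (subjects differ only by
seed), no angle wrap-around (synthetic angles stay small). Passing tests
therefore certify the *pipeline*, not performance on real forearms.

## What linear recovery can and cannot achieve

Two behaviors of the synthetic benchmark deserve explanation because they
are properties of the method, not bugs:

* **The bandpass sets a floor on linear recovery.** A raised-cosine ramp of
  1 s concentrates transition energy around 0.5–0.7 Hz — at and above the
  0.5 Hz low-pass corner — so part of the stimulus waveform is removed from
  every feature channel and no linear read-out can reconstruct it. On
  noiseless data the scheme-1 RR error is therefore a few percent NRMSE
  rather than numerically zero, and the first DOF (whose first activation
  starts at t = 0) additionally pays a record-edge cost. Slower ramps lower
  this floor; the default stays at 1.0 s.
* **Shuffled folds are optimistic on time series.** Zero-phase filtering
  smears every sample — including the noise realization — over neighboring
  frames; under schemes 1–2 the shuffled folds interleave those frames, so
  train and test sets are not independent. This is why scheme 1 scores best
  (as expected for shuffled CV), why small amounts of tracking noise do not
  degrade scheme-1 scores monotonically, and why a rich nonlinear basis
  (RR-RFF) can interpolate the trajectory under shuffling. Properties about
  noise degradation and about RR-vs-RR-RFF equivalence are therefore tested
  under the repetition-wise schemes 4 and 5, where folds are contiguous and
  such leakage is structurally excluded — scheme 5 also being the setting
  used for cross-method comparison.

## Robustness procedures

`adjust_contrast_brightness()` applies the affine pixel law
`alpha * f(x, y) + beta` with the convention scale, add, clip to [0, 255],
round; before clipping the operator composes as
`(a1, b1) then (a2, b2) = (a1 a2, a2 b1 + b2)`. `gaussian_blur()` convolves
with a normalized 2-D Gaussian kernel of side `k` (odd, up to 29), with
`sigma = k / 6` so the ±3-sigma support fits the kernel — the kernel size is
the specified quantity, the width rule is this package's documented choice —
using separable passes with reflected borders, which preserves local means
to within 1%.

The "simulated amputee" path (`trim_proximal()`) restricts the features to
the `n` most proximal markers (rows 0–2 of the 5 x 2 layout for `n = 6`,
i.e., 36 feature columns), leaving the frame axis untouched.
`robustness_sweep()` evaluates trim settings directly on trajectories; for
image-level settings it degrades an image sequence and re-runs detection
through a user-supplied adapter (`function(images) -> pose tibble`). The
fiducial detector itself is out of scope, so image settings without an
adapter are rejected with guidance.

## Degenerate inputs and tie-breaks

* Rank-deficient normal equations with `lambda = 0` are rejected with advice
  to use `lambda > 0`.
* A constant NRMSE target falls back to range 1 (NRMSE = RMSE).
* A marker with no detected sample cannot be imputed and is rejected by
  name; stimulus values outside [0, 1] are rejected naming the row rather
  than clipped.
* Grid-search ties resolve to the first grid point in (lambda, sigma) order;
  fold sizes differ by at most one, with contiguous folds for schemes 4–5
  aligned to equal fifths (repetition boundaries under the default
  protocol).
* Predictions are raw regression output, not clipped to [0, 1];
  `clip_unit()` is available as explicit post-processing.

## Problem sizes

The test suite and the acceptance script run entirely on generated data at
deliberately modest sizes: full-protocol subjects (2400 frames, 10 markers,
60 features) for the recovery, trimming and split-plan checks; 10 seeded
subjects for the cross-subject average; reduced sessions (1–2 DOFs, 2–5
repetitions, 4–6 markers) for trend and comparison properties; `n <= 200`
samples with `D` in {50, 500, 5000} over 20 seeds for the kernel-convergence
check; and small random matrices for the solver-oracle and fit-count
contracts, which are size-invariant.

## Known limitations

Real-data concerns deliberately not modelled: angle unwrapping across ±pi,
camera calibration and the fiducial detection algorithm itself, forearm
motion relative to the camera, and simultaneous multi-DOF activation. The
synchronization contract between pose and stimulus files is exact frame-ID
equality.
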