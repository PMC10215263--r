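---
title: "Estimating standing long jump length from smartphone inertial sensors: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating standing long jump length from smartphone inertial sensors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`sljump` estimates the length of a standing long jump (SLJ) from the
inertial sensors of a smartphone held at the hip. The heel-to-heel distance
of an SLJ is a standard field measure of lower-limb explosive power; the
package replaces the tape measure with the accelerometer and gyroscope a
phone already carries, plus a regression model over biomechanical features
of the preparation phase.

The pipeline is:

1. **Ingest and calibration** — read Phyphox-style CSV exports (nominally
   500 samples/s, full scales ±8 g and ±500 deg/s), estimate gyroscope
   static bias from a 60 s still trial, and estimate accelerometer offset
   and cross-axis sensitivity from three static acquisitions with one axis
   gravity-aligned each.
2. **Global frame** — rotate specific force so one axis is vertical
   (estimated from the static-window mean), subtract gravity, and extract
   the vertical (`a_V`) and anteroposterior (`a_AP`) kinematic components.
   With the phone held parallel to the movement plane, yaw is irrelevant:
   the AP direction is recovered as the principal horizontal direction of
   the data, signed so the propulsion burst is positive.
3. **Segmentation** — onset `t_0` (30 ms before the first sample deviating
   8 SD from the static baseline), minimum acceleration `t_UL`, minimum
   vertical velocity `t_UB`, upward zero-crossing `t_BP`, take-off `t_TO`
   (first frame with `a_V <= -g`), plus velocity (trapezoidal integration
   on `[t_0, t_TO]` only, to bound drift) and mass-normalized power.
4. **Features** — 61 per jump: 3 anthropometric, 4 ballistic
   (`b_jump = 2 v_V v_AP / g`, `h_jump = v_V^2 / 2g`, `t_flight = 2 v_V / g`,
   take-off angle), 48 biomechanical/power descriptors of the preparation
   phase, and 6 central frequencies from a 3-mode variational mode
   decomposition (VMD) of `a_V` and `a_AP`.
5. **Modelling** — 80/20 split, z-scoring with training-set parameters,
   Lasso (α = 0.1) feature reduction, then one of six architectures
   (linear, stepwise, SVM, bagged/boosted trees, Gaussian process
   regression, neural network) tuned by Bayesian optimization of 10-fold
   cross-validated RMSE within 30 evaluations.
6. **Agreement** — Bland–Altman bias and 95 % limits with confidence
   intervals, a Kendall's τ heteroscedasticity screen, accuracy / precision
   / bias, and permutation feature importance (PFI).

A physics-based simulator generates annotated synthetic recordings so that
every stage is testable without any measurement campaign.

## Signal model and calibration

The accelerometer measures specific force: at rest it reads `+g` upward,
in free fall it reads zero. All processing uses the gravity-removed
convention `a_V = 0` at rest and `a_V = -g` in flight — this is what makes
the take-off rule `a_V <= -g` work with a *constant* rotation estimated
from the static window. A gyro-driven attitude update would break the
flight plateau and is deliberately not used (the phone is quasi-static at
the hip during the jump; the `-g` plateau identifies flight regardless of
small scale errors, because zero specific force maps to exactly `-g` under
any linear miscalibration).

The accelerometer calibration model is affine,
`a_meas = S a_true + o`, with `S` symmetric (diagonal scales + cross-axis
terms). Three gravity-aligned static orientations give nine equations for
nine parameters, but the system has a one-dimensional null space: a uniform
all-ones perturbation of `S` trades exactly against a common offset shift of
`-g` per unit. We resolve it by the minimum-norm correction about the ideal
sensor (`S = I`, `o = 0`), with offsets expressed in units of `g` so the
ambiguity is split evenly between scales and offsets. Consequences, which
the tests assert: scales recover to well under 1 %, offsets to a few
hundredths of m/s² (a fraction of a percent of g), and applying the
estimated calibration always restores the gravity-aligned axes exactly, by
construction. Six-orientation (±g) protocols would remove the ambiguity
but are not part of the supported acquisition.

## Segmentation choices

* The onset rule uses `a_V` (not the acceleration norm), with baseline
  statistics from a configurable static window, default 0.5–2.5 s.
* If the static window is exactly noise-free (SD = 0, possible only for
  synthetic data) the threshold degenerates to "first sample deviating at
  all"; this keeps the noise-free oracle suite on the same code path.
* `t_BP` is the first negative-to-nonnegative crossing of `v_V` after
  `t_UB`, linearly interpolated and snapped to the nearest sample; exact
  zeros count as crossings. `t_UL` searches `[t_0, t_UB]` with earliest-tie
  break.
* A take-off crossing that occurs well before the vertical-velocity peak
  (final velocity below 60 % of the running maximum, or non-positive)
  indicates a corrupted signal — e.g. full-scale clipping — and the jump is
  flagged and excluded, mirroring the data-cleaning rule applied to the
  study dataset. Recordings that touch the ±8 g full scale are excluded
  outright.
* With acceleration noise present, the detected take-off lags the true
  flight start by a geometrically distributed number of samples (the
  plateau sits exactly at `-g`, so each flight sample crosses the threshold
  with probability ~0.5 at any noise level). At 500 Hz this contributes
  ≈ -0.02 m/s to the take-off velocity on average; the segmentation tests
  therefore assert a *mean* absolute take-off-velocity error below
  0.05 m/s at noise SD 0.05 m/s².

## Feature definitions worth flagging

Four rows of the published feature table are internally inconsistent and
were resolved by giving the feature *names* precedence over their printed
time subscripts:

* `l*` ("negative peak power") is the minimum of `P*`; `n*` ("positive
  peak power") is the maximum — the printed `t_Pmax`/`t_Pmin` subscripts
  appear transposed.
* `F*` ("time from acceleration positive peak to take-off") is
  `t_TO - t_a*max`, although the printed interval is `[t_a*min, t_TO]`.
* `Δv*` repeats the `Δa*` description but has velocity units and formula;
  it is the velocity range.
* `M*` ("positive power duration") is computed for both components despite
  its description naming only the vertical one; this is required to reach
  the stated count of 42 jump-related features. `R_AP` is then
  indistinguishable from `M_AP` by the printed definitions and is
  implemented identically (both span `[t_0, t_TO]`); the redundancy is
  harmless ahead of Lasso reduction.

The unweighting duration `A_V` follows the printed interval `[t_0, t_UB]`
(a `t_UL` variant is available via `unweighting_end`). The power formula is
not stated in the source material; we use the biomechanical standard
`P_V = (a_V + g) v_V` (ground-reaction force per unit mass times velocity),
with the gravity-free variant `a_V v_V` behind `include_gravity = FALSE`
for sensitivity analyses.

`D*` (main positive impulse time) is the summed duration of all samples
with `a* > 0` in `[t_0, t_TO]`.

## VMD

The 3-mode decomposition uses the standard ADMM scheme on the
mirror-extended analytic spectrum, with bandwidth penalty 2000, tolerance
1e-7, zero-initialized center frequencies, and no DC lock — the usual
defaults where the source material is silent. The inner loop is compiled
(Rcpp) since it runs twice per jump. Central frequencies are returned in
Hz sorted descending (`f1 > f2 > f3`). Tests validate mode recovery on
known tone mixtures to 10 %, reflecting that the exact VMD variant used
upstream is unknown.

## Modelling

* **Lasso**: α = 0.1 is interpreted as the per-observation-scaled L1
  penalty (the `1/(2n) RSS + α‖β‖₁` objective shared by MATLAB's `lasso`
  and glmnet's gaussian family), applied to pre-z-scored features with
  `standardize = FALSE`. Features with exactly zero coefficient are
  dropped.
* **GPR** is implemented in-package (exact Cholesky GP) because the needed
  kernel families — rational quadratic, exponential, Matérn 3/2 and 5/2,
  squared exponential — and the explicit zero/constant/linear basis are
  not available together in any installed library. The searched
  hyperparameters are kernel, noise SD σ ∈ [1e-4, 3.05] (log) and basis;
  the kernel length scale uses the median-pairwise-distance heuristic and
  the RQ shape parameter is fixed at 1. The prior signal variance covers
  the basis residuals — for the zero basis that includes the mean of `y`
  itself, otherwise predictions would shrink toward zero.
* **SVM** maps to `e1071::svm` (ε-regression): Gaussian / quadratic /
  cubic / linear kernels, ε ∈ [3.15e-4, 31.5], box constraint and kernel
  scale ∈ [1e-3, 1e3], all log-scaled.
* **Ensemble**: "Bag" is `randomForest` (number of learners, minimum leaf
  size, predictors sampled per split); "LSBoost" is `xgboost` least-squares
  boosting with learn rate 0.1 and depth-3 trees, minimum leaf size via
  `min_child_weight` and predictor sampling via `colsample_bytree`. The
  predictors-to-sample upper bound follows the post-Lasso feature count.
* **NN**: `nnet` supports exactly one logistic-sigmoid hidden layer, so
  the search space is layer size [1, 300] × weight decay λ
  [4.36e-8, 4.36e2] (both log) with depth fixed at one — a deliberate
  narrowing of the nominal 1–3-layer space, acceptable because a
  single-sigmoid-layer network lies inside every searched configuration
  class and is the configuration that won upstream.
* **Stepwise regression** uses AIC-based forward–backward `step()`, the
  closest open equivalent of the unspecified stepwise rule.
* **Bayesian optimization** is expected improvement under a GP surrogate
  (the package's own GP, squared-exponential kernel, on unit-cube-coded
  parameters with one-hot categories). The first evaluation is always the
  space midpoint, then a seeded random exploration phase, then EI steps;
  this guarantees the incumbent after a larger budget is never worse than
  after a smaller one at the same seed, a property the tests rely on.
* Normalization leakage is impossible by construction: test features can
  only be transformed through a `normalization_params` object fitted on
  the training set.

## Agreement statistics

Differences are oriented reference − estimate. Limits of agreement are
`bias ± 1.96 SD`; the CI of the bias uses `SE = SD/√n` and the CI of each
limit the classical approximation `SE = √3·SD/√n` (this choice reproduces
the published confidence intervals from the published bias/precision/n/t
inputs, which is also what the acceptance suite checks). The t quantile
defaults to `qt(0.975, n-1)` and can be pinned (e.g. to a printed 2.00).
The Kendall τ screen correlates pair means with absolute differences
(τ-b); the signed-difference variant is available behind a flag. PFI is
the mean ratio `MSE_permuted / MSE_intact` over independent permutations,
computed on the training set.

## The simulator

Each jump is a piecewise raised-cosine template in the gravity-removed
global frame: a static phase; a countermovement dip (half-lobes of
durations `unloading` and `yielding`, depth set by the programmed dip
velocity); a positive lobe (`braking` rise, `propulsion` fall) whose
integral equals the programmed vertical take-off velocity; a `-g` flight
plateau of ballistic duration; a landing transient; a quiet tail. The AP
channel carries a single positive lobe integrating to the programmed AP
take-off velocity. Gravity is re-added, a tilt/yaw rotation moves the data
into the sensor frame, and the scenario's offset, scale, cross-axis,
gyro-bias, noise and clipping corruptions are applied. All landmark times,
take-off velocities and the ballistic range are exact by construction
(`t_BP` by root-finding on the closed-form velocity integral).

The reference length is modelled as the ballistic range of the sensor
trajectory plus a stature-proportional landing reach (0.05 × stature) plus
Gaussian technique noise (SD 0.08 m by default), so anthropometrics carry
genuine predictive signal. Cohort defaults (take-off speed 4.35 ± 0.30 m/s
between participants, ±0.15 m/s within, mildly coupled to stature; angle
32 ± 4°) are tuned once so simulated lengths have mean ≈ 1.83 m and
SD ≈ 0.30 m, the envelope of the population the method targets. Cohort
recordings emulate an already-calibrated device with small residual errors
(offsets ~0.02 m/s², scale ~0.5 %); the calibration estimators are
exercised by their own dedicated static-trial tests instead, which keeps
cohort generation fast without changing what the cohort tests establish.

What the simulator does **not** emulate: arm-swing and wobbling-tissue
artifacts beyond what the raised-cosine spectra contain, non-planar
movement, sensor clock drift or dropped samples, and temperature-dependent
bias walk. Passing tests therefore demonstrate correctness of the
algorithms under the stated signal model, not field performance on real
recordings.

## Problem sizes and numerical choices

The property suites run at sizes chosen to make sampling error negligible
relative to the asserted tolerances: 500 velocity pairs for the ballistic
oracle (0.1 % tolerance against a numerically integrated projectile),
25 noise-free + 40 noisy jumps for the segmentation oracle, 1000 random
scenarios for the phase-ordering invariant, 10 cohorts of 300 jumps for
the modelling envelope (test RMSE within [0.08, 0.16] m at length-noise
SD 0.10 m), and 20 seeds for the Lasso recovery property. Kendall's τ for
the homoscedasticity check is computed on the pooled test predictions of
the 10 cohort seeds: per-seed τ on ~60 pairs has a null sampling SD of
≈ 0.09, so a per-seed τ < 0.1 assertion would fail by chance for a
perfectly homoscedastic model; pooling (n ≈ 600, null SD ≈ 0.03) tests
the intended property.

Other numerics: gravity is fixed at 9.81 m/s² (configurable); trapezoidal
integration throughout; GP Cholesky with a 1e-10 jitter; no low-pass
filtering by default (none is described in the source protocol); gyroscope
and accelerometer streams are aligned onto the accelerometer time base by
linear interpolation; gaps over 5 sample intervals are filled linearly
with a warning.

## Known limitations

* Three-orientation accelerometer calibration leaves one direction
  unidentifiable (see above); results are exact only modulo that
  trade-off.
* The detected take-off lags the true one by ~1 noise-dependent sample,
  biasing take-off velocity slightly low; this is inherent to the
  `a_V <= -g` rule at finite sampling rates.
* The exact published model (its 11 selected features, Table-3
  hyperparameters, test RMSE 0.122 m) is not reproducible without the
  original recordings; the package instead demonstrates the same pipeline
  recovering known ground truth under matched simulated conditions.
* `kendall_tau_hetero` and the Bland-Altman CIs assume independent pairs;
  repeated jumps by the same participant violate this mildly.
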