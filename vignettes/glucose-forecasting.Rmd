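---
title: "Multi-step glucose forecasting with temporal convolutional networks: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-step glucose forecasting: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The forecasting problem

A continuous glucose monitor (CGM) reports interstitial glucose every five
minutes. Given a patient's history of glucose (BG), carbohydrate intake (M),
basal insulin rate (Ba) and bolus insulin (Bo) up to an anchor time $t$, the
model predicts the glucose sequence $\hat y_{t+1},\dots,\hat y_{t+f}$, with
$f = 6$ steps (30 minutes) as the headline horizon and $f = 12$ (60 minutes)
supported throughout.

The different inputs act on glucose over different time scales, so the model
is built from four parallel views with their own history lengths:

1. $(BG, M)$ over $p_1 = 36$ steps (3 h) — meals raise glucose over hours;
2. $BG$ alone over $p_2 = 6$ steps (30 min) — the recent trajectory carries
   most short-horizon information;
3. $(BG, Ba)$ over $p_3 = 36$ steps — background insulin acts slowly;
4. $(BG, Bo)$ over $p_4 = 36$ steps — meal/correction boluses act over hours.

A history of length $p$ means exactly $p$ samples ending at and including
$t$: the stated history lengths correspond to $36 \times 5 = 180$ and
$6 \times 5 = 30$ minutes, which fixes the count at $p$ rather than $p + 1$.
Targets are the $f$ samples strictly after $t$.

## Architecture

Each view feeds an **encoder-decoder built from temporal convolutional
networks** (TCNs). A TCN stack is one residual block per dilation factor
$d \in \{1, 2, 4\}$; a block holds two causal dilated convolutions (kernel
$k = 2$, 64 filters), each followed by ReLU and 1-D spatial dropout
(rate 0.2, whole feature maps dropped, training only). Normalization layers
are supported (layer normalization) but disabled by default. The causal
dilated convolution is

$$F(s) = \sum_{i=0}^{k-1} f(i)\, x_{s - d\cdot i},$$

with left zero padding so output length equals input length and no output
depends on future inputs. One stack's receptive field is
$1 + \sum_{\text{conv layers}} (k-1)\,d = 15$ samples for the default
configuration.

The **encoder** summarizes its input as the feature vector at the final time
step (the latent state). The published description does not fix what the
decoder consumes at each step; this implementation repeats the latent vector
$f$ times and runs a second TCN stack over that constant sequence — the
standard non-autoregressive TCN sequence-to-sequence realization, which
predicts all $f$ steps in one pass and avoids exposure bias. Autoregressive
decoding is a known alternative and was deliberately not taken. A
**time-distributed linear head** (one weight vector shared across horizon
steps, no activation — scaled test glucose may exceed 1) maps decoder
features to one scalar per step.

The four component forecasts $\hat Y_c$ are combined by a **parametric
fusion layer**

$$\hat Y = \sum_{c=1}^{4} W_c \odot \hat Y_c,$$

where each $W_c$ is a learnable length-$f$ vector ($\odot$ elementwise over
horizon steps, broadcast over samples). Weights start at 0.25 and are left
unconstrained (no simplex projection): the fitted magnitudes are reported
per component and step by `report_fusion_contributions()` and are
interpretable as per-horizon contributions. One stack with dilations
$\{1,2,4\}$ sees 15 samples, less than the 36-sample histories of views 1,
3 and 4; the configuration is kept as published, and `n_stacks` / `dilations`
are exposed for users who want full coverage.

## Loss, weighting and optimization

Training minimizes an **event-weighted Huber loss**. The Huber threshold
$\delta = 0.5$ applies on min-max-normalized glucose (training operates on
scaled data); the event weight of each target element is decided on its true
mg/dL value: $\lambda_{hypo} = 100$ below 70 mg/dL, $\lambda_{hyper} = 10$
at or above 180 mg/dL, $\lambda_{normo} = 1$ otherwise. Splitting the scales
this way keeps $\delta$ meaningful on the normalized residuals while the
clinical categories stay in physical units. The heavy hypoglycemia weight
counteracts the extreme rarity of low-glucose samples.

Optimization is Adam (learning rate $10^{-4}$, batch size 32), with
gradients derived analytically layer by layer. The epoch budget is not
fixed by the published setup; the default is 200 epochs with early stopping
(patience 20) on a validation loss computed over the chronological tail 10%
of the training windows — a chronological split avoids look-ahead leakage in
time series. Best-validation weights are restored. All randomness
(initialization, shuffling, dropout) derives from the configuration seed, so
training is reproducible run-to-run on a fixed BLAS.

Per-patient modelling: one model is trained per patient (individual glucose
dynamics differ), with the scaler fitted on that patient's training split
only.

## Preprocessing rules

* **Gap filling.** CGM dropouts up to 30 minutes (6 samples, bound
  inclusive — "up to") are filled by *monotone* piecewise-cubic Hermite
  interpolation (`pracma::pchip`). A shape-preserving interpolant cannot
  overshoot into spurious hypo- or hyperglycemia, which a natural cubic
  spline can; the cited rule names only "piecewise cubic", and the monotone
  flavor is the safer reading for clinical data. Boundary gaps (no neighbor
  on one side) are left missing and reported.
* **Segment splitting.** Longer gaps split the record into contiguous
  segments; windows never span a split.
* **Calibration rejection.** A segment containing a fingerstick calibration
  that differs from the simultaneous CGM reading by *more than* 50 mg/dL is
  dismissed (exactly 50 is tolerated; the rule is a strict inequality).
* **Eligibility / quality.** Eligibility requires confirmed type-1
  diabetes, age over 18, and over 2 years since diagnosis. The quality trio
  (time in range > 70%, meals/day > 3.5, time in hypoglycemia < 2%) is
  computed and reported but not enforced by default.
* **Scaling.** Min-max per variable, fitted on training segments only; test
  values outside the training range scale beyond $[0,1]$ without clipping.
  Predictions are de-scaled with the glucose scaler before evaluation.
* **Windowing.** Anchors run from $\max(p)$ to $L - f$; a gap-free segment
  of length $L$ yields $L - \max(p) - f + 1$ windows at stride 1. The
  pipeline thins *training* anchors to one per 10 minutes (stride 2):
  adjacent 5-minute anchors give ~97%-overlapping windows, so moderate
  thinning sacrifices little information while keeping per-epoch cost
  proportionate -- though thinning too far visibly starves the model, so the
  default stays conservative; test windows always use stride 1.

## The virtual-patient generator

Real CGM/pump exports are proprietary, so the package ships a seedable
simulator whose only job is to produce data with the statistical structure
the pipeline assumes. It integrates a Bergman-type minimal model — plasma
glucose, remote insulin action, plasma insulin, and a two-compartment gut —
with fixed-step RK4 at 1-minute resolution (deterministic across platforms),
resampled to the 5-minute grid:

$$\dot G = -(S_G + X)G + S_G G_b + k_{gut} Q_2 / V_G, \qquad
  \dot X = -p_2\,(X - S_I (I - I_b)),$$
$$\dot I = -k_e I + u(t)/V_I, \qquad
  \dot Q_1 = -k_{gut} Q_1, \qquad \dot Q_2 = k_{gut}(Q_1 - Q_2).$$

The insulin kinetics ($k_e \approx 0.012{-}0.020\,\mathrm{min}^{-1}$) are
*effective subcutaneous* values — they fold the slow absorption of pumped
insulin into the plasma compartment so that one bolus acts over hours, as
dosed insulin does, rather than modelling IV clearance. Insulin sensitivity
is scaled accordingly, and the dosing parameters are derived from each
patient's kinetics: the carb ratio and correction factor that would exactly
balance meals are computed from $(S_I, k_e, V)$ and then perturbed by
±15-20%, which is what makes the cohort's control imperfect in a realistic,
internally consistent way.

Behavioral layer: 3-5 meals/day (main meals 40-90 g, snacks 10-30 g) at
jittered conventional times; meal boluses `carbs / carb_ratio` with a
multiplicative lognormal dosing error (sd 0.3) and an 8% missed-bolus rate;
a correction `(BG - 100)/CF` whenever glucose exceeds 170 mg/dL at a dosing
moment, re-checked two hours after each meal with its own per-event dosing
error. Correction stacking onto still-active meal boluses, and a ±30%
circadian basal profile around the equilibrium rate, are the simulated
sources of hypoglycemia — the same mechanisms that dominate in practice.
The CGM channel adds AR(1) noise (coefficient 0.7, innovation sd 4 mg/dL,
stationary start) to the clamped (20-600 mg/dL) noise-free trace, which is
retained alongside for oracle use.

What the generator does **not** emulate: exercise, stress and illness
effects, sensor compression artifacts and drift (beyond the injected
calibration offsets), meal-absorption variability across meal types, and
circadian insulin-sensitivity rhythms. Tests passing on this cohort
demonstrate that the pipeline's machinery is correct and that the model can
extract real signal; they do not certify accuracy on real patients.

`inject_artifacts()` adds the defects the cleaning stage must handle — CGM
dropouts and calibration records offset from the simultaneous CGM value —
deterministically from explicit specifications.

## Baselines

All baselines consume the same windows as the main model. Naive persistence
copies the anchor glucose to every step. Kernel ridge regression (linear and
RBF, $\alpha = 1$, $\gamma = 0.1$) and Gaussian-process regression (ARD-RBF
with length scales and variance fixed at their unit initial values plus a
noise term; no marginal-likelihood optimization) predict the final-step
value only, from 30 minutes of glucose plus 3 hours of basal/bolus/meal
history. The GP caps training at 2000 evenly spaced points (the exact
solve is cubic). ARX ($n_a = 6$, $n_b = [36, 36, 36]$, $n_k = [0, 0, 0]$,
plus an intercept) is fitted by least squares on one-step regression and
iterated over the horizon, feeding predictions back as glucose lags while
exogenous inputs take their observed values — pump and meal records are
known over a 30-minute horizon. A rank-deficient design (e.g. stretches of
constant basal) falls back to a tiny ridge penalty scaled to the design's
magnitude, with a warning.

## Evaluation

RMSE, MAE, MAPE (true value in the denominator, exactly as defined) and
NRMSE (RMSE over the evaluated true range) are reported overall and per
glycemic category, the category decided by the *true* value; an empty
category reports "No test samples" rather than zeros, and TPR/FPR with an
empty denominator are reported missing, never 0. Cohort aggregation uses
the sample (n-1) standard deviation. Quantitative metrics are evaluated at
the final predicted step (= the prediction horizon); per-step evaluation is
available through `forecast_step()`.

Clinical accuracy uses both error grids. Clarke zones are implemented as
the published inequality rules (including the low-glucose branch of Zone A,
which the one-line "within ±20%" summary omits). The Parkes (consensus)
grid for type-1 diabetes is encoded as the published boundary polylines and
classified from Zone A outward with inclusive bounds, so a point exactly on
a boundary lands in the lower-risk zone — boundary handling is otherwise
unspecified. Model comparison uses the Welch two-sample t-test on
per-patient metric values.

## Numerical choices and degenerate inputs

* Weight initialization: fan-in-scaled Gaussian, seedable.
* The encoder computes only the columns its final-step latent needs
  (receptive-field pruning); this is exact, not an approximation, and is
  verified against the dense path in the tests.
* A segment shorter than $\max(p) + f$ yields zero windows (not an error);
  an all-masked component set, a constant variable under min-max scaling,
  an empty training set, and a non-finite training loss are errors.
* Huber loss is continuous and once-differentiable at $|e| = \delta$; its
  gradient uses $\delta\,\mathrm{sign}(e)$ in the linear regime.
* Checkpoints are JSON at full double precision (lossless round-trip to
  1e-9 and beyond); the flat weight vector is rebuilt into the architecture
  implied by the stored configuration.
* The loss is symmetric in predicted/actual, so the roles of $y$ and
  $\hat y$ in its definition do not affect the value.

## Problem sizes used by the shipped studies

The test suite trains per-patient models on a 3-patient, 21-day cohort at
horizons of 30 and 60 minutes with a 60-epoch budget, and the reporting
script (`scripts/acceptance.R`) reports cohort metrics for a 2-patient,
21-day cohort at 30 minutes with the same 60-epoch budget — sizes chosen so a complete desk-scale study trains
in minutes on one CPU while leaving the learning signal (beating naive
persistence per patient; degradation from 30 to 60 minutes) clearly
measurable. Larger cohorts are a matter of configuration, not code.

## Known limitations

* The published cohort is proprietary; no quantitative result from it is
  reproducible here, and simulated-cohort numbers are not comparable to
  real-cohort numbers.
* One default TCN stack's receptive field (15 samples) under-covers the
  3-hour views; deeper stacks are configurable but not the default.
* KRR/GP predict a single step, the ARMAX comparator is not implemented
  (its estimation is tied to a proprietary toolbox), and uncertainty
  quantification is out of scope.
* Training determinism is guaranteed for a fixed BLAS and thread count;
  bit-level results may differ across BLAS builds.
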