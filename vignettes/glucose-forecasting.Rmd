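---
title: "Short-term glucose forecasting from CGM with baseline-record fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-term glucose forecasting from CGM with baseline-record fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucast)
```

## The problem

Continuous glucose monitoring (CGM) sensors sample interstitial glucose every
1--15 minutes. For people with type 2 diabetes, forecasting glucose 15, 30 or
60 minutes ahead enables early warning of hypo- (< 70 mg/dL) and
hyperglycaemia (> 180 mg/dL). Population-level forecasters trained on CGM
alone ignore stable physiological differences between patients —
glycated-haemoglobin level, age, weight, lipid profile — that modulate glucose
dynamics. `glucast` implements a *multimodal* forecaster: a sequence encoder
over the recent CGM window fused with a dense encoder of static baseline
health-record variables, alongside the corresponding *unimodal* (CGM-only)
model, a synthetic cohort generator to exercise the whole pipeline, and
clinical evaluation tools (Parkes consensus error grid, ambulatory glucose
profile statistics).

## Model

Each training example is a window of six consecutive glucose samples
$x_{t_0},\dots,x_{t_5}$ on a common 5-minute grid, min–max scaled to $[0,1]$,
with target the scaled glucose at $t_5 + \mathrm{PH}$ for a prediction
horizon $\mathrm{PH} \in \{15, 30, 60\}$ minutes. The pipeline is:

1. **BiLSTM.** A standard LSTM cell
   ($f,i,o = \sigma(\theta [h_{t-1}, x_t] + b)$,
   $\tilde C = \tanh(\theta_c [h_{t-1}, x_t] + b_c)$,
   $C_t = f \odot C_{t-1} + i \odot \tilde C$,
   $h_t = o \odot \tanh C_t$) is run forward over $t_0 \to t_5$ and backward
   over $t_5 \to t_0$; per-step hidden states are concatenated to a
   $6 \times 2H$ sequence.
2. **Self-attention.** The sequence attends to itself: weights are the
   row-softmax of the Gram matrix of hidden states, and each output row is
   the weighted combination of all rows. Weight rows sum to one by
   construction.
3. **1D CNN.** A kernel of 3 (stride 1, no padding) with 100 filters and
   ReLU activation maps the attended $6 \times 2H$ sequence to
   $4 \times 100$ feature maps (output length $\lfloor (6-3)/1 \rfloor + 1$),
   flattened to 400 features; 10% dropout is applied during training.
4. **Baseline encoder and fusion (multimodal mode).** The ordered, *unscaled*
   baseline vector of the active variable set passes through stacked
   dense+ReLU layers; its encoding is concatenated feature-wise with the CNN
   features and mixed by one dense+ReLU fusion layer.
5. **Regressor.** A dense layer with sigmoid activation produces the scaled
   prediction in $(0,1)$, inverted to mg/dL through the training scaler.

All weights start Glorot-uniform ($U(\pm\sqrt{6/(f_{in}+f_{out})})$; for the
convolution $f_{in}$ is kernel × channels and $f_{out}$ the filter count),
biases at zero. Training minimises mean squared error on the scaled targets
with mini-batch Adam. The log-likelihood objective
$\mathcal L = \sum_k \sum_i (\hat Y_i^k - \log \sum_{j \in t_i} \exp \hat
Y_j^k)$ is also implemented (`loss_eq14()`, selectable via
`model_config(loss = "eq14")`); because its candidate set $t_i$ is
under-determined for scalar regression we take it, when training, as the
same-subject predictions within the mini-batch, and keep MSE as the default
objective.

Backward passes are derived analytically for every stage (including the
two-path attention gradient through weights and values) and are verified
against central finite differences to $10^{-4}$ relative error in the test
suite.

### Design choices in the architecture

* The cell-state update combines the gated terms by **elementwise addition**
  — the conventional LSTM form; a concatenation there cannot type-check
  against the cell-state shape.
* Pipeline order is **BiLSTM → attention → CNN**, following the order in
  which the stages consume each other's outputs; naming conventions that
  list "CNN + LSTM + attention" are treated as labels, not order.
* Convolution output length uses the standard
  $\lfloor (l_f - m)/d \rfloor + 1$.
* Unspecified widths default to 64 LSTM units per direction, a 32+16
  baseline encoder and a 64-unit fusion layer; all are configurable.
* "50 iterations" of training per cross-validation cycle is read as 50
  epochs.

## Preprocessing

* Duplicate (patient, timestamp) rows collapse to their mean (sensor
  re-transmissions).
* Patients with **more than** 50% missing data are excluded (strict: exactly
  50% is retained). The expected sample count is span/native-interval + 1,
  computed before resampling.
* 15-min series are **upsampled** to the 5-min grid by linear interpolation;
  1-min series are **downsampled** to 5-min bin means (decimation is an
  option); interpolation never bridges a native gap at this stage.
* Interior missing runs are filled by linear interpolation; leading/trailing
  missing samples are dropped, not extrapolated — extrapolation would
  fabricate data. Gap locations are recorded for the windowing stage.
* Min–max scaling to $[0,1]$ is fitted **per cross-validation fold on the
  training windows only** — whether the original analysis fitted scalers
  globally or per fold is unstated, and the per-fold choice is the one that
  cannot leak test-day information. Test-time values outside the training
  range map outside $[0,1]$ unclipped.
* An augmented Dickey–Fuller regression (constant + lagged differences,
  embedded large-sample 5% critical value −2.86) is provided as a
  stationarity *quality check*; it never gates the pipeline.

## Windows and cross-validation

Windows slide with a stride of one grid step. A candidate window is dropped
if its span (inputs through target) crosses a calendar-day boundary or an
interpolated gap longer than 15 minutes; windows touching shorter
interpolated gaps are kept but flagged. Day boundaries plus day-labelled
targets make **leave-one-day-out** cross-validation leakage-free: each
distinct calendar day (pooled across patients — a population model) forms one
test fold, and all other days train the model. Fold test sets partition the
dataset; fold `k` trains from a fresh initialisation with seed
`seed + k`. Whether test days should be held out per patient or cohort-wide
is an open choice; cohort-wide is the default here because the model is a
per-sensor population model, and per-sensor populations are never pooled for
training.

The input length is fixed at **six samples**: the window scheme indexes
$t_0\dots t_5$ and the attention stage's sequence length is 6, so the window
spans 25--30 minutes of history.

## The synthetic cohort generator

Real pilot-study CGM with linked health records is not redistributable, so
the package ships a generator whose defaults emulate the study conditions: 40
patients, 15 on a 1-min sensor and 25 on a 15-min sensor, 8--28 days of
monitoring each. Baseline covariates are drawn from truncated normals with
the published cohort means and SDs (age 67 ± 9 y, HbA1c 7.42 ± 1.11%, weight
80.42 ± 28.46 kg, ...); the truncation window is $[\max(0, \mu - 4\sigma),
\mu + 4\sigma]$ — near-symmetric so the recovered means stay within 2% of the
targets while keeping values nonnegative (a hard physiologic lower bound at,
say, 35 kg would bias the recovered weight mean by several percent given the
large SD).

Glucose follows

$$g(t) = B + A\sin(2\pi t/24\mathrm h + \varphi)
       + \sum_k M_k\, k(t - t_k) + \varepsilon(t),$$

clamped to the common CGM reporting range [40, 400] mg/dL, with:

* basal level $B$ tied to HbA1c by the standard ADAG estimated-average-glucose
  relation $B = 28.7 \cdot \mathrm{HbA1c} - 46.7$ — this is what gives the
  multimodal branch a learnable signal; `baseline_effect_scale` interpolates
  between no covariate influence (0) and the full relation (1);
* circadian amplitude $A \sim U(10, 30)$ mg/dL with random phase;
* meals near 08:00/13:00/20:00 (jittered ±45 min daily), response kernel
  $k(u) = (u/\tau) e^{1 - u/\tau}$ with $\tau = 60$ min and amplitudes
  $M_k \sim U(30, 80)$ mg/dL — any smooth excursion suffices since meal
  covariates are out of scope, and this gamma-like rise/decay is realistic;
* AR(1) noise with coefficient 0.9 at 5-min spacing (CGM autocorrelation is
  high) and per-patient innovation SD $\sim U(2, 8)$ mg/dL; at other native
  intervals the coefficient is rescaled as $0.9^{\Delta/5}$ with the
  innovation SD adjusted to keep the stationary variance identical, so the
  two sensors see the same marginal noise level;
* missingness as **contiguous** dropout gaps (geometric lengths, mean 6
  samples) hitting the target fraction exactly, mimicking sensor dropouts
  rather than i.i.d. point loss.

What the generator does **not** emulate: glucose–insulin kinetics, sensor
calibration drift and error profiles, behavioural irregularity (skipped or
extra meals, exercise), or realistic inter-variable correlation in the
baseline record (covariates are drawn independently). Tests passing on this
cohort therefore demonstrate that the pipeline is wired correctly and that
the model can exploit a genuine baseline-to-dynamics channel — not that it
attains any particular accuracy on real patients.

## Study-scale settings

The package's own end-to-end experiments (acceptance tests and
`scripts/acceptance.R`) run on 12 synthetic patients × 10 days at the 15-min
native interval, windows thinned by a factor of 7, and the
`study_control()` model: 8 LSTM units/direction, 16 filters, 8+8 baseline
encoder, fusion width 16, Adam with step-decayed learning rate and gradient
clipping. These sizes were chosen so that a full sweep — three horizons ×
both architectures × leave-one-day-out folds × several seeds — remains a
single-CPU computation while the qualitative findings (error growth with
horizon, multimodal parity or better at long horizons, both models beating
last-value persistence at 60 min) are stable. The full-size defaults of
`model_config()` remain available.

## Numerical choices and degenerate inputs

* Degenerate min–max scaler (max = min): everything maps to 0 with a
  warning; inversion returns the constant.
* Attention softmax subtracts the row maximum; `loss_eq14()` uses
  log-sum-exp.
* Paired comparisons with zero-variance differences: p = 1 when all
  differences are zero, otherwise flagged degenerate with p → 0.
* Empty hypo-/hyperglycaemic strata report `NA` (undefined), never 0.
* Parkes grid boundary points are assigned to the better (more accurate)
  zone, the consensus-grid convention; out-of-range values are clamped to
  [0, 550] mg/dL with a warning. The shipped vertex file is the published
  digitisation of the type 2 consensus grid (Parkes et al. 2000; coordinates
  as tabulated by Pfutzner et al. 2013) and is swappable.
* The GMI relation 3.31 + 0.02392 × mean glucose reproduces the cohort's own
  printed pair (146.1 mg/dL → 6.8%).
* All randomness flows through R's RNG: a configuration plus seed determines
  cohorts, initialisation, shuffling and dropout bit-identically.

## Known limitations

* The forecaster sees only six glucose samples; time-of-day, meals and
  exercise are outside its input, so much of the 60-min excursion dynamics
  is irreducible for it (as for the persistence baseline).
* The attention stage starts near-uniform under Glorot initialisation, which
  makes position information emerge slowly during training; small-scale runs
  therefore benefit from the decayed, clipped Adam schedule used in
  `study_control()`.
* Eq.-style log-likelihood training is implemented but under-determined for
  scalar regression (see above); MSE is the working objective.
* Hypoglycaemic windows are rare in type 2 cohorts (and in the generator),
  so hypoglycaemic error estimates are noisy — mirrored by the undefined
  markers in stratified reports.
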