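---
title: "Multi-task neural survival analysis with missing values: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task neural survival analysis with missing values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survnet)
```

## The problem

Clinical survival cohorts are small, heavily right-censored, and riddled with
missing covariate values: in a typical early-stage lung-cancer registry most
patients are alive or lost to follow-up at the end of the study, and the
majority of rows are incomplete in at least one of a handful of
clinicopathologic variables. Dropping incomplete patients biases the sample;
naive imputation injects fabricated signal. This package fits a small
feedforward network that treats missingness as a first-class citizen and
learns a per-patient *prognosis index* usable to rank risk and to split a
cohort into high- and low-risk groups.

## The model

Each patient is a triplet $(x_i, s_i, t_i)$: a $p$-dimensional covariate
vector (default $p = 9$), an event indicator ($s_i = 1$ if death was
observed), and a follow-up time in months. Continuous covariates are
standardized on observed training values (sample standard deviation, $n-1$
denominator — fixed in the tests); categorical covariates carry nonzero
integer codes symmetric around zero (binary: $-1/+1$). Missing entries are
filled with zeros and flagged in an indicator matrix $R$ ($r_{ij} = 0$ iff
entry $ij$ is missing). Zero is reserved for "missing", which is why no
category may be coded 0.

The shared trunk is `input (p) -> 64 tanh -> batch norm -> 32 tanh`. Three
heads are trained jointly:

1. **Input reconstruction** (incomplete-aware autoencoder). A linear decoder
   maps the 64-unit encoding $a^2$ back to $x^*$, with loss
   $$J_{re} = \frac{1}{2n}\sum_i \| r_i \odot (x_i^* - x_i)\|^2 .$$
   Masked entries contribute nothing and receive exactly zero gradient, so
   the decoder never learns to reproduce the zero-fill placeholder.

2. **Fixed-horizon survival classification.** A logistic head on the 32-unit
   activation predicts $a^c = \Pr(\text{alive at } T)$, default $T = 36$
   months. Labels are $d_i = 1$ if $t_i \ge T$ and $d_i = 0$ if the patient
   died before the horizon; patients *censored* before $T$ carry no label and
   are masked out of the cross-entropy (validity mask $\delta_i$). A batch
   with no labelable rows contributes zero with a warning. Probabilities are
   clamped to $[10^{-7}, 1 - 10^{-7}]$ before logs.

3. **Cox regression.** A linear head produces the raw log-hazard $a^p$; the
   deployed prognosis index is the context-gated product
   $p_x = a^p \cdot a^c$ (elementwise). The loss is the negative mean log
   partial likelihood
   $$J_{cox} = -\frac{1}{D}\sum_{i: s_i = 1}\Big[p_{x,i} -
     \log \sum_{j:\, t_j \ge t_i} e^{p_{x,j}}\Big],$$
   with $D$ the event count, risk sets including the index patient and all
   ties (Breslow convention), and a numerically stable log-sum-exp inside.

The training objective is $J = \alpha J_{cox} + \beta J_c + \gamma J_{re}$
with defaults $\alpha = 0.2$, $\beta = 1$, $\gamma = 3$. All three terms are
minimized (the classification and Cox terms are negative log-likelihoods);
terms of disabled modules contribute exactly zero, which is how the
ablations (`use_reconstruction = FALSE`, `use_classification = FALSE`) are
defined. With gating, classification, and reconstruction all disabled the
model reduces exactly to a plain deep Cox network ("Cox-Net" baseline); the
test suite asserts this identity against a standalone reference forward
pass.

### Sign conventions and printed-formula repairs

Several of the published formulas cannot be implemented literally; the
package adopts the self-consistent reading and documents it here:

- The partial-likelihood inner sum is implemented as
  $\log\sum\exp(p_x)$ — the literal printed form (no exponential) is
  undefined for nonpositive scores and is not a likelihood. No
  strict-as-printed mode is offered.
- The classification validity mask is $\delta_i = 0$ exactly for patients
  censored before the horizon ("ignored"), the reverse of the printed
  indicator, which would train only on unlabelable patients.
- The concordance index uses the standard Harrell orientation (an earlier
  event with a higher risk score counts as concordant); the literal printed
  indicator orientation equals $1 - C$.
- Batch normalization normalizes the encoder activation $a^2$ (the printed
  variance argument is read as a typo), with learned scale/shift,
  $\epsilon = 10^{-5}$, biased batch variance, running statistics with
  momentum 0.1 and unbiased running variance (the convention of the deep
  learning framework the original was trained in).
- Boundary $t_i = T$: the patient survived *to* the horizon, so $d_i = 1$
  regardless of $s_i$.

### Gating semantics for negative log-hazards

When $a^p < 0$, gating shrinks the score toward zero as $a^c \to 0$, which
*raises* the rank of a patient the classifier believes will die. This is a
property of the published formula, implemented as written; it matters only
in the rare regime where the two heads disagree strongly. Both $p_x$ and
the raw $a^p$ are exposed (`predict_risk()`), and validation selection uses
the deployed, gated score.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `encoder_units`, `hidden_units` | 64, 32 | neurons | published network settings |
| `horizon_T` | 36 | months | published classification horizon |
| `alpha, beta, gamma` | 0.2, 1, 3 | — | published task weights |
| `epochs`, `batch_size` | 100, 64 | — | published protocol |
| `weight_decay` | 1e-5 | — | published; applied to weight matrices only |
| learning rate / smoothing / eps | 0.01 / 0.99 / 1e-8 | — | the RMSProp family's conventional defaults, pinned explicitly so runs reproduce across library versions |
| `dropout_rate` | 0 | [0, 1) | a dropout layer is named before the Cox head but no rate is published; it sits after the hidden activation and feeds the Cox head only (the classification head reads the undropped activation, which is the one its equation names) |
| `bias_terms` | `TRUE` | — | the printed equations omit biases; standard practice includes them, and a strict-equation mode (`FALSE`) is kept for comparison |

Model selection: after every epoch the validation C-index of the
inference-mode gated score is computed; the snapshot with the best value
(first-attained on ties) is returned. Batches without events skip the Cox
term with a logged count; plain shuffling is used rather than
event-stratified batching (a possible divergence from the original, which
does not say). An incomplete final batch of size 1 is folded into the
previous batch because batch normalization needs two rows.

## The synthetic cohort generator

The clinical cohorts behind the original study are not deposited, so every
experiment here runs on simulated data with a known answer.
`simulate_cohort()` draws continuous covariates from $N(0,1)$ and
categorical codes uniformly, forms the true log-hazard
$\eta = Z\beta\ (+\ \text{optional quadratic/interaction terms})$, and
samples event times from a Weibull proportional-hazards model by inverse
transform, so the marginal baseline survival is closed-form — that is what
the Kaplan-Meier calibration test checks at $n = 5000$. Censoring is
exponential with its rate solved by bisection so the expected censored
fraction matches the target given the realized event times; an
administrative cap truncates follow-up. Missingness is MCAR per entry
(MAR/MNAR out of scope, matching the uniform random zeroing of the
robustness experiment).

Defaults state the emulated world: $n = 1137$, entry-missingness 0.19
(≈85% of rows incomplete), censoring target 0.7 (≈30% events), Weibull
shape 1.3 / scale 140 months, cap 215 months. What the generator does *not*
emulate: covariate correlations, category imbalance, informative censoring,
measurement error. A green test on simulated data therefore establishes
algorithmic correctness and recoverable-signal behavior — not clinical
performance.

`oracle_cindex()` scores the *true* log-hazard against the simulated
outcomes: the ceiling any fitted model can approach. The parameter-recovery
acceptance criterion requires the trained default model to reach 90% of
that ceiling (median over five seeds) on a clean linear cohort.

## Numerical choices

- Log-sum-exp everywhere a risk-set sum appears; the Cox gradient uses the
  sorted cumulative form and is checked against an explicit double loop.
- Analytic backprop through every layer (including training-mode batch
  normalization) is validated against central finite differences to 1e-6.
- Concordance ties: tied risk scores earn credit 0.5; pairs with tied times
  are not comparable. Dichotomization: scores equal to the median threshold
  fall to the low-risk group (the strict-inequality rule).
- Kaplan-Meier confidence bands use the Greenwood variance on the
  complementary log-log scale (the band respects [0, 1]).
- Checkpoints serialize doubles with 17 significant digits, which
  round-trips IEEE doubles exactly.
- Seeds: every randomized operation takes an explicit seed and restores the
  caller's RNG state; repeat runs derive seed $s + 1009(i-1)$.

## Known limitations

- The Cox loss is normalized by the per-batch event count so the printed
  task weights remain meaningful across batch sizes; whether the original
  summed raw is unknown (config knob `normalize` on `cox_loss`).
- No Efron tie correction, time-varying covariates, competing risks, or
  multiple imputation — all out of scope by design.
- Training is plain mini-batch RMSProp; no early stopping beyond best-epoch
  snapshotting, no learning-rate schedule, no hyperparameter search.
- Performance numbers from the original clinical cohorts are not
  reproducible here (data not deposited); the test suite asserts the
  directional and structural properties instead.
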