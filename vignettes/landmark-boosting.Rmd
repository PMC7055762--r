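---
title: "Dynamic landmark-boosted risk prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic landmark-boosted risk prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landboost)
```

## The prediction problem

`landboost` addresses rolling one-year risk prediction from longitudinal
clinical records: for a patient with diabetes, estimate at every *landmark
time* $t$ (each full year since diabetes onset) the probability of
diabetic kidney disease (DKD) onset in the coming year, using only
information recorded strictly before day $365t$.

The outcome is operationalised through yearly status sequences
$\{y_i^t\}$, $y_i^t \in \{0, 1, \mathrm{NA}\}$: within outcome year $t$
(days $[365t, 365(t+1))$ from onset), the last valid outpatient kidney
lab decides the status — 1 if abnormal (MDRD eGFR below 60
mL/min/1.73m$^2$, or a urine albumin- or protein-to-creatinine ratio of
30 mg/g or greater), 0 if normal, `NA` when no qualifying lab was
collected, with no imputation.  Sequences truncate at the first 1.  A
patient is *eligible* at landmark $t$ when $y^t$ is non-missing and no
earlier status was 1; missing years do not censor later eligibility, so
$(0, \mathrm{NA}, 1)$ contributes at $t \in \{0, 2\}$.

## The landmark-boosting model

All models share one base learner: a second-order (Newton) boosted tree
classifier on the binomial log-loss.  Per boosting round, with current
margin $F(x_i)$ and $p_i = \sigma(F(x_i))$, gradients $g_i = p_i - y_i$
and hessians $h_i = p_i(1-p_i)$ drive an exact greedy, depth-limited
regression tree; split gain is
$\tfrac12\!\left[\frac{G_L^2}{H_L+\lambda} + \frac{G_R^2}{H_R+\lambda} -
\frac{G^2}{H+\lambda}\right]$ and leaf weights are $-G/(H+\lambda)$.
Missing values are handled sparsity-aware: every candidate split scores
both routings of the missing rows and an explicit present-vs-missing
split, keeping the gain maximiser.  Binary (presence-only) features
encode absence as 0; numeric absence is a genuine missing value, so
informative missingness is available to the trees.

Landmark-boosting chains these fits over landmark times:

* $t = 0$: an ordinary boosted fit on the eligible patients, zero
  baseline margin.
* $t \ge 1$: each eligible patient carries
  $\mathrm{logit}(\hat p^{(t-1)}_i)$ — the previous prediction on its own
  predictors — as a fixed per-row baseline margin, and new trees are
  ensembled on top of it using the predictors *updated at* $t$
  (latest-value aggregates as of day $365t$).  Patients without an
  earlier prediction start from a cold-start margin, the log-odds of the
  landmark's training prevalence.

Formally each landmark solves
$\min E_{t|t-1}\,L\!\left(y,\; F_t(x_t,\, F_{t-1}(x_{t-1}, y_{t-1}))\right)$
with $L$ the log-loss: a stagewise approximation in which the previous
prediction acts as the individual's prior risk and the new ensemble fits
the current population.

### Comparator representations

* **Latest-value**: one independent boosted fit per landmark on each
  predictor's last observed value before the landmark (time-agnostic).
* **Stack-temporal**: one independent fit per landmark on per-window
  columns — window 0 is the pre-onset history, window $w \ge 1$ covers
  days $[365(w-1), 365w)$ — so the feature dimension grows linearly,
  $p = \text{features} \times (t+1)$.
* **Discrete-survival**: a single pooled fit on one pseudo-observation
  per patient per eligible window (predictors from the window preceding
  the landmark, plus a window-index column), rows treated as
  independent.

## Design choices in the open

**Cross-fitted carried baselines.**  The carried margin of a *training*
patient is, by default, an out-of-fold prediction (5 folds): a model's
in-sample predictions partly memorise its training labels, and every
patient eligible at $t$ carried label 0 at $t-1$, so in-sample carrying
systematically deflates training margins relative to the honest
out-of-sample margins used when scoring new patients.  In simulation this
distribution mismatch is large enough to push landmark-boosting below the
latest-value baseline; cross-fitting removes it.  `cross_fit_folds = 1`
restores plain in-sample carrying.

**Carrying over missing years.**  A patient whose status was `NA` at
$t-1$ but who was predicted at an earlier landmark carries their most
recent available prediction (`carry = "latest"`); the stricter rule that
cold-starts everyone without a $t-1$ prediction is available as
`carry = "previous_only"`.  The default preserves individual history —
the point of the method — instead of resetting such patients to the
population prevalence.

**Early stopping.**  Boosting stops once the holdout AUROC (stratified
20% of the landmark's training rows) has not improved for
`early_stop_rounds` rounds (default 100), within a `max_trees` cap
(default 1000).  All trees grown up to the stop are kept: rounds beyond
the AUROC peak no longer change the ranking but keep refining the
probability scale, which matters for the observed-to-expected (O:E)
calibration.

**Window and tie conventions.**  Yearly windows are half-open,
$[365t, 365(t+1))$ days from onset; designs only use events with day
$< 365t$ (the leakage guard is tested by mutating post-landmark events
and asserting byte-identical training artifacts).  Same-day duplicate
numeric observations average; duplicate binary observations count once.
Split thresholds are midpoints of consecutive distinct observed values,
scanned in feature order then ascending threshold order with missing-left
scored before missing-right, and a candidate replaces the incumbent only
on strict gain improvement — fits are therefore deterministic and
row-order invariant up to floating-point rounding.  Probabilities are
clipped to $[10^{-6}, 1-10^{-6}]$ before any logit.  The top-40%
threshold flags $\lceil 0.4 n \rceil$ examples with stable
score-then-index tie-breaking; risk percentiles use average ranks scaled
to $[0, 100]$.

**Calibration flags.**  A 20-bin O:E table flags a bin overpredicted
(underpredicted) when a two-sided exact binomial test of the observed
count against $\mathrm{Bin}(n_b, E_b/n_b)$ rejects at $\alpha = 0.05$
with $O < E$ ($O > E$); a Poisson test is available where bin sizes are
large.

**Hyperparameters.**  `gbm_control()` validates depth (1–10; the tuning
grid spans the conventional 2–10), learning rate (0.01–0.1 grid, default
0.1), minimal child weight (minimum hessian sum per child, 1–10 grid)
and the L2 leaf penalty $\lambda$ (default 1; never reported for the
reference implementation, so it is exposed).  `tune_by_cv()` performs
stratified 10-fold cross-validation over a grid with ties broken toward
the smaller depth, then the smaller learning rate; landmark fits can
re-tune per landmark or reuse the first landmark's winner.

## What the synthetic cohorts emulate

`generate_cohort()` produces event tables whose *statistical* structure
matches what the analysis assumes, without claiming clinical realism:

* ten event domains with per-domain encounter renewal processes (gamma
  gaps at both the between- and within-patient level, mean-preserving
  under the positivity floors) whose mean gaps and variability default
  to the observation intensities reported for integrated clinical
  repositories (e.g. visits every ~36 days, billing data every ~228);
  dispersion is capped at the exponential, because at the raw reported
  between-patient spreads most patients' gaps would be unobservable
  inside a few-year window and the configured mean intensity could never
  be recovered from the emitted record;
* sparse binary carrier features and numeric features observed as noisy
  snapshots of static patient-level latents (measurement error is a
  first-class parameter, default equal to the between-patient spread);
* yearly outcomes drawn from a per-landmark logistic hazard on the
  centred latents, with missing outcome years (`NA`, default rate 0.2),
  yearly dropout (default 0.08), exit after the first recorded event,
  and one outpatient kidney lab per observed year whose value encodes
  the realised status;
* diabetes-onset anchor labs (two qualifying HbA1c records) and a normal
  pre-onset kidney lab, so the phenotyping layer runs unmodified on
  simulated data; two years of pre-onset history feed the first
  landmark.

Each patient draws from an RNG stream derived from the master seed and
the patient index, so cohorts are byte-reproducible.

Two presets define the canonical study conditions (4,000 patients, five
landmarks), deliberately placed at two ends of a regime axis.
`time_constant` is a compact, precisely measured, stationary world: four
strong fixed effects, small measurement error, flat baseline hazard
0.18.  Every landmark's data suffice to learn the whole risk surface, so
the choice of temporal representation should not matter and a correctly
fitted model should be calibrated (O:E near 1) — the preset exists as a
sanity endpoint.  `time_varying` is the regime the landmark scheme
targets: risk carried by ten repeatedly measured numeric markers
observed with measurement error 1.5 times the between-patient spread
(any single latest value is a coarse snapshot), one effect flipping sign
and one fading across landmarks, and the baseline hazard rising
0.156 → 0.257 to mirror the observed case-mix shift (eligible cohorts
shrink roughly 27% per year while yearly event prevalence climbs from
~16% to ~26%).  Here the carried baseline integrates several years of
noisy measurements where the latest-value snapshot cannot, and transfers
what was learned on the large early cohorts to the small late ones.

What the presets deliberately do **not** emulate: real vocabulary
semantics and comorbidity co-occurrence, time-varying latents
(progression trajectories), informative observation processes (sicker
patients measured more often), calendar-time practice drift, and
measurement error in the outcome labs themselves.  Passing the simulation
checks therefore shows the machinery is correct and the method behaves as
designed *under its own assumptions* — not that it will dominate on any
particular real cohort.

## Problem sizes used in the checks

The packaged checks run the presets at 4,000 patients (method
comparisons over 10 seeded replicates, half the cohort held out for
evaluation so per-landmark test sets stay informative), 10,000 patients
for the calibration check (swap-half cross-validation: fit on each half,
score the other, pool, so every patient is evaluated out-of-sample and
per-landmark observed-to-expected ratios are not dominated by split
noise), 20,000 for logistic recovery of the generating effects, and
2,000 for the observation-intensity moments;
boosted fits for these comparisons use depth 2, learning rate 0.1,
minimal child weight 5, $\lambda = 5$, at most 250 trees with patience
30 — a configuration chosen for stability on cohorts of this size, with
the full grid available through `tune_by_cv()`.

## Limitations

* The carried baseline is a scalar: corrections that depend on *which*
  historical evidence produced the previous risk are only available to
  the new trees through the updated predictors.
* Per-landmark models never revisit earlier ensembles, so a
  badly fitted early landmark propagates until the new trees unlearn it;
  the cross-fitting default mitigates but does not eliminate this.
* Feature-importance rank drift (`importance_rank_drift()`) uses
  gain-based importance, which is known to favour high-cardinality
  numeric features over binary indicators.
* The simulation presets are a scaled-down world: absolute discrimination
  levels are not comparable to values achievable on real,
  feature-rich clinical records.
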