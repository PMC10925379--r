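---
title: "Methods: uncertainty-gated multi-stage classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty-gated multi-stage classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uqcascade)
```

## The problem

Clinical prediction models usually assume every modality is on the table at
inference time. In practice data arrive in stages: routine clinical
variables and an ECG are cheap; SPECT myocardial perfusion imaging costs
money, time and radiation exposure. For predicting response to cardiac
resynchronization therapy (CRT), the question is not only *who will
respond* but *for whom is the expensive second-stage acquisition actually
necessary*.

`uqcascade` models this as selective prediction with a reject option. A
first-stage ensemble predicts the binary outcome from cheap (stage-1)
features and quantifies its own uncertainty; a rule-based gate sends only
uncertain patients on to a second-stage ensemble that additionally uses
the expensive (stage-2) features.

## Model components

### Pseudo-bootstrapped ensembles with uncertainty

Each stage's model is an ensemble of B elastic-net logistic regressions.
Member b is fitted on a random subset of `round(phi * n)` training rows
drawn **without replacement** — the tunable fraction `phi`, not the
classical with-replacement bootstrap, is what perturbs the members (hence
"pseudo-bootstrap"; `phi = 1` makes all members identical). For a new
patient the ensemble reports

* `p_mean`, the arithmetic mean of the member probabilities — the
  prediction; and
* `p_std`, their sample standard deviation (denominator B−1; defined as 0
  for B = 1, with a warning at fit time) — the uncertainty.

Preprocessing (centering, scaling by the sample standard deviation, then
the spatial-sign projection of each row onto the unit sphere) is fitted
once on the full training partition and shared by the members. Fitting it
per member would give each member its own geometry and make the member
disagreement partly an artifact of preprocessing noise. The spatial sign
transform blunts the leverage of outlying patients; we apply it to the
full model feature set after one-hot expansion and standardization, the
classical "center/scale then project" recipe. Two numerical edge cases are
handled explicitly: an all-zero standardized row cannot be projected and
is left at zero (warning), and a *single* retained feature is never
projected, because dividing a scalar by its absolute value collapses it to
its sign and destroys all magnitude information.

The elastic-net objective is the standard one — mean negative Bernoulli
log-likelihood plus `lambda * (alpha*L1 + (1-alpha)/2*L2)` on the slopes,
intercept unpenalized — fitted by `glmnet` at a single fixed `lambda` on
the already-standardized matrix. Defaults are `alpha = 0.5` and
`lambda = 0.01`. The penalty is deliberately weak: after the sphere
projection every row has unit norm, so feature scales are compressed by
roughly the square root of the feature count and a nominally moderate
penalty acts much more strongly than it would on unprojected data (at
`lambda = 0.05` we observed the probability range collapsing toward the
prevalence, which blinds both the midway gate and the uncertainty signal).

### Feature selection and hyperparameter tuning

Recursive feature elimination refits the base learner along a halving
schedule (p, p/2, …, 1), ranking features by absolute standardized
coefficient — the modelled protocol prescribes RFE but no ranking
criterion, and coefficient magnitude is the natural choice for a linear
base learner. The
retained subset is the smallest whose cross-validated AUC lies within
`tol = 0.002` of the best schedule entry (the usual parsimony rule; exact
ties always go to the smaller subset). Ensemble hyperparameters
(`n_models`, `sample_fraction`, optionally `alpha`/`lambda`) can be tuned
by inner cross-validation on the remaining training rows; the inner metric
is AUC, matching the outer objective, with ties broken toward fewer base
models and then a larger sample fraction. The default grids cover the
hyperparameter values the modelled protocol reports selecting across its
folds (B ∈ {25, 34, 37, 40, 49}, phi ∈ {0.70, 0.84, 0.85, 0.86, 0.95});
the default fixed specification B = 25, phi = 0.95 is the modal entry.

### The gate

A patient is escalated to stage 2 iff

```
p_std > tau_sigma   OR   |p_mean - 0.5| < tau_m
```

with strict inequalities. The two clauses are deliberately independent —
one catches unstable predictions, the other equivocal ones near the 0.5
decision midpoint ("midway" is read as distance from the midpoint; the
source describes the two thresholds only verbally). Escalated patients
take Ensemble 2's `p_mean` outright; stages are never blended. Final
class labels, where needed, use a fixed 0.5 cutoff on the final
probability.

### Tuning the gate: scaled weighted AUC

Thresholds are tuned on a first held-out validation slice by maximizing

```
objective(tau_sigma, tau_m; s) = AUC(cascade) * w(f; s)
```

where `f` is the fraction of validation patients resolved at stage 1 and
`w` is a weight in [0, 1], nondecreasing in both `f` and the scaling
parameter `s ∈ [0.5, 9]`, with `w(0) = 0` and `w(1) = 1`. Ties go to the
policy escalating fewer patients, then to the larger `tau_sigma`. The
whole tuning is repeated for each `s` on the grid {0.5, 1, 2, …, 9}, and a
second, disjoint validation slice picks the candidate with the highest
*plain* AUC (ties again to fewer escalations). Both slices are drawn once
per fit, so every `s` is tuned on identical data.

The exact shape of `w` is not recoverable from the source, so it is
configurable. The default is the saturating form

```
w(f; s) = 1 - (1 - f)^s
```

which is close to 1 for moderate `f` and collapses only as `f → 0`: it
penalizes *universal* escalation — the stated purpose of the weight —
while letting a genuinely better escalation pattern win. The steeper
power form `w = f^(1/s)` is also provided
(`cascade_config(weight_form = "power")`). We made the saturating form the
default after finding that under the power form the weight cost of
escalating 40–60% of patients (≈5–9% of the objective even at `s = 9`)
exceeds the achievable AUC gain whenever the two ensembles sit in the
realistic 0.70–0.80 AUC band, so the tuned cascade would almost never
leave stage 1 — inconsistent with the reference behaviour this package
models, where roughly half the patients are escalated at no material AUC
cost.

### Evaluation protocol

`run_nested_cv()` wraps everything in stratified nested cross-validation:
10 outer folds by default (for 218 patients: outer training folds of 196
± 1, test folds of 22 ± 1); within each outer training fold two
validation slices of 20 patients each are cut (remaining training set 156
± 1), used only for gate tuning and scaling selection. Outer folds and
slices are stratified by outcome — with 20-patient slices an unstratified
draw can easily lose a class. A programmatic leakage audit checks on
every fold that the test rows are disjoint from every fitting slice and
that the folds partition the cohort. All randomness descends from one
integer seed through a fixed stream-splitting scheme, so a run is exactly
reproducible and `emit_report()` replays byte-identically.

Metrics are AUC (exact Mann–Whitney concordance with midranks), accuracy,
sensitivity and specificity at the 0.5 cutoff, aggregated as unweighted
mean (sd) over folds, plus the mean and quartiles of the per-fold stage-1
fraction. Model comparisons use the DeLong test for paired AUCs (via
pROC, with a degenerate-variance guard returning p = 1 flagged) and
McNemar's test on paired correctness, exact binomial below 25 discordant
pairs and continuity-corrected chi-square above (the switch point is a
convention, exposed as an argument). Baseline tables use chi-square tests
for categorical variables and Welch's t-test for continuous ones — the
unequal-variance form is the safer default when the source says only
"two-sample t-test". The guideline comparator is a first-match rule table
(editable data, not code) mapping LVEF, LBBB, QRS duration and NYHA class
to recommendation classes I/IIa/none, predicting response for classes I
and IIa; it has no AUC because it emits labels, not scores.

`sample_size_simulation()` resamples each outer training fold **with
replacement** at fractions 0.1–1.0 (three repeats each, test folds
untouched) — note this sampler is deliberately distinct from the
without-replacement pseudo-bootstrap inside the ensembles.

## The synthetic cohort generator

No patient-level data ship with the package (the study cohort is
available only on request), so `synth_cohort()` generates cohorts with
known ground truth. It emulates the modelled data's structure: n = 218 by
default, a binary outcome calibrated to 55.5% prevalence (intercept found
by bisection against the expected prevalence of the drawn design,
tolerance 0.005), 14 stage-1 and 30 stage-2 features mixing continuous
(AR(1)-correlated, lag 0.2) and binary columns, and a configurable
*ambiguous subgroup*: the fraction `rho` of patients whose stage-1 linear
predictor lies nearest its cohort median. For these patients the residual
stage-1 signal is attenuated (factor 0.1) and the outcome is driven by
the stage-2 features instead. This construction — attenuation rather than
added noise — makes stage-1 predictions for subgroup members equivocal
(near the decision midpoint) and more variable under subsampling, so the
uncertainty signal the gate relies on exists by construction, while
stage-2 features carry genuine incremental signal exactly there.

Default effect sizes place the fitted models in the performance regime
the package targets: stage-1 coefficients 0.55 × a decaying
alternating-sign pattern (first-stage ensemble AUC ≈ 0.70 at a few
hundred training rows), stage-2 coefficients 2 × the pattern (the
subgroup's outcome is strongly predictable from the expensive modality,
whose cohort-level coefficient is diluted by the subgroup fraction in a
global linear fit). What the generator does **not** emulate: the real
cohort's covariance structure and marginal distributions (its published
baseline table is internally inconsistent and was not reverse-engineered),
missingness, measurement error in SPECT-derived quantities, or site
effects. Tests passing on these cohorts therefore demonstrate that the
machinery recovers planted structure — not that it would achieve any
particular performance on real patients.

## Problem sizes used by the tests

The test-suite and acceptance computations run at deliberately modest
scale: the gating experiment uses one generated cohort of n = 1000 with
`rho = 0.4`, evaluated by 5-fold nested cross-validation with 100-patient
validation slices (larger slices than the 20-patient study default, in
proportion to the larger cohort, so that gate tuning is not dominated by
slice noise); the protocol-shape check runs the full 10-fold plan at
n = 218; the sample-size simulation uses n = 300 with 3 outer folds, 10
fractions and 3 repeats. Oracle checks (all-pairs AUC, binomial McNemar,
bootstrap DeLong) use 1000 random instances, closed forms, and 10,000
bootstrap replicates respectively.

## Known limitations

* Only two stages; the interface does not yet admit a third.
* Only elastic-net logistic base learners; the ensemble container would
  accept other members but none are implemented.
* Cost is proxied entirely by the fraction of patients escalated; no
  monetary or risk weighting.
* The gate thresholds are tuned on small validation slices by design;
  with 20-patient slices the selected policies vary widely across folds.
  This mirrors the reference protocol rather than improving on it.
* No calibration assessment (Brier score, reliability curves) in this
  version.

## A minimal run

```{r example, eval = FALSE}
sc <- synth_cohort(synth_spec(n = 400, rho = 0.4, seed = 1))
fit <- cascade_fit(sc$cohort, seed = 1)
summary(fit)

res <- run_nested_cv(sc$cohort,
                     plan = cv_plan(n_outer_folds = 5, seed = 1))
print(res)
```
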