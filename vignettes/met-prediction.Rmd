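---
title: "Estimating METs of daily activities from heart-rate reserve: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating METs of daily activities from heart-rate reserve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrmets)
```

## The problem

Heart-rate monitors are cheap and ubiquitous, but raw heart rate is a poor
proxy for the energy cost of an activity: at the same workload, a fit
subject's heart rate is far lower than an unfit subject's, and classic
HR-to-energy-expenditure equations therefore require an individual
calibration session with gas-exchange measurement. `hrmets` implements a
calibration-free alternative: predict the metabolic equivalent (MET) of an
activity directly from **percent heart-rate reserve**,

$$\%HRR = \frac{HR_{activity} - HR_{rest}}{HR_{max} - HR_{rest}} \times 100,$$

with $HR_{max} = 208 - 0.7 \times \mathrm{age}$ (the Tanaka equation) and
$HR_{rest}$ the per-minute-averaged heart rate over 7 minutes of seated
rest. Because %HRR is normalized to each subject's own resting and maximal
heart rate, and METs are normalized to each subject's own resting energy
expenditure ($\mathrm{METs} = EE_{activity}/EE_{rest,\,sitting}$, with EE
from the abbreviated Weir equation
$EE = 3.941\,\dot VO_2 + 1.106\,\dot VCO_2$ kcal/min), both sides of the
regression are relative quantities and individual fitness differences
largely cancel. The shipped equations were developed on 40 adults (20 male,
20 female, ages 20–59, stratified 4–6 per sex-by-decade cell) performing 20
everyday activities from phone use to jogging, pooling 673 subject-activity
observations.

The package covers the full pipeline: R-R interval preprocessing,
physiological transforms, the published equations, de-novo model
development by exhaustive subset search, and validation. A synthetic-cohort
generator reproduces the study's statistical structure so that every stage
is testable end to end.

## R-R preprocessing

`rr_to_epoch_hr()` converts a beat-by-beat R-R log into heart rates on a
fixed 0.4-s epoch grid. Each beat with interval $rr$ ending at time $t$
occupies $[t - rr, t]$, and an epoch's heart rate is $60$ divided by the
overlap-weighted mean R-R of the beats covering it. We chose overlap
weighting over nearest-beat assignment because it is exact for constant
traces, has no boundary ambiguity, and is easy to verify against a
beat-by-beat brute-force oracle (the tests do exactly that). Epochs with no
beat coverage are missing.

`remove_epoch_outliers()` then screens epochs against mean ± k·SD — k = 4
for radio calisthenics, whose rhythmic whole-body movement produces
heavier-tailed epochs, k = 3 for all other activities. Three conventions
deserve note, as the protocol we follow does not pin them down:

* the mean and SD are taken over the **whole activity recording in a
  single pass**, not a rolling window — the simplest reading, and the one
  that makes the screen idempotent up to newly recomputed outliers;
* a constant trace (SD = 0) is artifact-free by construction, so nothing
  is removed rather than dividing by zero;
* the screen marks epochs missing; it never shortens the grid.

`activity_mean_hr()` averages per minute first, then averages the minute
means without weighting, so a sparsely covered minute counts the same as a
full one. Minutes whose epochs were all removed are dropped, not imputed.
A partial trailing minute is kept when it holds at least 15 s of epochs —
a cutoff we fixed once (a quarter minute) because the source protocol is
silent; shorter fragments are too noisy to stand as an equal-weight
"minute". `resting_hr_from_window()` applies the same rule to the opening
7-min seated window.

## The models

`published_models()` ships the six fitted equations — two with absolute HR
(`HR`, `HR+RHR`) and four with %HRR (`HRR`, `HRR+RHR`, `HRR+RHR+SEX`,
`HRR+RHR+HT`) — with their intercepts, coefficients, standardized
coefficients and fit statistics (r, R², SEE). `predict_mets()` evaluates
them strictly: the feature set must match the model exactly, height is in
centimetres, sex is coded male = 1 / female = 0, and predictions are not
clamped below 1 MET (the source equations apply no clamp; the %HRR-only
model can dip below 1 at slightly negative %HRR).

```{r published}
predict_mets("HRR", c(pct_hrr = 73.4))
predict_mets("HRR+RHR+HT",
             c(pct_hrr = 25, resting_hr = 65, height = 170))
```

## Model development

`enumerate_candidates()` reproduces the development protocol: one
heart-rate variable (HR or %HRR — never both, their correlation is ~0.93)
is mandatory in every candidate, combined with every subset of the
covariates in two families: family A allows weight and height (BMI
excluded), family B allows BMI (weight and height excluded), because BMI
and weight are strongly collinear. That gives 2⁵ = 32 candidates in family
A and 2⁴ = 16 in family B. Whether the heart-rate variable was truly forced
during the original search is not documented, so `force_hr = FALSE`
additionally enumerates covariate-only subsets.

`fit_ols()` fits each candidate by least squares on the pooled
observations and computes the full panel: SEE $= \sqrt{RSS/(n-k-1)}$,
standardized β $= \hat\beta_j \, SD(x_j)/SD(y)$, VIF from auxiliary
regressions of each predictor on the others, and AIC in the least-squares
profile form

$$AIC = n \ln(RSS/n) + 2(k + 2),$$

counting the $k$ slopes, the intercept and the error variance. The source
analysis cites AIC without a formula; the full Gaussian log-likelihood form
differs from ours by the constant $n(\ln 2\pi + 1)$ at fixed $n$, so the
two rank candidates identically (a test verifies this), and rankings — not
absolute AIC values — are the contract. If RSS is exactly zero the AIC is
degenerate at $-\infty$; selection then falls back to the fewest-predictor
zero-RSS model.

`select_best()` screens candidates before ranking: a model is excluded if
any coefficient's sign contradicts its predictor's marginal correlation
with METs (the classic suppressor-variable symptom; exact zeros pass by
convention), or if any VIF reaches 10. VIF = 1.1 — the value the original
analysis verified — is a report-only flag, not an exclusion rule, because
it was an observed property of that cohort, not a stated criterion. Ties in
AIC break toward fewer predictors, then lexicographically, making selection
deterministic. One caution: minimum AIC and maximum adjusted R² usually
coincide here but are not equivalent — AIC charges 2 per parameter while
adjusted R² charges the equivalent of $|t| > 1$ — so a marginal noise
covariate can top adjusted R² while losing on AIC; the package treats AIC
as the selector and the adjusted-R² agreement as approximate.

## Validation

`loso_predict()` implements leave-one-**subject**-out: all ~20 observations
of a subject leave together, the model is refitted on the remaining
subjects, and the held-out subject's observations are predicted. Leaving
out single observations instead would leak the subject's own
resting-HR/height/sex values into the training fold and flatter the error.
Errors are summarized by `activity_report()` as per-activity MPE
(mean ± SD of $(\hat y - y)/y \times 100$, pooled over leave-out
predictions), RMSE, and a two-sided Wilcoxon signed-rank test (exact below
25 pairs, normal approximation above). `bland_altman()` reports the bias,
the 95% limits of agreement $\pm 1.96\,SD$ of the differences, and the
trend of differences against the magnitude axis — the **measured** METs by
default (the reference method), the classic pair-mean axis via
`axis = "mean"`. `holdout_rmse()` repeats a 2:1 subject-level split
(development = round(2n/3) subjects), averaging per-activity RMSE over the
repetitions in which the activity reaches the validation fold; the default
10,000 repetitions follow the original protocol, while a few hundred give
per-activity averages stable to well under 0.02 METs (the test suite uses
500).

## The synthetic cohort generator

No subject-level data were deposited, so `generate_subjects()` /
`generate_observations()` build cohorts with the study's documented
structure: per-cell Gaussian anthropometrics (truncated at ±3 SD to avoid
impossible bodies, ages additionally to their decade), cell counts of 4–6
constrained to 20 per sex, per-activity %HRR Gaussians truncated below at
−5% (the lightest activities average ~1% with SD ~4, so mildly negative
values are legitimate), activity heart rates back-computed from each
subject's own resting HR and predicted HRmax for internal consistency, and
METs drawn from a configurable linear truth (`true_model_spec()`,
defaulting to the shipped three-predictor equation with residual SD equal
to its SEE of 0.623 METs). Because METs are a ratio of positive energy
expenditures, residual draws that would push a light activity to zero or
below are redrawn by default (`positive_mets = TRUE`); the truncation
touches only the lower tail of the lightest activities. Homoscedastic
Gaussian noise and a strict positivity constraint cannot both hold exactly,
and the truncation slightly biases refits of the generating equation (on
the order of half a percent on the %HRR slope), so calibration-recovery
experiments use `positive_mets = FALSE` — the exact Gaussian design, under
which refitting is unbiased — at the price of occasional non-physical METs. The `"table2"` missing-data mode thins each
activity uniformly at random to the published per-activity counts — who
actually dropped out is unknown — reproducing the 673 pooled observations.

Within sex, resting HR, height and weight are drawn independently: the
observed VIF < 1.1 says the real cohort was close to that, but only
approximately, and chance correlations at n = 40 subjects remain visible
in any single cohort. The generator's population R² can be computed
analytically from the configured variances (`expected_r2()`; 0.892 for the
default truth, against 0.890 published), and a calibrated mode rescales
the linear predictor's spread to hit a user-supplied R² exactly, for
fit-statistic recovery experiments.

What the generator does **not** emulate: heteroscedastic residuals (real
RMSE grows with activity intensity; synthetic residuals are homoscedastic
Gaussian, so per-activity RMSE is flat up to leverage effects), HR
on-kinetics and drift within an activity, gas-analyzer noise spectra, and
any genuine correlation between %HRR responses and fitness. Passing
recovery tests on synthetic cohorts therefore demonstrates that the
estimation machinery is correct under the stated model, not that the model
describes any new population.

`generate_rr_series()` emulates beat-to-beat logs for the preprocessing
stage: multiplicative jitter (default 5% relative SD, a typical resting
beat-to-beat variability) around 60/HR, with detection artifacts at a
configurable rate — half missed beats (doubled interval), half spurious
detections (interval shrunk to 35%) — which the ±3 SD epoch screen is
expected to catch.

## Worked example

```{r example}
subjects <- generate_subjects(seed = 1)
observations <- generate_observations(subjects,
                                      missing_pattern = "table2", seed = 2)
nrow(observations)

spec <- candidate_spec("pct_hrr", c("resting_hr", "height"), "A")
fit <- fit_ols(observations, spec, subjects)
fit

pairs <- loso_predict(observations, subjects, spec)
bland_altman(pairs$measured, pairs$estimated)
```

## Numerical conventions and problem sizes

All randomness flows through explicit integer seeds; every generator output
is a pure function of (configuration, seed). Resampling experiments in the
documentation and tests use desk-scale sizes chosen for statistical
sufficiency: 100 cohorts for coefficient/SEE recovery (Monte-Carlo SE of
the mean %HRR coefficient ≈ 1.5 × 10⁻⁴), 50 leave-one-out runs for the
limits-of-agreement mode, and 500 hold-out repetitions (per-activity
averages reproducible to < 0.02 METs across independent runs).

## Known limitations

* Pooled OLS ignores the repeated-measures structure (each subject
  contributes ~17 observations with identical resting HR, height and sex);
  the original analysis shares this limitation and flags it as a potential
  overfitting source. A mixed-effects treatment is out of scope.
* The MPE's SD aggregates pooled observations per activity; aggregation
  across subjects first would give slightly different SDs.
* Comparator equations from other laboratories are not shipped — their
  coefficients are not reproduced here — but `predict_mets()`'s strict
  feature interface makes plugging them in straightforward.
* predictions are unclamped and can fall below 1 MET near rest.
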