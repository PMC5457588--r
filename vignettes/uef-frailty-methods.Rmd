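---
title: "Methods: the upper-extremity-function frailty index and score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the upper-extremity-function frailty index and score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uefrailty)
```

## The problem

The Fried phenotype stages frailty in older adults as non-frail, pre-frail
or frail from five criteria (weight loss, exhaustion, low activity, grip
weakness, slow gait), but administering it needs walking space and time.
The upper-extremity-function (UEF) test replaces it with a 20-second trial
of repetitive, maximal-pace elbow flexion/extension recorded by angular-rate
sensors on the forearm and upper arm. The premise is that sarcopenia affects
the whole muscular system, so slowness, weakness, exhaustion (muscle
fatigue) and reduced flexibility are measurable at the elbow.

This package implements the full method: trace processing, the eight
elbow-motion outcomes, a proportional-odds categorical index with its
development pipeline, and a Framingham-style continuous 0-1 score, plus a
synthetic data generator so every stage is testable without subject data.

## The eight elbow-motion outcomes

Trials are segmented into flexion/extension cycles; all outcomes are
per-cycle quantities aggregated over the trial:

| outcome | definition | unit |
|---|---|---|
| speed | mean per-cycle angular-velocity range (max - min) | deg/s |
| flexibility | mean per-cycle elbow flexion (angle) range | deg |
| power | mean per-cycle (acceleration range x velocity range) | deg^2/s^3 |
| rise time | mean time from cycle onset to peak velocity | s |
| moment | mean per-cycle peak elbow moment, I x peak acceleration | Nm |
| speed variability | CV (%) of per-cycle velocity ranges | % |
| speed reduction | % change of mean velocity range, last vs first 5 s | % |
| flexion number | cycle count in 20 s | count |

Speed reduction is negative when the subject slows, the muscle-fatigue
signature. The moment uses the forearm+hand moment of inertia about the
elbow from anthropometric fractions (segment mass 0.022 of body mass,
segment length 0.254 of stature, radius of gyration 0.827 of segment
length, all configurable), with accelerations converted to rad/s^2.

### Numerical choices in the extraction

Cycle segmentation is not prescribed by the outcome definitions, so the
package makes it explicit and configurable:

* Candidate cycle onsets are positive-going zero crossings of a
  zero-phase 4th-order Butterworth low-pass copy (default cutoff 3 Hz).
  Detection runs on the filtered copy only; all outcome arithmetic uses
  the raw series.
* Onsets closer than a minimum cycle duration (0.25 s) are merged.
  Candidate cycles whose raw velocity range falls below 10% of the median
  candidate range, or below an absolute 20 deg/s noise floor, are
  discarded; an all-zero or all-noise series therefore yields zero cycles
  rather than an error or spurious counts.
* Leading and trailing partial segments are admitted as candidates under
  the same rules, so edge cycles are treated symmetrically in time.
* Elbow angle comes from trapezoidal integration of velocity with a
  per-cycle linear detrend: raw gyroscope integration drifts without
  bound, and the detrend removes the drift while leaving within-cycle
  excursion intact.
* Channel bias is estimated from an initial rest window when one exists
  (`rest_window`, default 0 s); the simulator emits traces that begin
  mid-movement, so it defaults off.
* Fatigue windows: a cycle belongs to the first/last 5 s if its midpoint
  time falls in the window. Midpoint assignment is deterministic for
  cycles straddling the window edge.

On a noise-free sinusoid (A = 200 deg/s, f = 0.5 Hz) the extractor
reproduces the closed forms - 10 cycles, speed 400 deg/s, flexibility
2A/(2 pi f) = 127.3 deg, rise time 0.5 s, power (4 pi f A)(2A) = 5.03e5
deg^2/s^3 - within 2%; this is asserted in the test suite.

## The categorical index: proportional-odds model

The index is a cumulative-logit (proportional-odds) model over the ordered
categories non-frail < pre-frail < frail:

$$P(Y \le k \mid x) = \mathrm{logistic}(\alpha_k + x^\top \beta), \qquad
  \alpha_1 < \alpha_2.$$

Orientation: a larger linear predictor pushes mass toward the less frail
categories, so positive coefficients are protective. This orientation makes
the published index coefficients coherent (positive for speed, flexibility,
log moment and flexion number; negative for age and BMI). The elbow moment
enters as its natural logarithm (standard in the points-score methodology
the score borrows from); sex is coded as a female indicator.

`propodds()` maximises the likelihood by damped Newton iterations with
analytic gradient and Hessian, starting from the closed-form intercept-only
solution (the cumulative logits of the empirical category proportions).
Steps are halved until the likelihood increases and the intercepts stay
ordered; convergence is declared when the largest score component falls
below 1e-8 (at most 100 iterations). The covariance is the inverse observed
information, and AIC = 2p - 2logL. Degenerate inputs are handled
explicitly: constant predictors are pinned at zero with `NA` variance
rather than failing; rank-deficient designs raise an error naming the
collinear columns; runaway standardised coefficients (|beta| x sd > 30)
raise a separation error naming the offending predictor. The fitter is
cross-checked in the tests against an independent ordinal regression
routine (`MASS::polr`) to at least four decimals on coefficients and
standard errors.

One sign caveat worth recording: in the published coefficient table the
speed-reduction coefficient is negative, which under this orientation reads
"more fatigue-related slowing predicts less frailty" - the opposite of the
marginal association. The same flip reproduces in fits to our synthetic
cohorts: conditional on speed, variability and flexion number, the residual
association of speed reduction can invert. The package keeps the outcome's
definition (negative = slowing) and lets fitted signs fall where the data
put them.

## The development pipeline

The index is developed in five steps, each exposed as a function:

1. **Descriptive screening** (`normality_screen()`): Shapiro-Wilk per
   outcome; when the raw test rejects at 0.05 and values are positive, the
   log is tested and a log transform recorded if it passes. Box-plot
   outliers (1.5 x IQR) are reported per frailty group and never removed.
2. **Univariate association** (`univariate_screen()`): one-predictor
   proportional-odds fits; outcomes with Wald p < 0.05 are selected. The
   threshold is a package default; on default synthetic cohorts all eight
   outcomes select, mirroring the strong marginal associations the index
   assumes.
3. **Collinearity** (`vif()`): VIF_j = 1/(1 - R^2_j), flagged above 10.
   Speed and power are near-duplicates by construction (both scale with
   velocity amplitude), the motivating case for this step.
4. **Forward stepwise selection** (`stepwise_aic()`): add the candidate
   lowering AIC most, stop when none lowers it; ties break by declaration
   order; candidates whose fit fails (e.g. an exact duplicate of a selected
   predictor) are skipped with a warning.
5. **Evaluation** (`crossval()`): stratified 10-fold cross-validation.

Fold assignment is stratified by frailty category: with only ~13% of
subjects frail, unstratified folds can lack frail members entirely, leaving
fold-level AUC undefined. Members of each category are dealt over the folds
in least-loaded order, so overall fold sizes differ by at most one and
every fold retains all three categories. Two dichotomisations give the two
AUCs: pre-frailty (non-frail vs pre-frail or frail, scored by
p(pre-frail) + p(frail)) and frailty (frail vs rest, scored by p(frail)).
AUC is the Mann-Whitney statistic (ties counted half), which the tests pin
against an exhaustive pairwise oracle. Accuracy defaults to three-class
arg-max agreement (ties classify toward the frailer category); a
dichotomised variant is selectable.

## The continuous score

The score converts the fitted index into integer points per variable, after
the cardiovascular risk-score methodology:

* For each scored variable the three frailty-group means are the reference
  values W; midpoints of adjacent means are the category cutoffs. The
  construction requires monotone group means; non-monotone variables raise
  an error naming the variable.
* Points for category j: round(beta_risk (W_j - W_ref) / B), rounding half
  away from zero, where beta_risk is the coefficient re-signed so larger
  risk means more points, and W_ref is the low-risk end, so points are
  non-negative and the reference category scores 0.
* The base constant B is the linear-predictor distance of a 4-year age
  increment, B = |beta_age| x 4 - age is used for B even though age and
  sex are excluded from the scored variables (they add no predictive value
  once the motion outcomes are in the model).
* A subject's score is the summed points divided by the maximum attainable
  total, landing on [0, 1] with 0 = most resilient, 1 = most frail. Values
  exactly on a cutoff go to the higher-risk category; variables whose three
  group means coincide carry no points and are excluded from the maximum.

On default synthetic cohorts the mean score increases strictly across the
Fried groups and the distribution is right-skewed; a gamma fit
(`gamma_fit()`, ML via `MASS::fitdistr` with a Kolmogorov-Smirnov
statistic) describes its shape. Because the score takes a few dozen
discrete values, the KS test against a continuous gamma can reject at
conventional levels even when the shape matches; the fitted parameters,
not the KS p-value, are the useful summary. Exact zero scores are offset
by half the smallest positive increment before fitting.

Design choices made here where the construction was genuinely open: the
normalisation is by the maximum attainable points (a published floor of 0.1
rather than 0 is not reproducible from the available description and is not
enforced); rounding ties go away from zero; the score's orientation is
fixed to "higher = frailer" even though published score-age and
score-cognition correlations appear inverted relative to that stated
orientation - on our synthetic cohorts the score correlates positively
with age, the coherent direction.

## The synthetic cohort generator

The generator exists so that the entire pipeline - extraction, modelling,
selection, validation, scoring - runs end-to-end under controlled truth.
It emulates a 352-subject cohort: group sizes are the largest-remainder
apportionment of the published prevalence (132/175/45), and per-group
demographics use the published means and SDs for age, height, BMI, MMSE
and sex ratio.

Distributional details:

* Demographics are truncated normals (age >= 60 per the inclusion
  criterion, MMSE in [0, 30], BMI > 10) with the location solved so the
  *truncated* mean equals the configured mean. Without this
  moment-matching, bounds near the location - the MMSE ceiling at 30
  especially - bias group means by several tenths of a point and distort
  the between-group contrasts the generator is supposed to reproduce.
* Weight is derived as BMI x height^2, so the anthropometrics are
  internally consistent and the BMI predictor has exactly its configured
  distribution; weight's emergent means land within ~1 kg of the published
  values.
* Per-group elbow-motion distributions are not published; the defaults
  impose the gradient the index presumes (non-frail to frail: cycle
  frequency 1.05/0.90/0.72 Hz, peak velocity 430/340/240 deg/s, range of
  motion 130/120/105 deg, fatigue decline 0.10/0.18/0.28, amplitude jitter
  CV 0.07/0.10/0.14), with magnitudes plausible for maximal-pace elbow
  flexion in older adults. All are configurable through
  `group_profile()`.
* Traces are trains of signed power-of-sine velocity pulses. The waveform
  exponent is solved per subject so the integrated angle matches the
  subject's range of motion, decoupling ROM from peak velocity at a given
  frequency. Per-cycle amplitude is linear in time through the first/last
  fatigue-window midpoints, so a configured decline of 0.2 produces a
  measured speed reduction of -20% by construction; multiplicative
  per-cycle jitter and additive white sensor noise (default 1.5 deg/s) are
  added, and the upper-arm channel is low-amplitude noise representing
  trunk stabilisation. The default sampling rate is 100 Hz, typical for
  wearable gyroscopes.

What the generator does *not* emulate: real gyroscope artefacts
(drift ramps, axis misalignment, soft-tissue oscillation), sex-specific
motion differences, the empirical covariance between demographics and
motion within groups, and outcome distributions calibrated to real
recordings. Passing tests therefore demonstrate the *machinery* - that the
extractor inverts the generative model, that the fitter recovers known
parameters, that selection and validation behave lawfully - not clinical
performance. Published real-data figures (whole-sample AUC 0.86/0.91,
cross-validated 0.77/0.80, AIC 461.72) are not reproduction targets: the
underlying cohort is not deposited, and our synthetic gradient is cleaner
than real data, so synthetic AUCs run higher (~0.93-0.98).

## Problem sizes and determinism

Simulation sizes used in the tests were chosen to keep the full suite
fast while leaving comfortable statistical margins: parameter recovery at
n = 5000, screening and selection behaviour at n = 500-2000, pipeline
end-to-end at the study size n = 352, distributional checks at
n = 1000-10000 draws. Every stochastic step takes an explicit seed and
restores the caller's RNG state; identical (configuration, seed) pairs
produce bit-identical cohorts, traces, folds and reports.

## A worked run

```{r, eval = FALSE}
sim <- generate_cohort(uef_config(), seed = 7)
cohort <- prepare_model_data(extract_cohort(sim))

univariate_screen(cohort)                       # all eight outcomes select
sel <- stepwise_aic(cohort,
                    candidates = c("speed", "flexibility", "log_moment",
                                   "speed_variability", "speed_reduction",
                                   "flexion_number", "bmi"))
crossval(cohort, sel$selected, k = 10, seed = 7)

full <- propodds(fried ~ speed + flexibility + log_moment +
                   speed_variability + speed_reduction + flexion_number +
                   bmi + age + sex_female, cohort)
card <- build_scorecard(full, group_means(cohort, names(full$coefficients)[1:7]))
scored <- score_cohort(card, cohort)
tapply(scored$uef_score, scored$fried, mean)
```

## Known limitations

* The segmentation thresholds (cutoff, minimum duration, range floors) are
  sensible defaults validated on synthetic waveforms, not tuned on real
  recordings.
* The separation heuristic (standardised coefficient > 30) can fire for
  extreme but estimable collinear pairs; in stepwise selection this is
  benign (the candidate is skipped), but direct fits of near-duplicate
  predictors will error by design.
* The published coefficient table's confidence intervals are not exactly
  Wald-form and one row's standard error appears duplicated from another;
  the shipped asset carries the printed estimates and SEs, and Wald
  intervals are always recomputed from them.
* Scorecard construction assumes monotone group means; with weak
  predictors at small n this can fail for individual variables, which then
  need to be dropped from the scored set (the error names them).
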