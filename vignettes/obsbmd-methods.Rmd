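---
title: "Methods: oxidative balance scoring and its association with bone mineral density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oxidative balance scoring and its association with bone mineral density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obsbmd)
```

This vignette documents the statistical machinery of `obsbmd`: the models,
their assumptions, the tunable parameters, the synthetic-data generator the
package validates itself against, and the numerical choices made where the
underlying methodology leaves room.

## 1. The oxidative balance score

The OBS aggregates 20 components — 16 dietary nutrient intakes and 4
lifestyle exposures — into a 0–40 composite in which higher values indicate
antioxidant-dominant exposure. Scoring rules, per component:

* **Gender-stratified tertiles** (all nutrients, BMI, cotinine): within each
  gender, cutpoints are the 1/3 and 2/3 sample quantiles of the
  *post-exclusion analysis sample*. Antioxidant components score lowest →
  highest tertile as 0, 1, 2; the pro-oxidant set (total fat, iron, BMI,
  cotinine, alcohol) reverses the order. Smoking exposure is measured as
  serum cotinine (ng/mL) and scored as a pro-oxidant tertile component.
* **Alcohol** (g/day) is categorical: 0 g/day scores 2 (non-drinker);
  below the gender threshold (15 g/day female, 30 g/day male) scores 1;
  at or above it scores 0. Thresholds are closed on the heavy side (15 g/day
  for a female is heavy).
* **Physical activity** enters as weekly MET-minutes,
  `MET = Σ sessions/week × minutes/session × MET value`, summed over
  activity classes, then tertile-scored as an antioxidant. The MET
  multipliers are configurable; both shipped classes (transportation
  walking/bicycling and moderate-intensity activity) default to 4.0, the
  GPAQ convention for those classes. Participants with
  ≥ 2880 MET-min/week (`met_active_threshold`) are labelled *active* in
  descriptive tables.

The lifestyle OBS (BMI + cotinine + PA + alcohol) spans 0–8, the dietary
OBS 0–32, and their sum the total OBS 0–40. Because the scoring is
rank-based within stratum, it is invariant to monotone rescaling of any
component and to participant order.

Numerical choices the tertile definition does not pin down, fixed here:

* Quantile definition: linear-interpolation sample quantiles
  (`stats::quantile` type 7). Any published tertile analysis must pick
  *some* definition; this one is the R default, deterministic, and easy to
  reproduce with a sort-based oracle.
* Assignment at a cutpoint: `value ≤ cutpoint ⇒ lower tertile`, so ties
  straddling a cutpoint all take the lower tertile's score. This keeps
  scoring deterministic and order-independent under heavy ties (e.g.
  zero-inflated MET totals).
* A stratum whose values are all identical cannot be split; every member
  scores 1, preserving the expected score mass, and a warning is raised.

Median splits (used for age and lifestyle-OBS grouping) assign the median
itself to the *low* group, matching the "≤ 13 years" and "OBS ≤ 5"
conventions of the tables this package reproduces.

## 2. Cohort handling

Input tables are validated against a fixed schema (closed categorical sets;
non-negative intakes, biomarkers, and BMD; unique participant IDs); missing
values are explicit `NA`s, never zeros, and rows that fail numeric coercion
are retained with `NA` cells and reported, not dropped. Exclusions run
*sequentially* in the published order — age > 18, any missing BMD outcome,
any missing dietary component, any missing lifestyle component — so that
each tally line is comparable to sequentially reported counts. (The
published counts do not state how overlapping criteria were resolved;
sequential application is this package's documented choice.) All downstream
analyses are complete-case; no imputation or survey weighting is applied,
matching the source analysis, which explicitly did not use sampling
weights.

NHANES ingestion goes through an editable variable map
(`inst/extdata/nhanes_variable_map.csv`); the core never hardcodes NHANES
variable names. SAS XPORT files are read via `foreign::read.xport`.

## 3. Descriptive comparison

Categorical variables are reported as `n (%)` and compared by chi-square
without continuity correction (Yates correction off by default — the
analyses here involve expected counts far above the small-sample regime;
the choice is documented rather than silently inherited). Continuous
variables are routed by a normality gate: Shapiro–Wilk in every group at
α = 0.05, any rejection selecting the nonparametric branch
(median [Q1, Q3], Mann–Whitney U for two groups, Kruskal–Wallis beyond).
The source analysis names its tests but not its normality rule, so the gate
is exposed as `shapiro_alpha` (0 forces parametric, > 1 forces
nonparametric).

## 4. Association models

All association fits are Gaussian-family identity-link GLMs — numerically
ordinary least squares, and tested against closed-form normal-equations
solutions to 10⁻⁸. Inference is Wald with normal quantiles. Reference
levels for dummy coding are fixed: male, non-Hispanic, < 9th grade, no
stimulant use. The standard adjustment set is age, gender, race, education,
family poverty-income ratio, and stimulant use.

* **Sensitivity (leave-one-covariate-out):** the adjusted model is refitted
  once per covariate with that covariate removed; a sign reversal confined
  to a single row identifies the confounder driving a crude-vs-adjusted
  sign flip.
* **Interaction/subgroup:** the interaction p-value is the Wald test of the
  exposure × modifier product term in the pooled model; per-stratum fits
  are reported unadjusted and adjusted, with the stratifying variable
  removed from its own strata's covariate sets (as in the reported
  analysis). Note the consequence: because age still varies *within* each
  age stratum and correlates with the exposure, stratum estimates are
  slightly biased away from the planted values — visible and intentional,
  since it reproduces the reported procedure. The package's
  parameter-recovery tests therefore check CI coverage on fits that keep
  age in the stratum models, and check only signs and the interaction test
  for the reported procedure.
* **Four-group comparison:** the 2 × 2 of median-split age and lifestyle
  OBS, omnibus Kruskal–Wallis plus pairwise Mann–Whitney with Bonferroni
  correction over the six pairs (the source marks significance stars
  without naming a correction; Bonferroni is the most conservative common
  choice).
* **OBS-group × gender model:** treatment coding with low OBS and male as
  the zero-coded references; the Gaussian scale parameter is reported as
  the maximum-likelihood estimate RSS/n with a chi-square interval.

## 5. Dose–response

The smooth is a penalized thin-plate spline GAM (Gaussian/identity) with
covariates entering linearly and smoothing selected by GCV; the basis
dimension adapts to the number of distinct exposure values (at most 10).
The curve is evaluated on an even exposure grid with numeric covariates at
their means and factors at reference levels.

The threshold model is the continuous two-segment form
`y = β₀ + β₁ x + β₂ (x − K)₊ + γ'Z + ε`: the slope below the breakpoint is
β₁, the slope above is β₁ + β₂ (their difference is exactly β₂, an identity
the tests assert), and the fitted mean is continuous at `K` by
construction. `K` is chosen by profiling the Gaussian log-likelihood over a
candidate grid — by default all distinct observed exposure values between
the 5th and 95th percentiles, so the resolution is data-driven (for an
integer-valued score that means integer candidates; a finer numeric grid
can be supplied, and the acceptance runs use 0.05 steps). The CI for the
upper slope is delta-method. The LRT compares the selected piecewise model
to the covariate-adjusted linear model; its reference distribution is χ²
with 2 df (the extra slope plus the profiled breakpoint) by default. The
breakpoint is a non-regular parameter, so the χ² reference is an
approximation; a parametric-bootstrap p-value (simulating from the fitted
linear model) is available via `p_method = "bootstrap"`. Null calibration
under the χ² default is verified by simulation (the test suite requires
non-rejection at α = 0.01 in ≥ 95% of linear-data replicates, i.e. the
approximation errs conservative if at all). Both covariate-adjusted and
unadjusted threshold analyses are supported, since the source does not say
whether its inflection search was adjusted.

## 6. Mediation

Single-mediator linear mediation per mediator–outcome pair (the source
reports per-mediator effects, not a joint decomposition): `a` from
`mediator ~ exposure + Z`, `b` and the direct effect `c′` from
`outcome ~ exposure + mediator + Z`, the total effect `c` from
`outcome ~ exposure + Z`, indirect effect `a·b`. On a common complete-case
sample `c = c′ + a·b` holds to machine precision — a strong internal
consistency check the tests enforce at 10⁻⁸. Inference is a percentile
bootstrap over participant resamples (default 1000 replicates, seeded; the
panel gives each mediator–outcome cell its own deterministic seed offset),
with the two-sided bootstrap p defined as the smallest level at which the
percentile interval excludes zero; a Sobel normal-theory p-value is also
reported since the source does not state its method. The proportion
mediated is reported only when the total and indirect effects share a
sign, and flagged undefined otherwise. One calibration caveat: under the
*complete* null (`a = b = 0`) the distribution of `â·b̂` is a product of
two near-zero normals and the percentile interval over-covers — a known
property of product-of-coefficients bootstraps, not a defect; the
calibration tests therefore use the partial null (`a = 0`, `b ≠ 0`), where
the indirect estimate is asymptotically normal and nominal ~95% coverage
is the right expectation.

## 7. The synthetic cohort generator

The generator is first-class, tested code: it provides ground truth for
every downstream stage. It emulates, per seeded draw in a fixed order:

* **Demographics:** integer ages uniform on 8–18 (median 13), 51.6% male,
  35.9% Hispanic, log-normal family PIR (median 1.58), stimulant use 4.4%
  in males and 1.2% in females, education mildly age-linked.
* **Diet:** the 16 intakes are log-normal with locations at the observed
  overall medians, a male location shift equal to the observed male/female
  log-median gap (males higher for 14 of 16 nutrients), and a common
  log-SD of 0.45 (back-calculated from representative IQR ratios).
* **Lifestyle:** BMI log-normal (median 21.4 kg/m²); cotinine log-normal
  (median 0.03 ng/mL) with a negative age trend; physical activity
  zero-inflated (session counts and minutes per class) with positive age
  trends in both participation and volume; alcohol identically zero, as
  observed in the whole study population (its score is the constant 2, so
  the realised lifestyle OBS spans 2–8 with median 5).
* **Confounding:** the cotinine and activity age trends make lifestyle OBS
  correlate with age (r ≈ 0.35–0.4). Age independently raises BMD
  (0.03 g/cm²/year), so age confounds the crude OBS–BMD association — the
  mechanism behind the planted crude-positive/adjusted-negative reversal —
  and education is kept only weakly age-linked so that age is the *sole*
  sign-flipping covariate in the leave-one-out sensitivity table.
* **Outcome structure:** BMD per site = site baseline (0.87/1.06/0.95
  g/cm² at age 13, small female lumbar offset) + age slope + the
  configured lifestyle-OBS effect + mediator contributions + N(0, 0.12)
  noise. The OBS effect is either age-conditional (+0.02 g/cm²/point at
  ≤ 13 y, −0.035 above — signs and orders from the reported subgroup
  estimates, with the old-age slope set so the pooled adjusted effect is
  negative at about −0.007 as reported) or a continuous two-segment
  U-shape (breakpoint 4.6, slopes −0.043/+0.066 — the reported inflection
  and segment magnitudes). Mediators are linear in the realised lifestyle
  OBS: uric acid a = −0.15 mg/dL/point with b = +0.02 g/cm² per mg/dL
  (indirect −0.003), GGT a = −0.8 IU/L/point with b = +0.0025 (indirect
  −0.002), albumin a = +0.02 g/dL/point with b = 0 (a non-mediating
  correlate).
* **Planted invalidity:** configurable counts of rows that fail exactly one
  sequential exclusion step each, so exclusion tallies have exact ground
  truth.

The generator reproduces the *features the analysis tests* — scoring
arithmetic, confounding direction, effect modification, U-shape, mediation
paths, missingness accounting — and deliberately not the full joint
distribution of real survey data: no survey design or clustering, no
measurement error in recalls, no correlation among nutrients beyond the
shared gender shift, no skew in BMD residuals. Passing tests therefore
demonstrate that the estimators recover known structure under clean
conditions, not that real NHANES data satisfy the models.

## 8. Scale ambiguity in the source tables

The descriptive table of the source prints lifestyle OBS as mean 1.292
(SD 0.455), which is mutually inconsistent with the 0–8 construction, the
median split at 5, and inflection points near 4.6 printed elsewhere in the
same analysis (as is an inflection reported to three decimals for an
integer-valued score). This package implements the stated 0–8 construction
and treats the 1.292 scale as unexplained; no quantity in the package is
calibrated to it. Similarly, whether day-1 or two-day-average recall was
used is unstated; the schema carries a single intake value per nutrient.

## 9. Validation problem sizes

The test suite validates at sizes chosen to balance statistical resolution
against a comfortably fast default run: oracle equivalence on dozens of
small random designs; parameter recovery at n = 1000–4000; the
study-scale preset at n = 1196–1200 with 100 replicates for the
age-interaction recovery; null calibration with 200 replicates (KS on
interaction p-values; LRT rejection rates) and 150 replicates of
bootstrap-CI coverage at n = 300 with 500 bootstrap draws. Noiseless
configurations check exact recovery (breakpoint to grid resolution, slopes
to 10⁻⁸).

## 10. Known limitations

* The OBS weights all components equally; no weighted or data-driven
  scoring is offered.
* Single breakpoint only; no non-Gaussian outcome families.
* Bootstrap p-values are resolution-limited to ~2/replicates; the reported
  0 means "below resolution".
* No survey-weighted or clustered-variance estimation (deliberately out of
  scope, matching the source), and no causal-inference sensitivity analysis
  for the mediation (E-values, sequential ignorability).
* Cross-sectional associations throughout; nothing here licenses causal
  claims.
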