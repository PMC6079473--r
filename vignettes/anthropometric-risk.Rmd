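---
title: "Methods: anthropometric risk, metabolic syndrome, and mortality models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anthropometric risk, metabolic syndrome, and mortality models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthrorisk)
```

This vignette documents the statistical model the package implements, the
choices that were genuinely open when building it, and what the synthetic
cohort generator does and does not establish about behaviour on real data.

## The risk model

### Indices and standardization

Raw anthropometrics are ingested in survey units (cm, kg). Three derived
indices complement height:

* `BMI = W·H⁻²` (kg/m²);
* `ABSI = WC·H^(5/6)·W^(−2/3)`, with WC and H in meters, the allometric
  normalization of waist circumference that removes its correlation with
  BMI and height. An equivalent form used as an internal cross-check is
  `WC/(BMI^(2/3)·H^(1/2))`;
* `HI = HC·(H/166 cm)^0.310·(W/73 kg)^(−0.482)`, the analogous hip
  normalization, reported in cm. The exponents and the reference values
  ⟨H⟩ = 166 cm, ⟨W⟩ = 73 kg are fixed constants of the definition and are
  never re-fitted.

ABSI and HI vary strongly with age and sex, so all four indices enter the
risk model as Z scores against age–sex reference moments
(`build_reference()` / `add_zscores()`). The default grid uses a first bin
for ages 18–19, 5-year bins from 20, and an open-ended top bin pooling ages
80+; cells with fewer than 25 subjects merge into their nearest age
neighbour so every retained cell has an estimable SD. Both knobs
(`age_bin_width`, `min_cell_n`) are configurable, and the table serializes
to CSV so published reference moments can replace sample-derived ones.
Reference moments are unweighted by default (`weighted = TRUE` switches to
weight-adjusted moments); queries outside the grid clamp to the boundary
bin with a warning rather than extrapolating.

### Hazard curves and ARI

For each index, `fit_hazard_curve()` estimates the log mortality hazard as
a smooth function of the Z score by penalized-spline Cox regression.
Attained age is the timescale: a subject enters the risk set at baseline
age and exits at age of death or censoring, which adjusts for age
nonparametrically and is the reason no age covariate appears in any model.
The spline is `survival::pspline()` with a default target of 4 degrees of
freedom — enough to express the J- and U-shaped relations seen for BMI
while keeping the fit stable at a few thousand events; `df = 0` delegates
the choice to the fitter's corrected-AIC criterion.

Each fitted curve is tabulated on a dense grid (z from −4 to 4, step 0.01)
and evaluated by natural cubic spline interpolation, so a curve is a
portable object independent of the fitting engine. The curve is centered by
the constant that makes the training-sample mean of `exp(h(z))` equal 1
*under the grid evaluator itself*; this anchoring is what entitles the sum

`ARI = h_H(z_H) + h_BMI(z_BMI) + h_ABSI(z_ABSI) + h_HI(z_HI)`

to its interpretation: `exp(ARI)` is hazard relative to the population
average, and `ARI = 0` is average risk. Z scores beyond ±4 evaluate at the
boundary with a warning — the curves are not trusted outside the range the
training data can support.

Curves are always fitted on a disjoint training subsample (the `training`
flag column) and applied to the evaluation subsample. This mirrors the
two-subsample design of examination surveys, where the subjects lacking
fasting laboratory measurements cannot contribute to MS models but are
ideal for curve estimation, and it prevents the models in the comparison
from being evaluated on data that shaped their own ARI predictor. The
training fits are unweighted by default (the training subsample acts as an
internal reference population); `weighted = TRUE` is available.

### Metabolic syndrome scoring

The five ATP III components are scored literally from their wording:
"at or above" thresholds are inclusive (BP 130/85 mmHg, TG 150 mg/dL,
glucose 110 mg/dL), "above"/"under" are strict (waist > 102/88 cm,
HDL < 40/50 mg/dL), and the medication clauses (BP medication, diabetes
pills) each suffice on their own. Whether the original waist criterion was
read as `>` or `≥` is not recoverable; the strict reading is used, and
because the scorer is exact at boundaries, flipping that choice would only
affect subjects measuring exactly 102.0/88.0 cm. A met clause decides a
disjunctive criterion even when its companions are missing; otherwise
missing inputs propagate as `NA` and downstream analysis is complete-case.
`msx_score` (0–4) omits the waist component — the variant used alongside
ARI, whose BMI and ABSI inputs already carry the waist information.

### Model comparison

`fit_model_roster()` fits ten Cox models (Base; ARI; MS; MS score; ARI +
MS; ARI + MS score; ARI + MSx score; MS components; ARI + MS components;
ARI + MSx components), all with sex and black race as covariates, Efron tie
handling, and sampling weights entering the partial likelihood as case
weights with robust (sandwich) variance for the confidence intervals.
Weights are normalized to sum to the sample size before fitting; without
that, the weighted partial likelihood — and hence AIC — would depend on the
arbitrary scale of the weights. With equal weights the fit reduces exactly
to the unweighted one.

Performance measures:

* **Δᵢ** — AIC difference from the minimum across the fitted set. Δᵢ = 0
  marks the best model; Δᵢ > 6 flags models that predict significantly
  worse for the sampled population; models within 6 of the best are treated
  as statistically tied. Equal AICs order deterministically by model name.
* **R²** — Royston–Sauerbrei explained variation on the log-hazard scale:
  the linear predictor is rank-transformed to expected normal order
  statistics scaled by κ = √(8/π), an auxiliary Cox fit on that regressor
  gives the prognostic separation D, and R² = (D²/κ²)/(π²/6 + D²/κ²). The
  original analysis names only "R²"; this estimator was chosen because it
  is stable under the age-timescale/left-truncation structure and cheap to
  compute. It lives in one documented function (`royston_r2`) so an
  alternative (e.g. O'Quigley's ρ²) can be swapped.
* **C** — weighted Harrell concordance over comparable pairs under the age
  timescale, ties counted ½, so a constant or uninformative score gives
  exactly 0.5.

The correlation report (`correlation_table()`) uses Pearson correlations on
complete cases; for 0/1 columns these are point-biserial/phi coefficients,
which is what makes its entries directly comparable with published
component-correlation tables.

## The synthetic cohort generator

`generate_cohort()` exists so that every stage has a testable ground truth.
Its defaults are fixed study conditions, not tuning knobs:

* **Anthropometrics.** Independent standard-normal target Z scores for H,
  BMI, ABSI and HI are drawn first; height and BMI follow sex-specific
  distributions with mild age trends, and waist/hip circumference are then
  *computed by inverting the index definitions*. Independence of the four
  index Z scores therefore holds by construction, which is exactly the
  property the ARI summation assumes and the property the correlation
  analysis should recover (fitted per-index hazard correlations < 0.1).
* **MS components.** A common-factor latent Gaussian with pairwise
  correlation 0.35 drives blood pressure, triglycerides, HDL and glucose;
  the waist slot of the factor structure is the subject's within-sex waist
  percentile, tying the laboratory components to the realized
  anthropometrics. The latent value maps through lognormal marginals whose
  medians were calibrated once (on a 50,000-subject pilot) and frozen, so
  that the realized 0/1 components intercorrelate near 0.2, component
  prevalences sit near (.35, .41, .36, .38, .19), and MS prevalence lands
  near 28% — the structure reported for the reference population. The
  latent 0.35 is deliberately higher than the binary 0.2: thresholding
  attenuates correlations, and the published ~0.2 values are on the binary
  scale.
* **Survival.** A Gompertz baseline on the age timescale
  (h₀(a) = b₀·e^{θa}, log b₀ = −9.7, θ = 0.09) multiplied by exp(true log
  hazard), inverted analytically for the death time and censored
  administratively at 20 years, yields ~30% deaths over follow-up at the
  generator's age distribution. The default true hazard uses centered
  linear index effects with slopes (−0.02, 0.17, 0.13, −0.09) for (H, BMI,
  ABSI, HI) — giving SD(ARI) ≈ 0.23 and the published ordering of index
  contributions (BMI > ABSI > HI ≫ H) — plus component log hazard ratios
  log(1.25), log(0.92), log(1.22), log(1.24) for BP, TG, HDL, Glu (waist
  0), and sex/race effects of log 1.6 and log 1.2. `linear_log_hazard()`
  and `ushaped_log_hazard()` build centered effect functions; every element
  is overridable through `cohort_config()`.
* **Design artifacts.** Sampling weights are Gamma(4, 4) (mean 1), and a
  Bernoulli(½) flag splits the cohort into training/evaluation halves,
  emulating the morning-subsample design.

What the generator does **not** emulate: cluster sampling and oversampling
(weights are iid, so design effects on variances are not reproduced),
measurement error in anthropometrics, non-proportional hazards, cohort
secular trends, and real missingness mechanisms. Passing tests on this
generator therefore demonstrate that the machinery is correct — formulas
exact, centering anchored, CIs with nominal coverage, model selection
consistent — not that any particular published hazard ratio would be
reproduced on a real survey file, which additionally depends on the
original sample's composition.

## Numerical choices and degenerate inputs

* Sample SDs use n−1; weighted SDs use the reliability-weight denominator
  `Σw − Σw²/Σw`. Zero-SD reference cells are an error (they arise only from
  degenerate input), and zero-variance columns in the correlation table are
  reported as `NA` with a warning rather than silently dropped.
* Implausible raw measurements (outside `anthro_bounds()`) are flagged per
  row, never silently excluded; exclusion is the business of
  `filter_cohort()`, whose five rules are applied in a fixed documented
  order with per-rule accounting, a record counting against the first rule
  it violates.
* Hazard-curve fits require ≥ 50 events by default; Cox fits refuse
  duplicated or aliased (collinear) predictors by name; AIC comparison
  refuses fits from different cohorts or weightings.
* Grid interpolation of curves uses natural cubic splines; with the 0.01
  grid step, interpolation error is orders of magnitude below statistical
  error, and the centering invariant holds to 1e−6 by construction under
  the same evaluator used in production.
* CSV round trips are value-exact (shortest round-trippable decimal
  representation); one reparse is an exact fixed point.

## Problem sizes used by the test suite

Statistical checks run at sizes chosen to keep Monte-Carlo error well below
the asserted tolerances while remaining quick on one CPU: curve-recovery
and structure checks at n = 20,000 (a single cohort each), confidence
-interval coverage at 200 replicates of n = 5,000 (fitting only the model
under test per replicate), and model-selection recovery at 11 replicates of
n = 5,000 with the full spline pipeline per replicate. The acceptance
script analyses a cohort of 10,442 so that its evaluation subsample
(~5,200) matches the scale of the motivating analysis.

## Known limitations

* The penalized-spline df (4) and the unweighted training fits are
  defensible defaults, not recovered facts about the original analysis;
  reproducing published coefficient tables to printed precision may require
  tuning both.
* Royston–Sauerbrei R² is one of several "explained variation" measures;
  absolute R² values are not comparable across measures, only rankings of
  models under the same measure.
* The age-timescale concordance counts pairs comparable under left
  truncation; it is not numerically identical to a follow-up-time
  concordance on the same data.
* ARI curves apply only within the Z range of the training sample (±4);
  extreme anthropometrics evaluate at the boundary by design.
* Alternative MS definitions (IDF, harmonized), alternative abdominal
  indices (WC/H ratio), and ethnicity-specific cutpoints are extension
  points, not implemented.
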