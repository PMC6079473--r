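# anthrorisk

Anthropometric risk index (ARI) and metabolic syndrome (MS) mortality
modelling for epidemiological cohorts, in R.

Body mass index alone is a blunt measure of mortality risk: waist and hip
circumference carry independent information once they are normalized for
height and weight. `anthrorisk` implements the full analysis pipeline that
combines the resulting family of statistically independent anthropometric
indices with the ATP III metabolic syndrome score in survival models of
all-cause mortality. It is aimed at biostatisticians and epidemiologists
working with examination-survey cohorts (NHANES-style data: anthropometrics,
blood pressure, fasting lipids and glucose, linked mortality follow-up,
sampling weights), and at methodologists who want a fully testable version
of the approach with a ground-truth cohort simulator.

## The model

Four indices are computed from height H, weight W, waist circumference WC
and hip circumference HC (cm/kg ingest; H and WC in meters inside ABSI):

    BMI  = W · H⁻²
    ABSI = WC · H^(5/6) · W^(−2/3)
    HI   = HC · (H/⟨H⟩)^0.310 · (W/⟨W⟩)^(−0.482),   ⟨H⟩ = 166 cm, ⟨W⟩ = 73 kg

ABSI and HI are allometric normalizations of waist and hip circumference
that make the quadruple (H, BMI, ABSI, HI) mutually near-uncorrelated. Each
index is converted to an age- and sex-specific Z score, and a penalized
spline Cox regression — with attained age as the timescale (delayed entry
at baseline age) — estimates the log mortality hazard attributable to each
index alone: h_H(z), h_BMI(z), h_ABSI(z), h_HI(z), each centered so the
training-sample mean of exp(h) is 1. Their sum is the anthropometric risk
index,

    ARI = h_H(z_H) + h_BMI(z_BMI) + h_ABSI(z_ABSI) + h_HI(z_HI),

so exp(ARI) is the subject's estimated hazard as a fraction of the
population average (ARI = 0 ⇔ average risk).

The metabolic syndrome side scores five ATP III components 0/1 — elevated
waist (> 102 cm men / > 88 cm women), blood pressure (≥ 130/85 mmHg or
medication), triglycerides (≥ 150 mg/dL), low HDL (< 40/50 mg/dL), glucose
(≥ 110 mg/dL or diabetes pills) — with MS defined as a score of 3+. Ten
survey-weighted Cox models combining ARI, MS occurrence, MS score, and the
individual components (always adjusted for sex and black race) are compared
by AIC differences Δᵢ (Δᵢ > 6 ⇒ significantly worse than the best model),
Royston–Sauerbrei explained variation R², and Harrell concordance C.

A cohort generator with known ground truth (independent index Z scores by
construction, latent-factor MS components calibrated to ~28% prevalence,
Gompertz baseline hazard on the age timescale) makes every stage testable
without any data download.

## Worked example

```r
library(anthrorisk)
library(dplyr)

cohort <- generate_cohort(10000, cohort_config(), seed = 2024)
result <- run_ari_pipeline(cohort, seed = 2024)

result$comparison %>% select(model, delta_i, r2, concordance)
#> # A tibble: 10 × 4
#>    model                delta_i     r2 concordance
#>    <chr>                  <dbl>  <dbl>       <dbl>
#>  1 ARI + MSx components    0    0.0902       0.610
#>  2 ARI + MS components     1.92 0.0902       0.610
#>  3 ARI + MSx score        23.9  0.0784       0.606
#>  4 ARI + MS score         26.9  0.0775       0.605
#>  5 MS components          39.1  0.0779       0.599
#>  6 ARI + MS               43.2  0.0712       0.600
#>  7 ARI                    53.3  0.0692       0.600
#>  8 MS score               62.9  0.0688       0.594
#>  9 MS                    105.   0.0539       0.576
#> 10 Base                  165.   0.0339       0.557
```

The generating model of this synthetic cohort (ARI plus the four non-waist
MS components) attains Δᵢ = 0; its rival including the redundant Waist
component is statistically tied (Δᵢ < 6), and everything else — including
ARI or MS alone — predicts significantly worse. Hazard ratios for the best
model:

```r
result$hazard_ratios %>%
  filter(model == "ARI + MSx components") %>%
  select(term, hazard_ratio, conf.low, conf.high)
#> # A tibble: 7 × 4
#>   term       hazard_ratio conf.low conf.high
#>   <chr>             <dbl>    <dbl>     <dbl>
#> 1 sexmale           1.56     1.40      1.75
#> 2 race_black        1.17     1.04      1.32
#> 3 ari               1.98     1.63      2.40
#> 4 ms_bp             1.22     1.08      1.36
#> 5 ms_tg             0.876    0.779     0.985
#> 6 ms_hdl            1.32     1.18      1.48
#> 7 ms_glu            1.19     1.04      1.37
```

Per unit of ARI — i.e. per e-fold of predicted relative hazard — mortality
hazard roughly doubles, while elevated blood pressure, low HDL and elevated
glucose each add 19–32% on top of the anthropometric risk. The fitted
curves themselves print and plot directly:

```r
result$curves$BMI
#> <hazard_curve BMI> pspline Cox log-hazard vs Z (df 4), 5016 subjects, 1644 deaths
#>   range over z in [-4, 4]: [-1.415, 0.680]; centering offset 0.0335
autoplot(result$curves$BMI)

mean(result$cohort$ms)   # 0.27  — MS prevalence of the simulated cohort
```

`write_pipeline_bundle()` (or `outdir =`) exports every artifact — cohort,
reference table, dense hazard-curve grids with JSON metadata, the model
comparison, hazard ratios and the correlation matrix — as versioned CSVs,
and `inst/scripts/run_pipeline.R` wraps the same pipeline for shell use.
Real extracts reach the pipeline through `apply_column_map()` (documented
column-mapping for external survey CSVs), `filter_cohort()` (auditable
exclusion accounting) and `read_cohort()`.

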