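# metsindex

Tools for evaluating obesity- and lipid-related indices as predictors of
metabolic syndrome (MetS) in chronic kidney disease (CKD) cohorts, with
and without type 2 diabetes (T2DM).

Clinicians screening CKD patients for MetS need simple anthropometric
and lipid-based scores rather than full component panels. This package
implements the complete analysis such a study runs: sex-specific index
calculators, rule engines for three MetS definitions, ROC analysis with
Youden-optimal cut-offs, and penalized logistic regression for adjusted
odds ratios — together with a synthetic cohort generator calibrated to
published CKD stratum summaries, so the whole pipeline is testable
without patient data.

## The indices

For waist circumference WC (cm), BMI (kg/m²), triglycerides TG and
HDL-C (mmol/L):

- **VAI** (visceral adiposity index), men:
  `WC / (39.68 + 1.88·BMI) × (TG / 1.03) × (1.31 / HDL)`;
  women: constants 36.58, 1.89, 0.81, 1.52.
- **CVAI** (Chinese visceral adiposity index), men:
  `−267.93 + age + 0.03·BMI + 4.00·WC + 22.00·log₁₀TG − 16.32·HDL`;
  women: `−187.32 + age + 4.32·BMI + 1.12·WC + 39.76·log₁₀TG − 11.66·HDL`.
- **LAP** (lipid accumulation product): `(WC − 65)·TG` (men),
  `(WC − 58)·TG` (women).
- **eGFR** by the 2009 CKD-EPI creatinine equation (creatinine input in
  µmol/L, race coefficient off by default).

BMI, WC and the visceral/subcutaneous fat areas (VFA/SFA) complete the
seven-predictor panel.

## The statistics

- **MetS diagnosis**: the Chinese 2020 guideline and revised NCEP-ATPIII
  rules call MetS at ≥ 3 of 5 components; the IDF rule requires central
  obesity plus ≥ 2 of the remaining 4. All thresholds live in a
  declarative definition list (`mets_criterion_defs()`).
- **Cut-offs**: ROC curves over the observed scores (positive call at
  score ≥ threshold); the optimal cut-off maximises Youden's
  J = sensitivity + specificity − 1; AUC is the pairwise concordance
  probability with DeLong 95% intervals.
- **Adjusted odds ratios**: Firth's bias-reduced penalized likelihood
  (Jeffreys-prior penalty `½ log det I(β)`), which stays finite under
  the complete or quasi-complete separation that small, well-separated
  strata produce, with Wald OR intervals and VIF/condition-index
  collinearity diagnostics.

## Worked example

```r
library(metsindex)
library(dplyr)

cohort <- generate_cohort(seed = 42)              # 537 synthetic CKD subjects
classified <- cohort |>
  add_indices(check_ranges = FALSE) |>            # BMI, VAI, CVAI, LAP, eGFR
  classify_t2dm() |>
  classify_mets("china2020")

prevalence_summary(classified)
#>   measure sex    t2dm  n_events n_total fraction   pct undefined
#> 1 t2dm    male   NA         214     372    0.575  57.5 FALSE
#> 2 t2dm    female NA          70     165    0.424  42.4 FALSE
#> 3 mets    male   TRUE       166     214    0.776  77.6 FALSE
#> 4 mets    male   FALSE       85     158    0.538  53.8 FALSE
#> 5 mets    female TRUE        59      70    0.843  84.3 FALSE
#> 6 mets    female FALSE       25      95    0.263  26.3 FALSE

men_dm <- filter(classified, sex == "male", t2dm)
optimal_cutoff(roc_curve(men_dm, vai, mets))
#>   threshold youden sensitivity specificity
#> 1      1.78  0.679        78.3        89.6
roc_auc(men_dm, vai, mets)
#>     auc     se ci_low ci_high  p_value method n_pos n_neg
#> 1 0.896 0.0217  0.853   0.938 1.52e-74 delong   166    48
```

The T2DM prevalences (57.5% / 42.4%) are exact consequences of the
calibrated stratum sizes; the MetS rows are *re-diagnosed* from the
generated measurements, so they track — but do not exactly equal — the
generating strata. VAI separates MetS from non-MetS men with T2DM with
AUC ≈ 0.90 at a cut-off near 1.8. An adjusted odds ratio for the
dichotomised index:

```r
men_dm <- mutate(men_dm, vai_high = as.numeric(vai >= 1.78))
fit <- fit_firth(men_dm, mets ~ vai_high + age + sbp + tc + ldl + egfr)
wald_or_ci(fit)[2, ]
#>   term     estimate    or ci_low ci_high
#> 1 vai_high     3.25  25.9   10.0    66.8
```

i.e. men with T2DM at or above the VAI cut-off have ~26-fold higher
adjusted odds of MetS in this synthetic cohort.

`run_study()` wraps all of the above per sex × T2DM stratum and writes
descriptive, prevalence, cut-off/OR and AUC tables plus ROC plots and a
run manifest.

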