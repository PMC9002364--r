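---
title: "Methods: adiposity indices, MetS criteria and the synthetic CKD cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adiposity indices, MetS criteria and the synthetic CKD cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsindex)
```

## Scope and model

metsindex implements the analysis a cross-sectional screening study of
metabolic syndrome (MetS) in chronic kidney disease (CKD) runs: derive
seven obesity- and lipid-related predictors per subject (BMI, WC, VFA,
SFA, VAI, CVAI, LAP), diagnose MetS under three component-counting
definitions, estimate each predictor's discrimination (ROC/AUC) and
Youden-optimal cut-off per sex × T2DM stratum, and quantify adjusted
associations with Firth penalized logistic regression. Because cohorts
of this kind are rarely deposited, the package also ships a calibrated
synthetic cohort generator so every stage is exercised end to end by
code alone.

## Index calculators

VAI, CVAI and LAP are sex-specific composites of waist circumference,
BMI, triglycerides and HDL-C (see the README for the formulas). Two
conventions deserve note:

* **CVAI age coefficient.** The CVAI linear score is implemented with a
  unit coefficient on age in both sexes, matching the formula as used
  by the study this package operationalises; published CVAI variants
  differ slightly in this coefficient, so callers comparing against
  other CVAI literature should check which parameterisation they need.
* **Creatinine units.** Serum creatinine is accepted in µmol/L — the
  magnitude clinical laboratories in this setting report — and
  converted internally to mg/dL (÷ 88.4) for the 2009 CKD-EPI
  creatinine equation. The race coefficient is excluded by default
  (`black = FALSE`), appropriate for a Chinese cohort and consistent
  with current practice.
* **LAP non-positivity.** LAP is negative or zero when WC does not
  exceed the sex offset (65 cm men, 58 cm women). Such values are
  *flagged* (`lap_nonpositive`), never rejected: the formula admits
  them and ROC analysis accepts any real score.

Out-of-range measurements (BMI outside 10–60 kg/m², WC outside 40–200
cm, height outside 1.2–2.2 m) produce warnings naming the subjects, not
errors, so deliberately extreme synthetic records remain testable; the
checks can be disabled with `check_ranges = FALSE`.

## MetS criteria engines

All thresholds are held in a declarative list
(`mets_criterion_defs()`), so alternative guideline revisions can be
plugged in without touching the classification code. Choices made where
guideline text is ambiguous:

* "Blood pressure ≥ 130/85" is read as SBP ≥ 130 **or** DBP ≥ 85 — the
  standard guideline reading, and it affects component counts.
* The Chinese 2020 hyperglycemia component accepts either fasting
  glucose ≥ 6.1 mmol/L or *diagnosed-and-treated* diabetes; its 2-h
  post-load glucose arm is omitted because the subject record carries
  fasting measurements only — the diagnosis arm substitutes.
* The Chinese 2020 low-HDL cut-point (< 1.04 mmol/L) is applied to both
  sexes, exactly as the guideline prints it.
* The IDF definition's numeric thresholds use the ethnic-specific
  Chinese waist cut-points (≥ 90 cm men, ≥ 80 cm women) and otherwise
  match the revised ATPIII set.
* Lipid-lowering treatment is **not** used as a surrogate for the TG or
  HDL components; only the hypertension and diabetes treatment flags
  enter, and only where the definitions call for them.

The combination rules are verified exhaustively over all 2⁵ component
patterns, and each printed threshold is tested at the boundary with the
printed inclusivity.

## ROC, AUC and optimal cut-offs

The positive-call convention is **score ≥ threshold** (inclusive), so a
subject exactly at a reported cut-off is called positive; candidate
cut-offs are the observed unique scores. AUC is computed as the
pairwise concordance probability (ties ½) via rank placements, which
equals the trapezoidal area under the operating-point polyline — the
two routes are compared on every random test instance. Confidence
intervals use the DeLong placement variance by default (Hanley–McNeil
available via `ci_method`); a class with a single member contributes no
estimable placement variance. The Youden maximiser breaks ties by
higher sensitivity, then by the smaller threshold — a package
convention, stated because results at tied maxima depend on it.

## Firth penalized logistic regression

Adjusted odds ratios come from maximising
ℓ(β) + ½ log det I(β) — the Jeffreys-prior penalty with
I(β) = XᵀWX — by modified-score Newton iterations with step-halving
(the penalized log-likelihood never decreases across accepted steps).
Convergence is declared when the modified-score sup-norm falls below
`tol = 1e-6`, within `max_iter = 50` iterations and up to 10 halvings
per step. Estimates are finite even under complete separation; a
separation heuristic (ordinary-ML fitted probabilities collapsing to
0/1) raises `separation_suspected`. Standard errors come from the
inverse Fisher information at the penalized estimate and intervals are
Wald on the log-odds scale; profile-penalized-likelihood intervals are
not implemented, a deliberate simplification since the reporting target
is Wald-style "OR (95% CI)" tables.

Known closed forms anchor the implementation: the intercept-only
penalized mode is logit((k + ½)/(n + 1)), and the saturated
one-binary-covariate fit equals the Haldane half-cell-corrected log
odds ratio, including zero-cell tables.

Collinearity among adjustment covariates is diagnosed by auxiliary-
regression VIFs plus Belsley condition indices with variance-
decomposition proportions on the unit-length-scaled design (intercept
included); flags follow the conventional VIF > 10 and condition index
> 30 with > 50% variance on ≥ 2 covariates rules.

For the stratified cut-off/OR table, both predictor codings are
supported and labelled: `"binary"` (indicator of score ≥ the
Youden-optimal cut-off — the default) and `"continuous"` (per natural
unit). Covariates are never standardised, so per-unit ORs stay on their
natural scales.

## The synthetic cohort generator

`default_cohort_spec()` encodes eight sex × T2DM × MetS strata with
sizes (79, 79, 42, 172) for men and (69, 26, 11, 59) for women — 537
subjects, 372 men and 165 women — and per-stratum marginal parameters
for 15 measured variables. Variables summarised as mean ± SD are
modelled normal; right-skewed variables summarised as median (IQR)
(TG, LAP-type quantities) are modelled lognormal with log-median and
log-IQR matched by quantile, an invertible and testable transform.

Within each stratum, adiposity-related variables (BMI, WC, VFA, SFA,
TG) share an exchangeable Spearman rank correlation of 0.3 through a
Gaussian copula — a modelling assumption chosen as a moderate,
physiologically plausible dependence, since only marginals are
published. The latent Pearson correlation is set to 2·sin(π·0.3/6) so
the *rank* correlation hits the target. Heights are drawn from
sex-specific normals (1.72 ± 0.06 m men, 1.60 ± 0.055 m women) and
weight is back-computed from the sampled BMI, so the index calculators
run on raw measurements; the printed VAI/CVAI/LAP summaries are never
sampled directly.

Physiologic guard rails (age ≥ 18, positive measurements, plausible
pressure and anthropometry ranges, fasting glucose < 7 mmol/L in
non-diabetic strata) are enforced by redrawing offending rows — up to
100 rounds, after which the spec is reported infeasible rather than
silently truncated. Diabetic strata carry the diagnosis flag and an 80%
glucose-lowering-medication prevalence; hypertension flags follow the
published per-stratum prevalences, with treatment equated to diagnosis
(treatment rates are not published separately).

Two things the generator deliberately does **not** emulate: the MetS
stratum label is a parameter-lookup device, not ground truth — the
pipeline re-diagnoses MetS from the generated measurements, and the two
agree only approximately (the agreement is reported, never asserted);
and the copula does not reproduce the full dependence structure of real
clinical data (e.g. TG–HDL anticorrelation, age–BP coupling). Passing
tests therefore demonstrate that the machinery is correct under the
published marginal structure, not that it would reproduce any
particular cohort's joint distribution.

`generate_separable()` provides bi-normal score cohorts with known AUC
Φ(μ/√2) and optimal cut-off μ/2 for closed-form recovery tests, and
`generate_planted()` plants a dominant VAI→MetS effect (label from
within-stratum standardised log-VAI plus Gaussian noise, SD 0.5) to
check that the pipeline's ranking machinery puts a genuinely dominant
index first.

## Pipeline conventions

* Normality gate: Shapiro–Wilk at α = 0.05 in both groups selects
  t-test/mean ± SD versus Mann–Whitney/median (IQR). The test name and
  level are recorded in the run manifest.
* Chi-square tests are reported uncorrected with the continuity-
  corrected statistic alongside; Fisher's exact test replaces both when
  any expected cell is below 5.
* Significance is two-sided p < 0.05 and no multiple-testing correction
  is applied — the analysis is deliberately reported test-by-test, and
  this is stated rather than hidden.
* Percentages are rounded to one decimal in rendered tables; full
  precision is retained in the machine-readable columns.
* Strata too small to model (events < covariates + 2), single-class
  strata and constant predictors yield diagnostics rows, never crashes.
* `run_study()` is deterministic given its inputs: identical cohort,
  configuration and seed give byte-identical CSV outputs.

Test problem sizes were chosen to make sampling error negligible
relative to each tolerance: closed-form AUC recovery uses 10⁵ subjects
per class, DeLong coverage uses 1000 replicates at 100 per class, and
the small-sample bias comparison uses 200 replicates at n = 50 — sizes
at which the checked quantities are stable to well within the asserted
bounds.

## Known limitations

* Cross-sectional associations only; no causal or longitudinal
  machinery.
* Profile-penalized-likelihood intervals and DeLong *paired* AUC
  comparisons are not implemented (CIs only, per stratum).
* The eGFR calculator implements the 2009 creatinine equation only —
  no cystatin-C or 2021 variants.
* The synthetic generator's copula is an assumption; conclusions about
  real cohorts require real data through the same interface
  (`add_indices()` onward accepts any subject-level data frame with the
  documented columns).
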