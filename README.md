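# exposcan

Exposome-wide association screening for longitudinal cohorts.

`exposcan` is an R package for environment-wide association studies (EWAS)
of lifestyle exposures against cardiometabolic traits in repeated-measures
cohorts — the setting where adults are examined every ~10 years and each
visit records clinical traits (BMI, blood pressure, lipids, glucose)
alongside hundreds of questionnaire-derived lifestyle variables (diet,
alcohol, tobacco, physical activity, sleep, psychosocial factors). It is
aimed at epidemiologists and biostatisticians who want a tested, seedable
implementation of the whole screening protocol rather than a pile of
one-off scripts.

## What it computes

**Average associations.** For each exposure–trait pair, a random-intercept
linear mixed model fitted by REML:

    y_ij = (b0 + u_j) + b1 age_ij + b2 age_ij^2 + b3 sex_j + b4 time_ij
           [+ b5 FFQver_ij + b6 TEI_ij] [+ b7 BMI_ij] [+ b8 fasting_ij]
           + b9 x_ij + e_ij,    u_j ~ N(0, s_u^2),  e_ij ~ N(0, s_e^2)

where `u_j` is the participant intercept absorbing within-person
correlation across visits, `time_ij` is years since the participant's
first visit, FFQ version and total energy intake (TEI) enter for dietary
exposures, BMI for all outcomes except BMI itself, and fasting status for
glycaemic and lipid outcomes. Inference on the exposure term `b9` is a
Wald z-test; its importance is measured by the drop in marginal R²
(`var(Xb) / (var(Xb) + s_u² + s_e²)`) when the term is removed.

**10-year change associations.** For each participant's first eligible
baseline/follow-up visit pair (~10-year gap), ordinary least squares of
the follow-up trait value on the baseline exposure, adjusted for baseline
age and age², sex, follow-up time, the baseline trait value, the mean of
baseline and follow-up BMI, and (for dietary exposures / blood-based
traits) baseline FFQ version, TEI and fasting status at both visits.

**Discovery and prioritization.** P-values are adjusted per trait × mode
family with a step-up Benjamini–Hochberg procedure; associations with
adjusted p < 0.05 are *tentative signals*. Signals are ranked within each
of ten lifestyle categories by variance explained, the top 5 per category
per trait are retained, variables top-ranked for at least 5 of the 9
traits and flagged modifiable are prioritized, and the prioritized set is
clustered (average linkage on 1 − r) into intervention target groups.

Harmonization implements the standard cleaning rules for this design:
published additive corrections for lipid- and blood-pressure-lowering
medication (+0.208 mmol/L triglycerides, +1.347 total cholesterol, −0.060
HDL, +1.290 LDL, +15/+10 mmHg SBP/DBP), Friedewald LDL
(TC − HDL − TG/2.2), BMI from anthropometry, food-intake-level
plausibility filtering (bottom 5%, top 2.5%), FFQ quality rules, rank-based
inverse-normal transformation (Blom offset), low-to-high dummy coding, and
exclusion of categoricals with ≥ 90% single-level dominance.

Because cohort data of this kind cannot be redistributed, the package
ships a synthetic-cohort generator (`generate_cohort()`) with planted,
labelled exposure→trait effects, so every stage — and the package's own
test suite — runs against known ground truth.

## Worked example

```r
library(exposcan)
man <- run_pipeline(demo_pipeline_config(seed = 1), "demo-out")
print(man)
```

```
exposcan run manifest
  seed: 1, package 0.1.0
  stage simulate         0.02s
  stage harmonize        0.03s
  stage screen_average   0.74s
  stage screen_change    0.16s
  input_visits           869
  input_exposures        40
  clean_visits           700
  clean_exposures        36
  tentative_signals      13
  prioritized            1
```

The demo simulates 400 participants with 40 exposures and plants a strong
protective physical-activity effect on BMI and triglycerides (standardized
slopes −0.6 and −0.4) plus a tobacco effect on triglycerides.
Harmonization removes flagged participants and four dominated
categoricals (869 → 700 visits, 40 → 36 exposures). The screen's top
signals:

```
             exposure         trait    mode   estimate         p_fdr tentative
 physical_activity_01           bmi average -2.1408312 1.878989e-122      TRUE
 physical_activity_06           bmi average -1.1023096  2.459320e-15      TRUE
 physical_activity_03           bmi average -0.9041298  5.377138e-11      TRUE
 physical_activity_02           bmi average -0.9247143  1.753393e-10      TRUE
           tobacco_01 triglycerides average  0.1904275  9.657709e-10      TRUE
```

The planted exposure is the strongest signal (−2.14 BMI units per SD of
exposure ≈ −0.6 of the trait's total SD of 3.8, as planted); its
within-category correlates (block correlation 0.3) echo it at smaller
magnitude, exactly the correlation-driven redundancy the
ranking/clustering steps exist to handle. `physical_activity_01` is then
the one variable top-ranked for both screened traits and modifiable,
hence the single prioritized exposure in `priority.csv`.

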