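---
title: "Exposome-wide screening of cardiometabolic traits: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exposome-wide screening of cardiometabolic traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exposcan)
```

`exposcan` implements an environment-wide association screen: hundreds of
lifestyle exposures are tested, one at a time, against nine cardiometabolic
traits in a longitudinal cohort, once for the *average* association over
all visits and once for the association with the ~10-year *change* in the
trait. This vignette explains the models, the harmonization rules, the
tunable parameters, what the synthetic-data generator does and does not
emulate, and the choices we made where the design was genuinely open.

## The two screening models

### Average associations: a random-intercept mixed model

Repeated visits of the same participant are correlated, so the
per-exposure model for trait $y$ of participant $j$ at visit $i$ is

$$y_{ij} = (\beta_0 + u_j) + \beta_1\,\mathrm{age}_{ij} +
\beta_2\,\mathrm{age}^2_{ij} + \beta_3\,\mathrm{sex}_j +
\beta_4\,t_{ij} + \dots + \beta_x\, x_{ij} + \varepsilon_{ij},$$

with $u_j \sim N(0, \sigma_u^2)$ a participant-specific random intercept
and $\varepsilon_{ij} \sim N(0, \sigma_e^2)$ the visit residual. The
covariate set is fixed by protocol: age, age², sex, educational level
(ordered integer codes) and follow-up time always; FFQ version and total
energy intake (TEI) when the exposure is dietary (food, nutrient,
beverage or alcohol categories); BMI except when BMI is the outcome;
fasting status for glycaemic and lipid outcomes. Follow-up time $t_{ij}$
is defined as years since the participant's first retained visit — the
one point where the model statement leaves room, since "follow-up time"
could also be read as calendar time; years-since-baseline keeps the term
zero-centred at entry and independent of enrolment year.

Fitting is restricted maximum likelihood. Writing
$\lambda = \sigma_u^2/\sigma_e^2$, the fixed effects and $\sigma_e^2$
profile out of the REML criterion in closed form, leaving a
one-dimensional criterion in $\log\lambda$ that `fit_random_intercept()`
minimizes by a 41-point bounded grid on $[-15, 10]$, Brent refinement to
tolerance $10^{-8}$, and a short damped-Newton polish (central
differences) so variance components agree with closed-form oracles to at
least six figures. For grouped data the weighted cross-products needed at
each candidate $\lambda$ reduce to per-group sums, one $O(g\,p^2)$ pass,
which is what makes a screen of a few thousand exposure × trait models
cheap. When the criterion is minimized at the boundary
$\sigma_u^2 = 0$ — always the case when every participant has a single
visit, where the intercept variance is unidentifiable — the fit reduces
exactly to ordinary least squares.

Inference on the exposure term is a Wald z-test with a standard-normal
reference. At the cohort sizes this screen is built for (tens of
thousands of observations) the difference from a small-sample t reference
is negligible; for small synthetic runs (hundreds of rows) the normal
reference is mildly anticonservative, which the test suite's coverage
check quantifies rather than hides.

The importance measure is marginal (fixed-terms) variance explained,
$R^2_m = \mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) +
\hat\sigma_u^2 + \hat\sigma_e^2)$. Per-variable "variance explained" has
no unique definition in a mixed model; we attribute to a term the drop in
$R^2_m$ when that term's fitted contribution is subtracted from
$X\hat\beta$ (floored at zero, sibling dummy indicators removable
together). This is cheap, never requires a refit, and reduces to the
squared standardized slope for a predictor orthogonal to the covariates —
the property the tests check. Alternatives (commonality analysis,
refitted semi-partials) could be substituted behind the same interface.

### Change associations: baseline-adjusted regression

For long-term associations each participant contributes at most one
baseline/follow-up pair: the baseline is the first visit with a later
visit whose gap falls within `target_years` ± `tolerance_years`
(defaults 10 ± 2; the survey's decade design implies ~10-year gaps but
no tolerance is part of the protocol, so it is exposed as a parameter),
and the follow-up is the later visit with gap closest to target. The
model is ordinary least squares of the follow-up trait value on the
baseline exposure, adjusted for baseline age and age², sex, follow-up
time, the baseline trait value, the mean of baseline and follow-up BMI
(omitted when BMI is the outcome), and — for dietary exposures and
blood-based traits respectively — baseline FFQ version/TEI and fasting
status at both visits. Two deliberate asymmetries with the average model
are worth flagging: educational level is *not* part of this covariate
set, and fasting status follows the same
glycaemic/lipid-outcomes-only rule as the average model; both follow the
protocol's printed covariate list rather than a silent harmonization of
the two models. The change-mode importance measure is the semi-partial
R²: the drop in model R² when the exposure column is refitted out.

## Discovery, ranking, prioritization

P-values are BH-adjusted within one family per trait × mode — average
and change screens are corrected separately, matching how signal counts
are reported per trait for each analysis. `bh_adjust()` is the exact
step-up estimator ($\tilde p_{(i)} = \min_{j \ge i} m\,p_{(j)}/j$,
capped at 1); the suite verifies it against both a brute-force double
loop and `stats::p.adjust`. *Tentative signals* are associations with
adjusted p strictly below `alpha` (default 0.05).

Ranking proceeds within trait × category on variance explained, after
collapsing dummy rows to their parent variable (keeping the maximum
variance explained — the level contrast that matters most for ranking);
ties break by smaller raw p, then name, so results are deterministic.
The top `top_k` (default 5) per category per trait feed the cross-trait
rule: a variable present in the top sets of at least `min_traits`
(default 5 of 9) traits *and* flagged modifiable in the catalog is
prioritized; non-modifiable candidates are kept in the report with their
exclusion reason. We read "top-ranked" as membership in the per-category
top-5 of a trait rather than rank 1 — the "(five per category per
trait)" phrasing of the rule supports this — and the threshold is a
parameter in any case.

Prioritized variables are clustered on distance $1 - r$ (signed Pearson
correlation on pairwise-complete transformed values) with average
linkage. Signed, not absolute, correlation: target groups are allowed to
mix positively and negatively associated variables, and a protective and
a harmful variable tracking the same behaviour should still cluster.
Pairs with fewer than 3 complete observations or zero variance are
masked and imputed with the mean unmasked distance before clustering.
The number of flat "target groups" is a user parameter: in practice such
groups are read off a dendrogram by a scientist, and we do not pretend
the algorithm chooses it.

## Harmonization rules and their parameters

| Parameter | Default | Meaning |
|---|---|---|
| `medication_constants` | +0.208 TG, +1.347 TC, −0.060 HDL, +1.290 LDL (mmol/L); +15 SBP, +10 DBP (mmHg) | additive correction for treated participants |
| `trait_normal_ranges` | broad physiological bounds | plausibility window; outside values set missing |
| `ffq_missing_limit` | 0.10 | max FFQ item missingness per visit |
| `fil_lower_pct`, `fil_upper_pct` | 5, 2.5 | implausible food-intake-level tails (bottom / top) |
| `dominance_threshold` | 0.90 | modal-level frequency dropping a categorical |
| `inv_normal_offset` | 3/8 | rank offset of the inverse-normal transform |
| `conversion_maps` | none | per-trait linear maps aligning instrument eras |

Notes on the open points:

* **Inverse-normal offset.** The protocol says only that numeric
  variables were inverse-normalized; the Blom offset
  $(r - 3/8)/(n + 1/4)$ is the commonest convention in epidemiology and
  is exposed as configuration. "Scaled for comparability" is delivered by
  the normal-quantile map itself (unit variance asymptotically); no
  second standardization pass is applied. Ordinal exposures pass their
  integer codes through the same transform, i.e. are treated as
  continuous.
* **Dominance boundary.** "90% of the observations in one category" does
  not fix the boundary; we drop at ≥ 0.90 (inclusive).
* **Trait plausibility ranges** are package defaults, labelled as
  artifact choices — the original study's ranges live in unpublished
  supplementary material.
* **BMR for the food intake level** (TEI/BMR) defaults to the Schofield
  sex/age-band equations on weight, or a user-supplied column; the
  protocol does not name its method.
* **FIL percentiles** are computed on the input table at hand (not on a
  fixed external reference), and the portion-indication rule blanks a
  visit's dietary values when *any* portion indicator is missing.
* **Order of operations**: medication correction precedes outlier
  filtering (so a treated-but-plausible value is corrected before being
  judged), and cell-level filters are mutually independent, so their
  order cannot change the final table — a property the tests assert.
* Instrument-era alignment is an optional user-supplied linear map per
  trait, since published conversion equations are cohort-specific.
* No imputation anywhere: every model is complete-case on exactly the
  columns it uses.

## The synthetic cohort: what it emulates, what it does not

`generate_cohort()` reproduces the statistical structure the two models
assume: participants aged 30–70 with 1–3 visits at decade ages
{30, 40, 50, 60} (±1 year jitter, mean 2.2 visits — matching a cohort
with ~31k participants and ~68k examinations), nine traits with
realistic means/SDs, participant random intercepts correlated across
traits through a shared factor (default correlation 0.3), ten exposure
categories (default 286 exposures with the published 10-category split)
whose within-category latents share a common factor at the configured
block correlation (default 0.3), dietary latents coupled to energy
intake through the food-intake-level path so the energy-residual step
has real confounding to remove (coupling chosen so within-category
correlation is preserved), ordinal and categorical exposures obtained by
thresholding their latent normals (which preserves the block
structure across types), a configurable share of categoricals built with
a ≥ 90% dominant level to exercise the dominance filter, medication and
exclusion flags at plausible prevalences, and completely-at-random
missingness on exposure cells (the protocol describes no missing-data
mechanism, so none is invented).

Planted effects are *standardized* slopes: one total trait SD
($\sqrt{\sigma_u^2 + \sigma_e^2}$) per SD of the exposure's latent
scale, so a slope of 0.25 is equally detectable on BMI (SD ≈ 3.8) and
on SBP (SD ≈ 17). The generator returns the full effect matrix with the
derived null and cross-trait (≥ 5 traits) sets, so recovery can be
scored without re-deriving ground truth.

What it does **not** emulate — and therefore what green tests do *not*
establish about real data: informative missingness, measurement error in
the FFQ, exposure–covariate confounding beyond the energy-intake path,
non-Gaussian trait distributions, selection effects in who returns for
follow-up visits, and real instrument drift. Passing the suite shows the
machinery is correct under its own assumptions, not that those
assumptions hold in any particular cohort.

## Numerical choices and degenerate inputs

* REML search is bounded on $\log\lambda \in [-15, 10]$; the boundary
  fit $\lambda = 0$ is compared explicitly and wins ties, so singleton
  cohorts degrade to OLS exactly.
* Rank-deficient designs fail fast with the names of the dependent
  columns; in a screen this is caught per model and recorded in the
  row's `status` instead of aborting the run.
* `inverse_normal` refuses constant or near-empty vectors (no rank
  information); `harmonize_cohort` drops such exposures and logs them.
* `energy_adjust` requires ≥ 3 complete pairs and non-constant energy
  intake; residuals are orthogonal to TEI to ~1e-10 by construction.
* age² is built from mean-centred age to tame collinearity with the
  intercept; slopes are unchanged by this reparameterization.
* All randomness flows through a single integer seed; identical
  configuration and seed give byte-identical output files, which the
  pipeline manifest (MD5 digests per artifact) makes checkable.

## Problem sizes used by the test suite

The suite is sized for a single CPU: the coverage study uses 500
replicates of 2000 participants × 2 visits with one exposure; the
end-to-end prioritization study uses 50 replicates of 2000 participants
with a 30-exposure panel (3 per category) and a planted exposure
affecting 6 of 9 traits at standardized slope 0.25; FDR calibration uses
1000 replicated 286-test families. These sizes give Monte-Carlo error
comfortably inside the asserted tolerances while keeping a full run in a
few minutes.

## Known limitations

* Random intercepts only: no random slopes, crossed effects, or
  non-Gaussian outcomes — deliberate non-goals.
* Wald/normal inference is anticonservative for very small samples.
* The per-term variance-explained decomposition ignores collinearity
  among terms (the parts need not sum to the whole); rankings within a
  correlated category should be read as "representative member", which
  is how the clustering step treats them.
* One pair per participant in the change screen; multi-interval
  trajectories are out of scope.
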