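---
title: "Methods: deriving a count-based hospital-ED risk index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving a count-based hospital-ED risk index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical procedure it
implements, the choices made where the design was genuinely open, and what
the synthetic-data experiments do and do not demonstrate.

## The estimand and the pipeline

The outcome is binary: any overnight hospital stay or emergency-department
visit in the 90 days preceding a follow-up assessment of an elderly
(60+) home-care client. Predictors are dichotomous baseline assessment
items from nine domains, plus a baseline *prior-use* flag (any hospital/ED
use in the 90 days before baseline). The goal is not a maximally
discriminating black-box model but a transparent, unweighted *count* of
clinically meaningful risk factors — an index a field assessor can compute
and explain — derived by:

1. a cross-cohort **poolability check**,
2. a **univariate odds-ratio screen** with derivation/validation
   confirmation,
3. **staged stepwise logistic regression** with a dual-sample retention
   rule, and
4. **index construction** (count, protective decrement, cap, prior-use
   extension), followed by stratified-rate evaluation.

## Screening

Items are dichotomous on arrival (the generator emits binary items; for
real ordinal data the package expects the caller to apply a dichotomization
rule first — `read_cohort_csv()` validates 0/1 values and reports offending
rows). For each item a 2×2 exposure-by-outcome table is built separately in
the derivation and validation samples and the cross-product odds ratio
computed. Thresholds are inclusive: OR ≥ 1.30 (both samples) flags a risk
candidate, OR ≤ 0.75 flags a protective candidate. The screen is point-OR
thresholding by design: at repository scale almost everything is
"statistically significant", so effect magnitude, not a p-value, is the
filter. No confidence intervals are attached, deliberately.

**Zero cells.** When any cell of a table is zero the Haldane–Anscombe
correction (+0.5 to all four cells) is applied before forming the ratio.
This keeps rare items in the screen rather than dropping them; the amount
is configurable (`screening_config(continuity_correction=)`). A table that
is all zeros, or still has a zero off-diagonal product after correction,
has no defined OR; `screen_all()` records `NA` and classifies the item
neutral instead of failing the whole screen.

**Poolability** is *directional consistency only*: every probe item's OR
must lie on the same side of 1 in every cohort. No formal homogeneity test
(e.g. Breslow–Day) is imposed, because the pooling rationale being encoded
is a qualitative "same risk forces at work", not equality of effect sizes.
The default probe set (`default_probe_items()`) mirrors the classic
literature probes — pneumonia, congestive heart failure, urinary tract
infection, Alzheimer's disease (expected protective: the item is coded
disease-present, and its OR is expected below 1), nine-plus medications.
Note that under the package's default planted truth the CHF-like item is
null, so on default synthetic data that probe's direction is sampling noise;
a meaningful check should probe items that carry real effects, which is what
the examples and the validation suite do.

## Stepwise selection

The stepwise stage is specified as *staged*: stage 1 considers only
clinical complications, disease diagnoses, and specialized treatments (the
domains with the most compelling face validity); stage 2 offers the
remaining six domains to the surviving model. Within a stage the package
uses **forward selection with likelihood-ratio entry** at α = 0.05, best
candidate (largest LR statistic) first. Forward-vs-backward was an open
choice; forward selection was adopted because the candidate pool after
screening is small and the selection trace (`$trace`) makes every entry and
drop auditable.

The distinctive rule is **dual-sample retention**: after every entry, each
covariate must hold a multivariate OR of at least 1.2 in the derivation fit
*and* in the same covariate set refit on the validation sample, or it is
dropped (all failing covariates at once, repeated until stable) and barred
from re-entry. Protective candidates are evaluated against the reciprocal
threshold (OR ≤ 1/1.2) rather than excluded, since protective factors are
intended to enter the final model. Whether the validation check should
refit coefficients or evaluate frozen derivation coefficients was
ambiguous; *refit* is the default (consistent with reporting distinct
derivation and validation ORs per covariate), and
`selection_config(validation_rule = "derivation_only")` is the switch for
the single-sample variant.

**Numerics.** The fitter is a self-contained Newton/IRLS routine:
convergence when the score vector's max-norm is ≤ 1e-8 (cap 100
iterations); step-halving keeps the likelihood ascent monotone, with the
acceptance slack *relative* to |log-likelihood| so floating-point rounding
at large n cannot trigger futile halving; candidate fits warm-start from
the current model's coefficients. Degenerate designs (constant outcome or
covariate, singular information) and quasi-complete separation (any
|β| > 15 on the log-odds scale) raise classed errors
(`hedri_degenerate_error`, `hedri_separation_error`). The test suite checks
the fitter against `glm()` and against direct numerical likelihood
maximization with `optim()`, and checks the selector against exhaustive
best-subset enumeration on a small instance.

## The index

Final-model covariates with OR > 1 are counted; covariates with OR < 1
subtract. Rules, in order: raw count of risk items present; minus one if
*one or both* protective factors are present (the decrement is deliberately
idempotent in the number of protective factors); floored at zero (the
published category axis starts at 0 — a person with a protective factor and
no risk factors scores 0, not −1); capped at 6+ for the category. The
extended index maps persons without prior use to categories 0–6 and with
prior use to 7–12. The source scale offers seven no-prior cells but only
six prior cells, so the mapping is 7 + min(score, 5): prior-use scores of 5
and above share the top cell. This was an unresolved ambiguity; the chosen
mapping is recorded here and enforced exhaustively in the tests.

The canonical 16-item definition ships as data
(`inst/extdata/hospital_ed_index.json`, loaded by
`default_index_definition()`): fourteen named items plus two configurable
slots, because the published description names only fourteen of the sixteen
final covariates explicitly. The slots default to a fever-like complication
and the nine-plus-medications treatment item (the latter is named in the
source discussion as a final-model treatment). Home health aide screens
protective univariately but is *not* in the default protective pair —
only Alzheimer's disease and day care are, matching the final published
pair.

## The synthetic-cohort generator

The generator is first-class, tested code, and its defaults are the study
conditions used throughout the validation suite:

* **123 items** in the published nine-domain profile
  (28/19/15/6/12/4/11/10/18).
* **Planted truth**: 16 elevated-risk items with conditional ORs spread
  over 1.5–2.0, placed as 7 clinical complications, 3 diseases, 6
  treatments (the composition of the canonical index); 2 protective items;
  105 null items. Protective conditional ORs are 0.60 (Alzheimer's-like)
  and 0.65 (day-care-like): marginal univariate ORs attenuate under
  non-collapsibility across the other planted effects, and these values put
  the *observable* screening ORs near the published day-care value
  (~0.66) rather than at the 0.75 boundary.
* **Prevalences**: fixed per named item (e.g. pneumonia 0.04, falls 0.30,
  nine-plus medications 0.35); null items cycle through
  {0.05, …, 0.40}.
* **Cohorts**: six, with intercepts calibrated (first order, by
  subtracting the expected planted linear predictor) to spread follow-up
  event rates over roughly 0.27–0.41; equal sampling weights.
* **Prior use**: independent Bernoulli(0.45) with planted coefficient
  log(4) — prior utilization as the dominant single predictor.
* **Ages**: uniform integers on [60, 100]; metadata only, never a
  covariate.
* **Seeds**: one master seed; each stochastic stage (cohort assignment,
  ages, items, prior use, outcome, split) draws from a deterministically
  derived child seed, so the whole pipeline is bit-reproducible.

Items are generated **independently** by default. Real assessment items
are correlated; independence is a declared simplification that makes
planted-truth recovery analyzable, not an inference about real data. An
optional within-domain correlation hook
(`sim_config(domain_correlation=)`) threshold-shares a latent Gaussian
factor per domain for sensitivity analyses, and is off by default.

Consequently, passing the recovery experiments shows that the pipeline's
*mechanics* are correct under known conditions — it does not show that the
index transfers to correlated, missingness-afflicted real repositories, and
no missing-data mechanism is modelled at all (complete cases are the
analytic contract).

### Effect-size profiles and the prior-use crossing

One consequence of independence deserves emphasis. With 16 independent
items at conditional ORs 1.5–2.0, persons in the 6+ category carry a
summed log-odds load of ~3, so the synthetic category gradient is much
steeper than published gradients from correlated real data. Under those
conditions a prior-use OR of 4 cannot lift the (prior use, category 0) rate
above the (no prior use, category 6+) rate — the crossing that makes prior
utilization "a powerful driver in and of itself". The published
no-prior gradient (≈17% at category 0 to ≈32% at 6+) implies *adjusted*
per-item effects near OR 1.13–1.15. The package therefore evaluates the
crossing on the moderate profile `default_catalog(risk_ors = 1.15)` with a
baseline intercept of qlogis(0.174) and prior-use OR 4 — the conditions the
published stratified rates themselves imply — and the crossing emerges
reproducibly (the acceptance script reports corner rates near 41% and 31%
at n = 200,000). The strong profile remains the default for screening and
selection recovery, where the planted values are the published *univariate*
magnitudes.

## Problem sizes and tolerances used in validation

The validation suite generates cohorts of 100,000 persons (50,000 per
split) for screening/selection recovery across ten seeds, 100,000–200,000
for the rate-gradient and crossing checks, and 6,000 for byte-level
determinism of the full file pipeline; oracle comparisons use 200 small
tables (exact equality) and 100 small logistic fits (1e-5 against an
independent optimizer, 1e-6 for the univariate MLE-vs-cross-product
identity). The monotone-gradient check tolerates adjacent-cell reversals
within twice the pooled binomial standard error, because the gradient claim
being encoded is qualitative, never a formal trend test.

## Known limitations

* Selection inference: the stepwise procedure's standard errors are
  conditional on selection and should not be read as honest post-selection
  inference; the package reports ORs, not CIs, for the index items.
* The screen and retention rules are threshold rules; items with true
  effects just under the thresholds are excluded by design.
* No discrimination metrics (AUC / c-statistic) are offered: the index's
  contract is a monotone stratification, and reporting discrimination
  would misrepresent what the derivation optimizes.
* The generator emulates marginal structure (prevalences, event-rate
  spread, planted effects), not the joint dependence of real assessment
  items, ordinal item scales, ICD codings, or assessment-timing
  variability.
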