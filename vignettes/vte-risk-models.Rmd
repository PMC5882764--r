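---
title: "Validating VTE risk assessment models in lung cancer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating VTE risk assessment models in lung cancer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vteram)
```

## The problem and the models

Ambulatory lung-cancer patients on chemotherapy have a high incidence of
venous thromboembolism (VTE), yet primary thromboprophylaxis is not given
routinely; additive clinical point scores are used to find the high-risk
minority. `vteram` implements four such scores and the statistics needed
to validate them against an observed binary VTE outcome.

The Khorana score (KRS) family is additive with one point per item. For
lung cancer the tumour-site item is always worth 1 point, so every
patient starts at 1 and the theoretical 0-point low band is unreachable;
the KRS items are platelets > 350 × 10⁹/L, leukocytes > 11 × 10⁹/L,
hemoglobin < 10 g/dL and/or use of erythropoiesis-stimulating agents, and
BMI ≥ 35 kg/m². PROTECHT appends one point each for platinum- and
gemcitabine-based chemotherapy; CONKO swaps the BMI item for WHO/ECOG
performance status ≥ 2. All three call ≥ 3 points high risk.

COMPASS-CAT is a weighted sum: anthracycline treatment (6), ≤ 6 months
since cancer diagnosis (4), central venous catheter (3), advanced disease
(2; TNM 7th-edition stages IIIB and IV), a cardiovascular composite (5;
at least two of peripheral artery disease, ischemic stroke, coronary
artery disease, hypertension, hyperlipidemia, diabetes, obesity), recent
hospitalization for acute medical illness (5), personal VTE history (1),
and platelets ≥ 350 × 10⁹/L (2). High risk is ≥ 7 points; the maximum is
28. Only the items above are implemented — variants of the score defined
for other cancers (hormonal therapy, breast-specific items) are out of
scope, as are other published RAMs (Vienna CATS, ONKOTEV, Tic-Onco) and
biomarker extensions.

Two threshold subtleties are deliberate and covered by boundary tests:
the KRS-family platelet and leukocyte items are strict (`> 350`, `> 11`)
and the hemoglobin item is strict (`< 10`), while the COMPASS-CAT
platelet biomarker is inclusive (`>= 350`); the time item is inclusive
(`<= 6` months). Exactly 350 × 10⁹/L therefore fires COMPASS-CAT but not
the KRS. The BMI item uses ≥ 35 even though it is often phrased "above
35": the threshold form is the one used operationally for patient
counting, and the cohort schema enforces that the `obesity` comorbidity
flag (which feeds the cardiovascular composite) equals `bmi_ge_35`, since
both encode BMI ≥ 35 kg/m².

Each scorer returns a `fired_items` audit trail (`item = points`); the
point total always equals the sum of the trail, which is what the
exhaustive enumeration tests exercise (all 2⁴–2⁸ item combinations per
model against an independent counting/dot-product oracle).

### Risk banding

The KRS banding is 0 low / 1–2 intermediate / ≥ 3 high, the convention of
the original score. PROTECHT and CONKO publications group everything
below 3 points simply as non-high; because the lung-site point makes 0
unreachable here, those two models emit only `intermediate` and `high`.
COMPASS-CAT is two-banded: `low` below 7, `high` at or above.

## Validation statistics

**2×2 machinery.** Cells are (a, b, c, d) = (exposed event, unexposed
event, exposed non-event, unexposed non-event). Sensitivity, specificity,
PPV and NPV follow the usual ratios with exact Clopper–Pearson 95%
intervals; a zero denominator yields a flagged `NA`, never a silent 0.
Odds ratios are the cross-product ad/bc with the Woolf log-scale standard
error √(1/a + 1/b + 1/c + 1/d) and a ±1.96·SE interval; if any cell is
zero, 0.5 is added to all four cells (Haldane–Anscombe) and the result is
flagged, and a table with both cells of a diagonal zero is returned
non-estimable. Univariate screening uses this closed form rather than an
iterative fit — for a single binary factor the logistic MLE coincides
with it, which the suite verifies to 6 significant digits.

**Tests.** The chi-square test is Pearson's X² without Yates continuity
correction, df = 1 (the form that reproduces the reference p-values
0.0002 and 0.0122 from their printed counts). The Mann–Whitney U uses
midranks; the two-sided p-value comes from exact enumeration of all
label assignments when both samples have ≤ 8 observations (ties allowed),
otherwise from the normal approximation with tie-corrected variance and
no continuity correction. No multiple-testing adjustment is applied
anywhere, matching the validation design being reproduced (reporting at
0.05, multivariate entry at 0.01).

**ROC.** One operating point per distinct score, thresholds descending,
"score ≥ threshold" positive, anchored at (0,0) and (1,1). The
trapezoidal AUC of this step curve equals the tie-inclusive Mann–Whitney
concordance (ties ½), i.e. the C statistic — asserted on random inputs as
a property. The AUC standard error is Hanley–McNeil. The optimal cutoff
maximizes Youden's J = sensitivity + specificity − 1; the criterion is an
assumption (the validation design being reproduced names none), and ties
break toward the higher threshold so the more conservative rule (fewer
test-positives) is preferred.

**Logistic regression.** `fit_logistic()` is a binomial maximum-
likelihood fit (IRLS, ≤ 100 iterations, deviance tolerance 1e-12) with
Wald standard errors, OR = exp(β), and CI = exp(β ± 1.96·SE). Separation
is detected when some fitted probability is within 1e-6 of 0 or 1 while a
coefficient magnitude exceeds 10; the fit is then returned with a warning
and a flag instead of being repaired (no Firth or Bayesian correction —
detection and exclusion, not repair, is the design). The multivariate
stage admits factors with univariate chi-square p below `alpha_in`
(default 0.01), excluding non-estimable factors and factors with a zero
cell among events or non-events (which force quasi-complete separation),
and records every exclusion.

**Rounding.** Percentages are rounded half away from zero (34.7 → 35,
82.5 → 83), integer percent by default and one decimal where the
convention calls for it (17.7, 23.8, 16.9). Rounding is presentation
only: all stored proportions keep full precision, and report JSON is
written at full precision.

## The synthetic cohort generator

`generate_cohort()` emulates a 118-patient ambulatory lung-cancer cohort.
Covariates are drawn independently at configured marginal prevalences
(male 58%, atrial fibrillation 11%, chronic kidney disease 13%,
gemcitabine 21%, platinum 81%, recent hospitalization 56%, WHO PS ≥ 2
15%, BMI ≥ 35 5.1%, central venous catheter 5.9%, anthracyclines and ESA
0%, and so on), with three built-in couplings: TNM stage is drawn from
the cohort's categorical stage distribution and advanced disease is
*derived* from it (IIIB + IV = 87/118 — note the stage table implies a
larger advanced fraction (74%) than the separately tabulated 64%, an
inconsistency in the source marginals that the generator resolves in
favour of the stage distribution); `obesity` is identical to `bmi_ge_35`
by construction; and the binary blood-count items are derived from
continuous log-normal draws. Blood counts fix realistic dispersions
(sdlog 0.35 platelets, 0.40 leukocytes, 0.12 hemoglobin) and solve the
location parameter so the threshold-crossing probability matches the
configured prevalence (34% platelets > 350, 20% leukocytes > 11, 3.4%
hemoglobin < 10); the implied medians (≈ 303 × 10⁹/L platelets,
≈ 7.9 × 10⁹/L leukocytes, ≈ 12.5 g/dL hemoglobin) are plausible
pre-chemotherapy values. Time since diagnosis is uniform on (0, 12]
months, so about half the patients fire the ≤ 6-month item — newly
diagnosed cohorts likely fire it more often, and the bound is
configurable. Peripheral artery disease has no tabulated marginal; 3% is
a one-time choice typical of an outpatient oncology population.

The outcome is logistic: logit p = β₀ + ln(8.73)·[COMPASS-CAT ≥ 7] +
ln(3.37)·[gemcitabine] + ln(7.19)·[atrial fibrillation], where the
high-score indicator is computed from the patient's own generated
covariates by the actual scorer. β₀ is calibrated by bisection so the
Monte-Carlo expected event rate (40,000 covariate draws under a fixed
internal seed, tolerance 1e-4) equals the 16.9% target; with all effect
ORs at 1 this reduces to the closed form logit(0.169), which the tests
check. VTE event times are exponential with median 2.5 months, truncated
at follow-up (uniform 1–24 months); they are descriptive colour, not an
analysis surface. All draws are governed by one integer seed in a fixed,
documented field order; the generator restores the caller's RNG state.

What the generator does *not* emulate: correlations between comorbidities
(real hypertension and hyperlipidemia co-occur; only marginals are
known), mutual exclusivity of platinum and gemcitabine regimens,
anticoagulation effects, or competing mortality. Consequently the
synthetic joint distribution of score items — e.g. the fraction of
patients reaching COMPASS-CAT ≥ 7 — need not match any particular
observed cohort, and passing tests demonstrate correctness of the
*pipeline*, not clinical performance of the scores on real patients.

## Problem sizes and statistical checks

The suite validates parameter recovery at two scales, chosen as the
smallest sizes at which each claim is sharp: at n = 100,000 each
recovered log-OR must lie within ±0.1 of its generating value (Wald SEs
there are ≈ 0.02–0.04, so the bound is a 3–5σ guarantee, and the fit
takes ~1 s); at n = 10,000 over 20 seeded replicates, recovery is tested
on the standardized scale — the per-factor median of |β̂ − β|/SE must
stay below 1.5 (the true median of a standard half-normal is 0.674, so
this fails with negligible probability under a correct generator/fit pair
but catches any bias or mismatch), with a 0.6 gross-error bound per
replicate. A naive "median relative OR error < 10%" bound at n = 10,000
would be a coin flip for the strongest factor (its Wald SE ≈ 0.124
implies a median relative error near 9%), which is why the standardized
form is used. Law-of-large-numbers checks of the marginals run at
n = 200,000 with an absolute ±0.005 band. The desk-scale end-to-end run
(simulate 118 → full report) completes in a few seconds.

## Known limitations

* The univariate screen handles binary factors only (as 2×2 tables);
  continuous predictors enter only through `fit_logistic()` directly.
* Separation is excluded/flagged, never corrected; cohorts in which a
  factor is pathologically nested in the outcome yield no estimate for
  that factor by design.
* The KRS site point is hard-coded for lung primaries; applying the
  package to mixed-site cohorts would require the full site taxonomy,
  which is out of scope.
* Survival analysis (Kaplan–Meier, log-rank) is out of scope; `death` and
  follow-up fields are carried but not modelled.
* Atrial fibrillation is a single boolean; paroxysmal and permanent AF
  are not distinguished.
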