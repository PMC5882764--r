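# vteram

Venous thromboembolism (VTE) risk assessment models for ambulatory
lung-cancer patients, with the full statistical pipeline used to validate
them on a cohort.

Patients receiving outpatient chemotherapy for lung cancer face a
substantial risk of deep vein thrombosis and pulmonary embolism, but
routine thromboprophylaxis is not recommended; clinicians instead use
additive point scores ("risk assessment models", RAMs) to find the
patients who might benefit. `vteram` is for biostatisticians and clinical
researchers who want to apply or validate these scores on a patient-level
cohort table, and for methodologists who want a reproducible, fully
synthetic test bed for that validation.

## The models

For a patient with pre-chemotherapy platelet count *P* (10⁹/L), leukocyte
count *W* (10⁹/L), hemoglobin *H* (g/dL):

* **Khorana risk score (KRS)** = 1 (lung primary) + 1[*P* > 350] +
  1[*W* > 11] + 1[*H* < 10 or ESA use] + 1[BMI ≥ 35].
  Risk: 0 low, 1–2 intermediate, ≥ 3 high.
* **PROTECHT** = KRS + 1[platinum chemotherapy] + 1[gemcitabine
  chemotherapy]; high at ≥ 3.
* **CONKO** = KRS with the BMI item replaced by 1[WHO/ECOG performance
  status ≥ 2]; high at ≥ 3.
* **COMPASS-CAT** = 6·[anthracycline] + 4·[≤ 6 months since diagnosis] +
  3·[central venous catheter] + 2·[advanced disease, TNM IIIB/IV] +
  5·[≥ 2 cardiovascular risk factors] + 5·[recent hospitalization for
  acute medical illness] + 1·[personal VTE history] + 2·[*P* ≥ 350];
  high at ≥ 7.

Validation statistics: sensitivity/specificity/PPV/NPV of each high-risk
group with exact binomial intervals; cross-product odds ratios with Woolf
95% confidence intervals (Haldane–Anscombe 0.5 correction for zero
cells); Pearson chi-square (no continuity correction); Mann–Whitney *U*
with midrank ties (exact enumeration for small samples); ROC curves whose
trapezoidal AUC is the tie-inclusive concordance (C statistic), with
Hanley–McNeil standard errors and Youden-optimal cutoffs; and univariate
screening (*p* < 0.01) feeding a multivariate logistic regression with
Wald odds-ratio intervals and separation detection.

A seeded generator (`generate_cohort()`) produces synthetic cohorts with
the marginal structure of a 118-patient lung-cancer cohort and a logistic
VTE outcome (high COMPASS-CAT OR 8.73, gemcitabine OR 3.37, atrial
fibrillation OR 7.19; event rate calibrated to 16.9%), so the entire
pipeline runs and is testable without patient data.

## Worked example

Score a single stage-IV adenocarcinoma patient, 2 months from diagnosis,
recently hospitalized, with hypertension + hyperlipidemia + coronary
artery disease and platelets 362:

```r
library(vteram)
score_khorana(patient)
#> <ram_score> KRS: 2 points (intermediate)  items: site_lung=1; platelets_gt_350=1
score_compass_cat(patient)
#> <ram_score> COMPASS_CAT: 18 points (high)  items: diagnosis_le_6_months=4;
#>   advanced_disease=2; cardiovascular_risk_factors=5; recent_hospitalization=5;
#>   platelets_ge_350=2
```

The Khorana score awards the unconditional lung-site point plus the
platelet point (362 > 350) — intermediate risk. COMPASS-CAT fires five
weighted items for 18 points, well above its 7-point high-risk threshold.

Validate all four models on a synthetic cohort:

```r
co <- generate_cohort(synthetic_config(n = 118, seed = 42))
rep <- run_analysis(co)
rep$summary
#> $n        118
#> $vte_n    20
#> $vte_rate_pct  16.9
rep$diagnostics[rep$diagnostics$model == "COMPASS_CAT", 1:9]
#>        model tp fn fp tn sensitivity_pct specificity_pct ppv_pct npv_pct
#>  COMPASS_CAT 18  2 78 20              90              20      19      91
```

16.9% of the simulated patients develop VTE (the calibrated rate); at
n = 118 the estimated diagnostic metrics are noisy, which is exactly what
the package's large-sample tests quantify. The same pipeline is available
from a shell:

```sh
vteram simulate --n 118 --seed 42 --out cohort.csv
vteram score    --in cohort.csv --out scores.csv
vteram report   --in cohort.csv --out report.json --text report.txt
```

(`exec/vteram` in the installed package; run it with `Rscript` if it is
not on your PATH.)

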