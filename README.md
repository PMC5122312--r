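# pedasthma

Rule-based case finding for **paediatric asthma** in primary-care EMR
extracts, together with the diagnostic-validation statistics used to judge
such rules against a gold-standard chart review, and a synthetic-cohort
generator so the entire pipeline runs without any real patient data.

## Who this is for

Chronic-disease surveillance in networks such as CPCSSN (the Canadian
Primary Care Sentinel Surveillance Network) relies on *case definitions*:
deterministic rules over coded and free-text EMR elements that label each
patient as having or not having a condition. This package implements the
operational case definition for asthma in children aged 1–17 and the
machinery to validate any such binary classifier against physician review.

## The case definition

A patient aged 1–17 (completed years at the extraction reference date,
default 2015-06-30) is a **case** when

```
n_rx >= 2   OR   (n_rx >= 1 AND (billing_hit OR encounter_hit OR condition_hit))
```

where

* `billing_hit` — any billing diagnosis with ICD-9 code 493 or a derivative
  (`493`, `493.0`, `493.90`, …; prefix match on the normalised code);
* `encounter_hit` / `condition_hit` — any encounter-diagnosis or
  problem-list row with a 493-prefix code, **or** free text containing a
  token starting with `asth` that is *not* an uncertainty notation.
  Uncertainty notations are matched whole-field by the globs
  `*asthma*query*`, `*query*asthma*`, `*asthma*?*`, `*?*asthma*`
  (`*` = any sequence, `?` = the literal question mark), so "asthma query",
  "query asthma", "asthma?" and "?asthma" never count;
* `n_rx` — the number of prescriptions for one of 22 qualifying medications
  (inhaled corticosteroids, ICS/LABA combinations, short/long-acting
  beta-agonists, leukotriene receptor antagonists, systemic corticosteroids,
  ipratropium), matched by 7-character ATC code, with a drug-name fallback
  for rows lacking a code.

Validation metrics are the standard diagnostic-accuracy quantities from the
2×2 algorithm-vs-gold table — sensitivity `TP/(TP+FN)`, specificity
`TN/(TN+FP)`, PPV `TP/(TP+FP)`, NPV `TN/(TN+FN)` — with exact
(Clopper–Pearson) or Wilson confidence intervals, plus percent agreement and
Cohen's kappa `(p_o − p_e)/(1 − p_e)` for inter-rater comparisons.

## Worked example

Metrics straight from published confusion counts (1–17-year stratum of a
1000-record validation):

```r
library(pedasthma)
cm <- confusion_matrix(tp = 125, fp = 12, tn = 845, fn = 18)
sensitivity(cm)
#> <metric_estimate> 87.4 (80.8-92.4) [125/143, clopper-pearson, 95% CI]
ppv(cm)
#> <metric_estimate> 91.2 (85.2-95.4) [125/137, clopper-pearson, 95% CI]
```

So 87.4% of gold-standard cases are found by the rule, and 91.2% of
patients the rule flags are true cases.

A full synthetic round trip — generate a cohort with known labels, classify
it, validate the verdicts:

```r
lc  <- generate_cohort(cohort_config(n_patients = 1000, seed = 7))
lc
#> <labelled_cohort> 1000 patients, 143 gold-positive (14.3%), 9 suspected
#> <emr_cohort> 1000 patients (reference date 2015-06-30)
#>   billing: 67  encounters: 277  conditions: 61  prescriptions: 419

cls <- classify_cohort(lc$cohort)
alg <- setNames(cls$is_case, cls$patient_id)
stratified_report(lc$cohort, alg, lc$gold)
#> Validation report (clopper-pearson, 95% CI; % to one decimal)
#> Age range         n    TP    FP    TN    FN  Sensitivity        Specificity        PPV                NPV
#> 1-17 years     1000   124     9   848    19  86.7 (80.0-91.8)   98.9 (98.0-99.5)   93.2 (87.5-96.9)   97.8 (96.6-98.7)
#> 3-17 years      878   106     7   757     8  93.0 (86.6-96.9)   99.1 (98.1-99.6)   93.8 (87.7-97.5)   99.0 (97.9-99.5)
#> 6-17 years      710    89     5   610     6  93.7 (86.8-97.6)   99.2 (98.1-99.7)   94.7 (88.0-98.3)   99.0 (97.9-99.6)
```

The false negatives here are the deliberately sparse "suspected" records
(very young patients with little documentation) plus gold-positives whose
generated documentation falls below the rule's thresholds.

A tiny file-based cohort ships under
`inst/extdata/synthetic_demo/` (synthetic, generated by
`cmd_simulate(..., seed = 2024)`), and the same workflows are available from
a shell via the installed `exec/pedasthma` script:

```sh
pedasthma simulate --out sim --seed 5
pedasthma classify --in sim --out cls.csv
pedasthma validate --classification cls.csv --gold sim/gold.csv --out report.csv
```

Every command writes a JSON run manifest (config snapshot, input digests,
seed, version) next to its outputs.

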