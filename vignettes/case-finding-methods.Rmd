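---
title: "Case-finding methods: the asthma rule engine, its validation statistics and the synthetic cohort generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-finding methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedasthma)
```

## The rule and its assumptions

The classifier is a deterministic rule over four EMR element types —
billing diagnoses, encounter diagnoses, health-condition (problem-list)
entries and prescribed medications — evaluated per patient with no date
window: any occurrence up to the cohort reference date counts. An
age-eligible patient (1–17 completed years, inclusive) is a case when they
have at least two qualifying prescriptions, or one qualifying prescription
together with at least one diagnosis criterion.

Assumptions worth making explicit:

* **Age convention.** Completed years at the cohort `reference_date`
  (default 2015-06-30, the extraction cut-off convention). Source records
  do not state whether ages should be evaluated at extraction or at
  encounter date, so the reference date is a parameter everywhere,
  including on the command line. A patient with a missing or unparseable
  birth date is excluded from classification (flagged ineligible) with a
  warning, never silently treated as eligible.
* **Prescription counting.** "More than a single prescribed medicine" is
  read as at least two qualifying prescription *rows*, regardless of
  molecule or date — prescription occurrences, not distinct drugs, are
  what EMR medication tables record. `rx_count_mode` offers
  `"distinct-drug"` and `"distinct-date"` for sensitivity analyses.
* **Diagnosis-only patients are non-cases.** A patient with a 493 code or
  qualifying text but zero qualifying prescriptions does not meet the
  combination rule. `allow_diagnosis_only = TRUE` enables an exploratory
  arm that counts them, since chart reviewers plainly weigh diagnostic
  labels on their own.
* **Billing is code-only.** The text inclusion/exclusion patterns apply to
  encounter and condition free text; billing rows contribute only via
  their ICD-9 code.

## Text matching semantics

Two distinct matchers operate on whitespace-normalised, case-folded text:

* **Inclusion** is token-level: `asth*` matches any whitespace-delimited
  token whose letters begin with `asth`, after stripping adjacent
  punctuation (so "?asthma" still *includes*; whether it *qualifies* is
  the exclusion matcher's job). A pattern without `*` must equal a whole
  token.
* **Exclusion** is whole-field glob matching: `*` matches any (possibly
  empty) sequence and `?` is the **literal** question mark — the patterns
  target uncertainty notations like "asthma?" and "?asthma", so treating
  `?` as a single-character wildcard would be wrong (it would, for
  example, exclude "xasthma"). The matcher is implemented by anchored
  segment scanning (first/last segments pinned when the pattern does not
  start/end with `*`, middle segments found greedily left to right), and
  the test suite checks it against an independently written regex
  transliteration on >10,000 random strings.

An excluded text row contributes nothing, but is strictly local: it never
vetoes other rows of the same patient.

## Validation statistics

Sensitivity, specificity, PPV and NPV are binomial proportions of the 2×2
algorithm-vs-gold table; each carries a two-sided confidence interval.

* **Interval method.** The default is the exact Clopper–Pearson interval
  (beta quantiles; lower bound 0 at zero successes, upper bound 1 at full
  successes), the conventional choice for diagnostic-accuracy tables; the
  Wilson score interval is available by flag. Against the published
  1–17-year stratum (sensitivity 87.4, printed interval 80.6–92.2), this
  package computes 80.8–92.4 with Clopper–Pearson and 81.0–91.9 with
  Wilson: Clopper–Pearson is the closer of the two, but neither reproduces
  the printed bounds exactly, so the printed interval recipe (and its
  rounding chain) evidently differed in some unstated detail. Point
  estimates, which this package reproduces exactly, are the reliable
  comparison surface; we kept Clopper–Pearson as default.
* **Rounding.** Percentages print to one decimal with halves rounded away
  from zero (91.85 → 91.9), matching the published table's formatting;
  all stored values remain unrounded proportions.
* **Degenerate inputs.** A zero denominator (e.g. no gold-positives in a
  stratum) yields an undefined metric reported as `NA`, never 0 or 1; an
  empty stratum produces a row of undefined metrics rather than an error.
* **Kappa.** Cohen's kappa uses expected agreement from the product of the
  raters' marginal proportions and returns 1 whenever observed agreement
  is perfect, including the degenerate single-category case where
  `1 − p_e = 0`.

## The synthetic cohort generator

No distributional information about documentation patterns accompanies the
case definition, so every generator default is an assumption, stated here
and in each run's provenance file — not a claim about real primary-care
data.

* Gold-positive status is Bernoulli per patient at `prevalence = 0.143`,
  the chart-review case prevalence observed in a 1000-record paediatric
  sample (143/1000).
* Ages are uniform integers on 1–17; birth dates are back-computed from
  the completed age with a uniform 0–364-day offset so anniversary
  boundary logic is exercised on every run.
* Gold-positives draw documentation from `case_profile`: probabilities
  0.50/0.75/0.50 of at least one billing/encounter/condition row, free
  text sampled from capitalisation and punctuation variants
  ("asthma", "Asthmatic bronchitis", …), and a prescription-count
  distribution with most mass at ≥2 (0.06/0.14/0.40/0.25/0.15 on 0–4),
  reflecting repeat prescribing as the dominant criterion.
* Gold-negatives draw from `control_profile`: a 5% rate of uncertainty
  texts covering all four exclusion shapes ("asthma query", "query re
  asthma", "?asthma", "asthma ?"), a 15% rate of benign labels ("acute
  bronchitis", "bronchiolitis", …), a 0.4% rate of stray 493 billing rows,
  and a lone-reliever prescription tail (0.90/0.09/0.01 on 0–2) emulating
  transient viral wheeze treated symptomatically.
* A **suspected** subset of gold-positives (6% by default) emulates very
  young (1–2-year-old) patients with sparse records: gold-positive by the
  reviewers' resolution of such records, yet mostly invisible to the rule.
  These are the generator's designed false negatives.
* About 10% of prescription rows carry only a drug-name string (no ATC
  code), exercising the name-fallback matcher.

One pseudo-random stream per run, fully determined by `seed`; patient order
is generation order, and identical configurations produce byte-identical
written tables.

### Calibrated mode

`calibrate_profiles(target_sensitivity, target_specificity, ...)` replaces
the free-running profiles with a mixture that makes the classifier's
expected accuracy *exactly* the targets under the default rule: each
gold-positive is generated guaranteed-qualifying with probability equal to
the target sensitivity (prescription count redrawn from the ≥1 part of the
distribution, a single script always paired with an encounter criterion)
and guaranteed-sub-threshold otherwise (at most one reliever script, never
combined with a qualifying criterion); gold-negatives symmetrically become
false positives — repeat reliever scripts, or one script plus a stray 493
billing row — with probability one minus the target specificity. Observed
sensitivity/specificity are then binomial around the targets, which is what
the recovery tests assert (3 standard errors, 20 seeds, n = 5000). The
suspected subset is drawn inside the sub-threshold arm so calibration stays
exact; calibration is defined with respect to the *default* case
definition, and reconfiguring the classifier (e.g. `allow_diagnosis_only`)
voids it.

### What passing tests do and do not show

The generator emulates the *structure* of extract tables and the corner
cases of the matching rules — not longitudinal visit dynamics, co-medication
plausibility, coding-practice drift, or population representativeness.
Recovery of a configured operating point therefore demonstrates that the
rule engine and the validation statistics are implemented correctly, not
that the rule would achieve those metrics on any real population; the
published chart-review comparison is the only real-data evidence, and this
package reproduces its summary statistics from the printed counts rather
than re-deriving them from records.

## Problem sizes and numerical choices in the test suite

The suite validates the exclusion matcher against the regex oracle on
10,000+ random strings; the combination rule against an exhaustive
truth-table oracle (eligibility × 2³ criterion combinations × 0–3 scripts);
round-trip identity on hand-built and randomly generated cohorts (n = 100–
250); and operating-point recovery on twenty 5000-patient calibrated
cohorts at the published point (0.874, 0.986), asserting agreement within
three binomial standard errors in at least 19 of 20 seeds. These sizes keep
each property comfortably identifiable (3-SE bands of roughly ±4% on
sensitivity at n = 5000 and 14.3% prevalence) while the whole suite runs in
well under a minute.

## Known limitations

* The rule engine replicates the *semantics* of the deployed case
  definition, not the behaviour of any particular query tool it originally
  ran on; undocumented tool-level quirks (e.g. how same-day duplicate
  prescriptions were de-duplicated, if at all) cannot be reproduced.
* ICD-10/SNOMED vocabularies, free-text NLP beyond the stated globs, and
  drug dose/duration logic are out of scope.
* The printed confidence-interval recipe could not be identified exactly
  (see above); interval bounds may differ from published ones by a few
  tenths of a percentage point.
* The inter-rater 2×2 table behind a published kappa of 0.88 with 97%
  agreement is not uniquely reconstructible, so kappa is validated against
  its formula and simulations, not against that figure.
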