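Package: pedasthma
Title: Rule-Based Case Finding and Validation for Paediatric Asthma in
    Primary-Care EMR Extracts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a validated operational case definition for
    paediatric asthma over CPCSSN-style electronic medical record extracts:
    ICD-9 code matching (493 and derivatives), free-text diagnosis matching
    with glob-style exclusion of uncertainty notations ("asthma query",
    "?asthma"), an ATC-coded respiratory medication list, and the
    combination rule requiring more than a single prescribed medicine or a
    single medicine plus another criterion.  Also provides the
    diagnostic-validation statistics used to assess such rules against a
    gold-standard chart review (sensitivity, specificity, predictive values
    with exact or score confidence intervals, percent agreement, Cohen's
    kappa, age-stratified reports) and a synthetic-cohort generator with
    known gold labels so the whole pipeline can be exercised without real
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
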