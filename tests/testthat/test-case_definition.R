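test_that("ICD-9 matching is prefix-based on the normalised code", {
  expect_true(match_icd9_asthma("493"))
  expect_true(match_icd9_asthma("493.90"))
  expect_true(match_icd9_asthma("  493.0 "))
  expect_true(match_icd9_asthma("ICD-9: 493.02"))
  expect_false(match_icd9_asthma("496"))
  expect_false(match_icd9_asthma("49"))
  expect_false(match_icd9_asthma(""))
  expect_false(match_icd9_asthma(NA_character_))
  expect_identical(match_icd9_asthma(c("493", "496", "4930")),
                   c(TRUE, FALSE, TRUE))
})

test_that("inclusion matching is token-initial, case-insensitive and punctuation-tolerant", {
  expect_true(match_include_text("asthma"))
  expect_true(match_include_text("Asthmatic bronchitis"))
  expect_true(match_include_text("r/o ASTHMA."))
  expect_true(match_include_text("?asthma"))      # punctuation stripped
  expect_false(match_include_text("gastroesophageal reflux"))
  expect_false(match_include_text("pasthma"))     # not token-initial
  expect_false(match_include_text(""))
  # a pattern without '*' must match a whole token
  expect_true(match_include_text("mild asthma", "asthma"))
  expect_false(match_include_text("asthmatic", "asthma"))
})

test_that("exclusion globs match uncertainty notations whole-field", {
  expect_true(match_exclude_text("asthma query"))
  expect_true(match_exclude_text("query asthma"))
  expect_true(match_exclude_text("?asthma"))
  expect_true(match_exclude_text("asthma?"))
  expect_true(match_exclude_text("Asthma - query"))
  expect_true(match_exclude_text("rule out ? asthma"))
  expect_false(match_exclude_text("asthma"))
  expect_false(match_exclude_text("questionnaire"))
  expect_false(match_exclude_text(""))
  # '?' is the literal character, never a single-character wildcard
  expect_false(match_exclude_text("xasthmax", "?asthma*"))
  expect_true(match_exclude_text("?asthmax", "?asthma*"))
})

test_that("the glob matcher agrees with a regex transliteration oracle", {
  patterns <- case_definition()$text_exclude
  set.seed(4242)
  strings <- c(
    random_glob_strings(10000),
    # adversarial fragments around the pattern vocabulary
    "asthma query", "queryasthma", "asthma?x", "x?asthma", "as thma query",
    "query", "?", "??", "asthmaquery", "q u e r y asthma", "asthma  query"
  )
  got <- match_exclude_text(strings, patterns)
  want <- vapply(strings, oracle_exclude, logical(1),
                 patterns = patterns, USE.NAMES = FALSE)
  expect_identical(got, want)
  # and per-pattern, so multi-pattern ORing cannot mask a disagreement
  for (p in patterns) {
    got1 <- match_exclude_text(strings, p)
    want1 <- vapply(strings, oracle_exclude, logical(1), patterns = p,
                    USE.NAMES = FALSE)
    expect_identical(got1, want1, label = p)
  }
})

test_that("qualifying text is inclusion minus exclusion", {
  expect_true(qualifying_text("asthma"))
  expect_false(qualifying_text("query asthma"))
  expect_false(qualifying_text("asthma query"))
  expect_false(qualifying_text(""))
  expect_identical(qualifying_text(c("asthma", "asthma?", "URTI")),
                   c(TRUE, FALSE, FALSE))
})

test_that("medication matching uses ATC codes with name fallback", {
  expect_true(is_asthma_medication("Ventolin", "R03AC02"))
  expect_true(is_asthma_medication("Atrovent", "R03BB01"))
  expect_true(is_asthma_medication("x", "r03dc03"))     # case-folded code
  expect_false(is_asthma_medication("Tylenol", "N02BE01"))
  # name fallback only when the code is absent
  expect_true(is_asthma_medication("Fluticasone propionate 50mcg", ""))
  expect_true(is_asthma_medication("PREDNISONE 5 mg tab", ""))
  expect_false(is_asthma_medication("Fluticasone propionate", "N02BE01"))
  expect_false(is_asthma_medication("amoxicillin", ""))
  expect_length(case_definition()$atc_codes, 22L)
})

test_that("the combination rule matches an exhaustive independent oracle", {
  config <- case_definition()
  grid <- expand.grid(eligible = c(TRUE, FALSE), b = c(TRUE, FALSE),
                      e = c(TRUE, FALSE), h = c(TRUE, FALSE), k = 0:3)
  got <- classify_case(grid$eligible, grid$b, grid$e, grid$h, grid$k, config)
  want <- mapply(classify_oracle, grid$eligible, grid$b, grid$e, grid$h,
                 grid$k)
  expect_identical(got, unname(want))
  # the diagnosis-only arm flips exactly the zero-script diagnosis rows
  config2 <- case_definition(allow_diagnosis_only = TRUE)
  got2 <- classify_case(grid$eligible, grid$b, grid$e, grid$h, grid$k,
                        config2)
  extra <- grid$eligible & grid$k == 0 & (grid$b | grid$e | grid$h)
  expect_identical(got2, got | extra)
})

test_that("every arm of the rule classifies as documented on the fixture cohort", {
  verdicts <- classify_cohort(rule_arm_cohort())
  got <- setNames(verdicts$is_case, verdicts$patient_id)
  expect_identical(got[names(rule_arm_expected)], rule_arm_expected)
  # the age-gated patient fails only on eligibility
  gate <- verdicts[verdicts$patient_id == "age_gate", ]
  expect_false(gate$eligible_age)
  expect_identical(gate$age_years, 18L)
  expect_true(gate$billing_hit && gate$encounter_hit)
})

test_that("classification is deterministic and covers every patient once", {
  lc <- generate_cohort(cohort_config(n_patients = 300, seed = 99))
  v1 <- classify_cohort(lc$cohort)
  v2 <- classify_cohort(lc$cohort)
  expect_identical(v1, v2)
  expect_identical(sort(v1$patient_id), sort(lc$cohort$patients$patient_id))
  expect_identical(nrow(classify_cohort(emr_cohort())), 0L)
})

test_that("adding qualifying evidence never flips a case to non-case", {
  lc <- generate_cohort(cohort_config(n_patients = 200, seed = 55))
  cohort <- lc$cohort
  before <- classify_cohort(cohort)
  set.seed(56)
  targets <- sample(cohort$patients$patient_id, 40)
  # extra qualifying prescription
  extra_rx <- data.frame(patient_id = targets, date = as.Date("2015-01-05"),
                         drug_name = "Montelukast", atc_code = "R03DC03")
  c2 <- emr_cohort(patients = cohort$patients, billing = cohort$billing,
                   encounters = cohort$encounters,
                   conditions = cohort$conditions,
                   prescriptions = rbind(cohort$prescriptions, extra_rx),
                   reference_date = cohort$reference_date)
  after_rx <- classify_cohort(c2)
  # extra qualifying encounter row
  extra_enc <- data.frame(patient_id = targets, date = as.Date("2015-01-05"),
                          diagnosis_code = "", diagnosis_text = "asthma")
  c3 <- emr_cohort(patients = cohort$patients, billing = cohort$billing,
                   encounters = rbind(cohort$encounters, extra_enc),
                   conditions = cohort$conditions,
                   prescriptions = cohort$prescriptions,
                   reference_date = cohort$reference_date)
  after_enc <- classify_cohort(c3)
  b <- setNames(before$is_case, before$patient_id)
  for (after in list(after_rx, after_enc)) {
    a <- setNames(after$is_case, after$patient_id)
    expect_false(any(b[names(a)] & !a))
  }
})

test_that("an excluded text row never affects other rows' contributions", {
  cohort <- rule_arm_cohort()
  noise <- data.frame(
    patient_id = names(rule_arm_expected),
    date = as.Date("2015-02-02"),
    diagnosis_code = "",
    diagnosis_text = "asthma query"
  )
  c2 <- emr_cohort(patients = cohort$patients, billing = cohort$billing,
                   encounters = rbind(cohort$encounters, noise),
                   conditions = cohort$conditions,
                   prescriptions = cohort$prescriptions,
                   reference_date = cohort$reference_date)
  verdicts <- classify_cohort(c2)
  got <- setNames(verdicts$is_case, verdicts$patient_id)
  expect_identical(got[names(rule_arm_expected)], rule_arm_expected)
})

test_that("prescription count modes collapse duplicates as configured", {
  pts <- data.frame(patient_id = "p", birth_date = "2008-01-01", sex = "M")
  rx <- data.frame(patient_id = "p",
                   date = c("2014-01-01", "2014-01-01", "2014-06-01"),
                   drug_name = "Salbutamol", atc_code = "R03AC02")
  cohort <- emr_cohort(patients = pts, prescriptions = rx)
  count_for <- function(mode) {
    evaluate_criteria(cohort, case_definition(rx_count_mode = mode))$n_prescriptions
  }
  expect_identical(count_for("rows"), 3L)
  expect_identical(count_for("distinct-drug"), 1L)
  expect_identical(count_for("distinct-date"), 2L)
})

test_that("case-definition configs validate and round-trip through YAML", {
  expect_error(case_definition(min_rx_alone = 1), "min_rx_alone")
  expect_error(case_definition(age_min = 10, age_max = 2), "age_min")
  expect_error(case_definition(atc_codes = "BOGUS"), "ATC")
  cd <- case_definition(age_min = 3, rx_count_mode = "distinct-drug")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_case_definition(cd, path)
  expect_identical(read_case_definition(path), cd)
})

test_that("patients with missing birth dates are warned about and ineligible", {
  pts <- data.frame(patient_id = c("ok", "nodob"),
                    birth_date = c("2008-01-01", ""), sex = "F")
  rx <- data.frame(patient_id = c("ok", "ok", "nodob", "nodob"),
                   date = "2014-01-01", drug_name = "Salbutamol",
                   atc_code = "R03AC02")
  cohort <- emr_cohort(patients = pts, prescriptions = rx)
  expect_warning(v <- classify_cohort(cohort), "missing")
  got <- setNames(v$is_case, v$patient_id)
  expect_true(got[["ok"]])
  expect_false(got[["nodob"]])
})
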