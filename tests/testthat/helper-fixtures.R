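# Shared fixtures and independent oracles, built in code at test time.

# Hand-built cohort covering every arm of the combination rule:
#   rule_two_rx        : two reliever scripts, no diagnosis rows  -> case
#   rule_one_rx_bill   : one script + billing 493                 -> case
#   rule_one_rx_enc    : one script + encounter text "asthma"     -> case
#   rule_one_rx_cond   : one script + problem-list text           -> case
#   excluded_only      : "asthma query" encounter, no scripts     -> non-case
#   dx_only_no_rx      : billing 493 only, zero scripts           -> non-case
#   age_gate           : full criteria but age 18                 -> non-case
rule_arm_cohort <- function(reference_date = as.Date("2015-06-30")) {
  sal <- function(id, k) {
    data.frame(patient_id = id,
               date = as.Date("2014-03-01") + seq_len(k),
               drug_name = "Salbutamol", atc_code = "R03AC02")
  }
  patients <- data.frame(
    patient_id = c("rule_two_rx", "rule_one_rx_bill", "rule_one_rx_enc",
                   "rule_one_rx_cond", "excluded_only", "dx_only_no_rx",
                   "age_gate"),
    birth_date = c("2010-01-15", "2007-05-02", "2006-11-30", "2004-07-07",
                   "2009-02-10", "2003-09-21", "1997-06-30"),
    sex = c("M", "F", "M", "F", "M", "F", "M")
  )
  billing <- data.frame(
    patient_id = c("rule_one_rx_bill", "dx_only_no_rx", "age_gate"),
    date = "2014-01-10",
    diagnosis_code = c("493", "493.90", "493")
  )
  encounters <- data.frame(
    patient_id = c("rule_one_rx_enc", "excluded_only", "age_gate"),
    date = "2014-02-20",
    diagnosis_code = "",
    diagnosis_text = c("asthma", "asthma query", "asthma")
  )
  conditions <- data.frame(
    patient_id = "rule_one_rx_cond",
    date_onset = "2013-06-01",
    condition_code = "",
    condition_text = "Asthmatic bronchitis"
  )
  prescriptions <- rbind(
    sal("rule_two_rx", 2), sal("rule_one_rx_bill", 1),
    sal("rule_one_rx_enc", 1), sal("rule_one_rx_cond", 1),
    sal("age_gate", 3)
  )
  emr_cohort(patients = patients, billing = billing, encounters = encounters,
             conditions = conditions, prescriptions = prescriptions,
             reference_date = reference_date)
}

rule_arm_expected <- c(
  rule_two_rx = TRUE, rule_one_rx_bill = TRUE, rule_one_rx_enc = TRUE,
  rule_one_rx_cond = TRUE, excluded_only = FALSE, dx_only_no_rx = FALSE,
  age_gate = FALSE
)

# Independent regex transliteration of the exclusion glob semantics:
# '*' -> '.*', every other character (including '?') is a literal, whole
# string anchored. Deliberately a different mechanism from the package's
# segment-scanning matcher.
glob_to_regex <- function(pattern) {
  metas <- c(".", "\\", "+", "?", "^", "$", "[", "]", "(", ")", "{", "}", "|")
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  out <- vapply(chars, function(ch) {
    if (ch == "*") ".*" else if (ch %in% metas) paste0("\\", ch) else ch
  }, character(1))
  paste0("^", paste(out, collapse = ""), "$")
}

oracle_exclude <- function(text, patterns) {
  text <- tolower(trimws(gsub("[[:space:]]+", " ", text)))
  if (!nzchar(text)) return(FALSE)
  any(vapply(patterns, function(p) {
    grepl(glob_to_regex(tolower(p)), text)
  }, logical(1)))
}

# random strings over a small alphabet rich in the matcher's corner
# characters
random_glob_strings <- function(n, max_len = 12) {
  alphabet <- c("a", "s", "t", "h", "m", "q", "u", "e", "r", "y",
                "?", " ", ".", "x")
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample.int(max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

# independently written boolean oracle for the combination rule
classify_oracle <- function(eligible, b, e, h, k) {
  if (!eligible) return(FALSE)
  if (k >= 2) return(TRUE)
  if (k >= 1 && (b || e || h)) return(TRUE)
  FALSE
}

# label vectors engineered to produce given confusion counts
labels_for_counts <- function(tp, fp, tn, fn, prefix = "p") {
  n <- tp + fp + tn + fn
  ids <- sprintf("%s%05d", prefix, seq_len(n))
  gold <- c(rep(TRUE, tp), rep(FALSE, fp), rep(FALSE, tn), rep(TRUE, fn))
  alg <- c(rep(TRUE, tp), rep(TRUE, fp), rep(FALSE, tn), rep(FALSE, fn))
  list(algorithm = setNames(alg, ids), gold = setNames(gold, ids))
}
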