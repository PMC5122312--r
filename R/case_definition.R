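# The operational case definition for paediatric asthma: any occurrence of
# ICD-9 493 (and derivatives) in billing, encounter diagnosis or health
# condition entries; any free-text occurrence of "asth*" in encounter or
# condition text, excluding uncertainty notations ("asthma query", "?asthma",
# "asthma?"); a list of 22 ATC-coded respiratory/systemic-steroid
# medications; and the combination rule: a patient aged 1-17 is a case with
# more than a single qualifying prescribed medicine, or a single qualifying
# medicine plus at least one other criterion.

# Table of qualifying medications: inhaled corticosteroids, ICS/LABA
# combinations, short- and long-acting beta-agonists, leukotriene receptor
# antagonists, systemic corticosteroids, ipratropium.
ASTHMA_MEDICATIONS <- data.frame(
  drug_name = c(
    "Beclomethasone", "Budesonide", "Fluticasone", "Triamcinolone",
    "Mometasone", "Ciclesonide",
    "Salmeterol and fluticasone", "Formoterol and budesonide",
    "Formoterol and beclometasone", "Formoterol and mometasone",
    "Salbutamol", "Terbutaline", "Fenoterol", "Salmeterol", "Formoterol",
    "Indacaterol", "Zafirlukast", "Montelukast",
    "Dexamethasone", "Prednisolone", "Prednisone", "Ipratropium bromide"
  ),
  atc_code = c(
    "R03BA01", "R03BA02", "R03BA05", "R03BA06",
    "R03BA07", "R03BA08",
    "R03AK06", "R03AK07",
    "R03AK08", "R03AK09",
    "R03AC02", "R03AC03", "R03AC04", "R03AC12", "R03AC13",
    "R03AC18", "R03DC01", "R03DC03",
    "H02AB02", "H02AB06", "H02AB07", "R03BB01"
  ),
  stringsAsFactors = FALSE
)

default_drug_name_keys <- function() {
  # single-agent names for fallback matching when a prescription row has no
  # ATC code; combination products contain a component name as a substring
  keys <- tolower(ASTHMA_MEDICATIONS$drug_name)
  keys <- unique(unlist(strsplit(keys, " and ", fixed = TRUE)))
  sort(keys)
}

#' Case-definition configuration
#'
#' Bundles every tunable element of the asthma case definition with its
#' operational defaults: the ICD-9 prefix (`"493"`, matching 493 and all its
#' derivative sub-codes), the free-text inclusion pattern (`"asth*"`, a
#' token-initial prefix), the four exclusion globs targeting query/uncertainty
#' notations, the 22-entry qualifying medication list (ATC codes plus drug
#' names for rows lacking a code), the eligible age band (1-17 completed
#' years inclusive), and the two prescription-count thresholds of the
#' combination rule.
#'
#' @param icd9_prefix diagnosis-code prefix defining an asthma code.
#' @param text_include character vector of inclusion patterns; a trailing
#'   `*` makes the pattern a token-initial prefix, otherwise a whole token
#'   must match.
#' @param text_exclude character vector of exclusion globs applied to the
#'   whole (whitespace-normalised, case-folded) text field; `*` matches any
#'   character sequence and `?` is the literal question mark.
#' @param atc_codes qualifying ATC codes (7-character shape).
#' @param drug_names lowercase drug-name substrings used only when a
#'   prescription row carries no ATC code.
#' @param age_min,age_max eligible completed-age band, inclusive.
#' @param min_rx_alone qualifying prescriptions sufficient on their own
#'   (default 2: "more than a single prescribed medicine").
#' @param min_rx_with_criterion qualifying prescriptions sufficient together
#'   with at least one diagnosis criterion (default 1).
#' @param rx_count_mode how prescription occurrences are counted: `"rows"`
#'   (every prescription row; the default reading), `"distinct-drug"`
#'   (distinct molecules) or `"distinct-date"` (distinct prescription dates),
#'   for sensitivity analyses.
#' @param allow_diagnosis_only if `TRUE`, a patient with a qualifying
#'   diagnosis criterion but no qualifying prescription is also a case
#'   (exploratory arm; default `FALSE`, the literal combination rule).
#' @return an object of class `case_definition`.
#' @examples
#' cd <- case_definition()
#' cd$atc_codes[1:4]
#' @export
case_definition <- function(icd9_prefix = "493",
                            text_include = "asth*",
                            text_exclude = c("*asthma*query*", "*query*asthma*",
                                             "*asthma*?*", "*?*asthma*"),
                            atc_codes = ASTHMA_MEDICATIONS$atc_code,
                            drug_names = default_drug_name_keys(),
                            age_min = 1L,
                            age_max = 17L,
                            min_rx_alone = 2L,
                            min_rx_with_criterion = 1L,
                            rx_count_mode = c("rows", "distinct-drug",
                                              "distinct-date"),
                            allow_diagnosis_only = FALSE) {
  rx_count_mode <- match.arg(rx_count_mode)
  atc_codes <- toupper(trimws(atc_codes))
  bad <- !grepl(ATC_SHAPE, atc_codes)
  if (any(bad)) {
    stop_input("invalid ATC code in configuration: '%s'", atc_codes[bad][1])
  }
  age_min <- as.integer(age_min); age_max <- as.integer(age_max)
  if (is.na(age_min) || is.na(age_max) || age_min > age_max) {
    stop_input("age_min must be <= age_max")
  }
  min_rx_alone <- as.integer(min_rx_alone)
  min_rx_with_criterion <- as.integer(min_rx_with_criterion)
  if (min_rx_with_criterion < 1L || min_rx_alone <= min_rx_with_criterion) {
    stop_input("need min_rx_alone > min_rx_with_criterion >= 1")
  }
  structure(
    list(
      icd9_prefix = as.character(icd9_prefix),
      text_include = as.character(text_include),
      text_exclude = as.character(text_exclude),
      atc_codes = atc_codes,
      drug_names = tolower(as.character(drug_names)),
      age_min = age_min, age_max = age_max,
      min_rx_alone = min_rx_alone,
      min_rx_with_criterion = min_rx_with_criterion,
      rx_count_mode = rx_count_mode,
      allow_diagnosis_only = isTRUE(allow_diagnosis_only)
    ),
    class = "case_definition"
  )
}

#' @export
print.case_definition <- function(x, ...) {
  cat("<case_definition>\n")
  cat(sprintf("  ICD-9 prefix: %s   ages: %d-%d (completed years)\n",
              x$icd9_prefix, x$age_min, x$age_max))
  cat(sprintf("  include text: %s\n", paste(x$text_include, collapse = " ")))
  cat(sprintf("  exclude text: %s\n", paste(x$text_exclude, collapse = " ")))
  cat(sprintf("  medications: %d ATC codes (+%d name keys), counted by %s\n",
              length(x$atc_codes), length(x$drug_names), x$rx_count_mode))
  cat(sprintf("  rule: >= %d scripts alone, or >= %d with another criterion%s\n",
              x$min_rx_alone, x$min_rx_with_criterion,
              if (x$allow_diagnosis_only) " (diagnosis-only arm enabled)" else ""))
  invisible(x)
}

#' Read or write a case definition as a YAML config file
#'
#' @param path file path.
#' @param config a `case_definition`.
#' @return `read_case_definition` returns a `case_definition`.
#' @export
read_case_definition <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(case_definition))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown)) {
    stop_input("unknown case-definition key(s): %s",
               paste(unknown, collapse = ", "))
  }
  do.call(case_definition, vals)
}

#' @rdname read_case_definition
#' @export
write_case_definition <- function(config, path) {
  stopifnot(inherits(config, "case_definition"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Match an ICD-9 code against the asthma rubric
#'
#' A code matches when, after trimming whitespace and stripping a leading
#' "ICD-9:"-style tag, it begins with the configured prefix; "493", "493.0"
#' and "493.90" all match the default prefix (493 and derivatives).
#' Vectorised; empty codes never match.
#'
#' @param code character vector of diagnosis codes.
#' @param prefix code prefix (default `"493"`).
#' @return logical vector.
#' @examples
#' match_icd9_asthma(c("493", "493.90", "496"))
#' @export
match_icd9_asthma <- function(code, prefix = "493") {
  code <- as.character(code)
  code[is.na(code)] <- ""
  code <- trimws(code)
  code <- sub("^[Ii][Cc][Dd][ -]?9?[ ]*[.:][ ]*", "", code)
  code <- trimws(code)
  nzchar(code) & startsWith(code, prefix)
}

# -- glob matching ------------------------------------------------------------
# '*' matches any (possibly empty) character sequence; every other character,
# including '?', is literal; the pattern must cover the whole string.
# Implemented by anchored segment scanning rather than regex translation so
# the test suite can check it against an independent regex oracle.
glob_match_one <- function(text, pattern) {
  if (!grepl("*", pattern, fixed = TRUE)) return(identical(text, pattern))
  leading <- startsWith(pattern, "*")
  trailing <- endsWith(pattern, "*")
  segs <- strsplit(pattern, "*", fixed = TRUE)[[1]]
  segs <- segs[nzchar(segs)]
  if (!length(segs)) return(TRUE)          # pattern is all stars
  # anchor the first segment at the start when the pattern has no leading '*'
  if (!leading) {
    first <- segs[1]
    if (substr(text, 1L, nchar(first)) != first) return(FALSE)
    text <- substr(text, nchar(first) + 1L, nchar(text))
    segs <- segs[-1]
  }
  # anchor the last segment at the end when the pattern has no trailing '*'
  if (!trailing && length(segs)) {
    last <- segs[length(segs)]
    if (nchar(text) < nchar(last)) return(FALSE)
    tail_part <- substr(text, nchar(text) - nchar(last) + 1L, nchar(text))
    if (tail_part != last) return(FALSE)
    text <- substr(text, 1L, nchar(text) - nchar(last))
    segs <- segs[-length(segs)]
  }
  # remaining segments float: greedy leftmost search in order
  pos <- 1L
  for (seg in segs) {
    if (pos > nchar(text) + 1L) return(FALSE)
    hit <- regexpr(seg, substr(text, pos, nchar(text)), fixed = TRUE)
    if (hit < 0L) return(FALSE)
    pos <- pos + as.integer(hit) - 1L + nchar(seg)
  }
  TRUE
}

#' Free-text inclusion match
#'
#' Case-insensitive token matching: the text is split on whitespace,
#' punctuation adjacent to each token is stripped, and a pattern with a
#' trailing `*` (e.g. `"asth*"`) matches any token beginning with its literal
#' prefix; a pattern without `*` must equal a whole token. Empty text never
#' matches.
#'
#' @param text character vector of free-text fields.
#' @param patterns inclusion patterns (default `"asth*"`).
#' @return logical vector.
#' @examples
#' match_include_text(c("Asthmatic bronchitis", "gastroesophageal reflux"))
#' @export
match_include_text <- function(text, patterns = "asth*") {
  text <- normalize_text(text)
  pats <- normalize_text(patterns)
  prefix <- endsWith(pats, "*")
  keys <- sub("\\*$", "", pats)
  vapply(text, function(t) {
    if (!nzchar(t)) return(FALSE)
    tokens <- strsplit(t, " ", fixed = TRUE)[[1]]
    tokens <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", tokens)
    tokens <- tokens[nzchar(tokens)]
    if (!length(tokens)) return(FALSE)
    for (i in seq_along(keys)) {
      hit <- if (prefix[i]) any(startsWith(tokens, keys[i]))
             else any(tokens == keys[i])
      if (hit) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}

#' Free-text exclusion match
#'
#' Whole-field, case-insensitive glob matching (after collapsing whitespace
#' runs): `*` matches any character sequence, `?` is the literal question
#' mark. The default patterns exclude query/uncertainty notations such as
#' "asthma query", "query asthma", "asthma?" and "?asthma". Empty text never
#' matches.
#'
#' @param text character vector of free-text fields.
#' @param patterns exclusion globs.
#' @return logical vector.
#' @examples
#' match_exclude_text(c("asthma query", "?asthma", "asthma"))
#' @export
match_exclude_text <- function(text,
                               patterns = case_definition()$text_exclude) {
  text <- normalize_text(text)
  pats <- normalize_text(patterns)
  vapply(text, function(t) {
    if (!nzchar(t)) return(FALSE)
    for (p in pats) if (glob_match_one(t, p)) return(TRUE)
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}

#' Does a free-text field qualify as an asthma criterion?
#'
#' True when the inclusion pattern matches and no exclusion pattern does:
#' any occurrence of "asthma" counts, any occurrence of "asthma query" (and
#' its variants) does not.
#'
#' @param text character vector.
#' @param config a [case_definition()].
#' @return logical vector.
#' @examples
#' qualifying_text(c("asthma", "query asthma", ""))
#' @export
qualifying_text <- function(text, config = case_definition()) {
  match_include_text(text, config$text_include) &
    !match_exclude_text(text, config$text_exclude)
}

#' Is a prescription a qualifying asthma medication?
#'
#' A prescription qualifies when its uppercased ATC code is on the
#' configured list, or -- only when the ATC code is empty -- its lowercased
#' drug name contains one of the configured name keys.
#'
#' @param drug_name character vector of free-text drug names.
#' @param atc_code character vector of ATC codes (may be empty strings).
#' @param config a [case_definition()].
#' @return logical vector.
#' @examples
#' is_asthma_medication("Ventolin", "R03AC02")
#' is_asthma_medication("Fluticasone propionate 50mcg", "")
#' @export
is_asthma_medication <- function(drug_name, atc_code,
                                 config = case_definition()) {
  atc <- toupper(trimws(ifelse(is.na(atc_code), "", as.character(atc_code))))
  name <- normalize_text(drug_name)
  by_code <- atc %in% config$atc_codes
  no_code <- !nzchar(atc)
  by_name <- rep(FALSE, length(name))
  if (any(no_code) && length(config$drug_names)) {
    pat <- paste(config$drug_names, collapse = "|")
    by_name[no_code] <- grepl(pat, name[no_code])
  }
  by_code | by_name
}

#' Apply the combination rule
#'
#' The classification rule over an evaluated criteria profile: an
#' age-eligible patient is a case with at least `min_rx_alone` qualifying
#' prescriptions, or at least `min_rx_with_criterion` qualifying
#' prescriptions together with at least one diagnosis criterion (billing,
#' encounter diagnosis or health condition). All arguments are vectorised.
#'
#' @param eligible_age logical; within the configured age band.
#' @param billing_hit,encounter_hit,condition_hit logical criterion flags.
#' @param n_prescriptions integer count of qualifying prescriptions.
#' @param config a [case_definition()].
#' @return logical case verdicts.
#' @examples
#' classify_case(TRUE, FALSE, FALSE, FALSE, 2)  # two scripts alone
#' classify_case(TRUE, TRUE, FALSE, FALSE, 1)   # one script plus billing
#' classify_case(TRUE, TRUE, TRUE, TRUE, 0)     # no script: not a case
#' @export
classify_case <- function(eligible_age, billing_hit, encounter_hit,
                          condition_hit, n_prescriptions,
                          config = case_definition()) {
  any_criterion <- billing_hit | encounter_hit | condition_hit
  meets <- n_prescriptions >= config$min_rx_alone |
    (n_prescriptions >= config$min_rx_with_criterion & any_criterion)
  if (config$allow_diagnosis_only) meets <- meets | any_criterion
  as.logical(eligible_age & meets)
}

#' Evaluate the case-definition criteria for every patient
#'
#' Computes one criteria profile per patient: completed age at the cohort
#' reference date and eligibility; whether any billing code, encounter entry
#' (code or qualifying text) or health-condition entry matches; and the
#' number of qualifying prescriptions. Billing is code-only; the text
#' exclusion patterns apply to encounter and condition free text. Patients
#' with a missing birth date are flagged ineligible with a warning.
#'
#' @param cohort an [emr_cohort()].
#' @param config a [case_definition()].
#' @return data frame with one row per patient: `patient_id`, `age_years`,
#'   `eligible_age`, `billing_hit`, `encounter_hit`, `condition_hit`,
#'   `n_prescriptions`.
#' @export
evaluate_criteria <- function(cohort, config = case_definition()) {
  stopifnot(inherits(cohort, "emr_cohort"), inherits(config, "case_definition"))
  ids <- cohort$patients$patient_id
  age <- age_in_years(cohort$patients$birth_date, cohort$reference_date)
  if (anyNA(age)) {
    warning(sprintf(
      "%d patient(s) with missing/unparseable birth_date treated as ineligible",
      sum(is.na(age))), call. = FALSE)
  }
  eligible <- !is.na(age) & age >= config$age_min & age <= config$age_max

  hit_ids <- function(df, hit) unique(df$patient_id[hit])

  b_hits <- hit_ids(cohort$billing,
                    match_icd9_asthma(cohort$billing$diagnosis_code,
                                      config$icd9_prefix))
  e <- cohort$encounters
  e_row <- match_icd9_asthma(e$diagnosis_code, config$icd9_prefix) |
    qualifying_text(e$diagnosis_text, config)
  e_hits <- hit_ids(e, e_row)
  h <- cohort$conditions
  h_row <- match_icd9_asthma(h$condition_code, config$icd9_prefix) |
    qualifying_text(h$condition_text, config)
  h_hits <- hit_ids(h, h_row)

  rx <- cohort$prescriptions
  rx_q <- is_asthma_medication(rx$drug_name, rx$atc_code, config)
  rxq <- rx[rx_q, , drop = FALSE]
  n_rx <- integer(length(ids))
  names(n_rx) <- ids
  if (nrow(rxq)) {
    counts <- switch(config$rx_count_mode,
      "rows" = table(rxq$patient_id),
      "distinct-drug" = {
        key <- ifelse(nzchar(trimws(rxq$atc_code)),
                      toupper(trimws(rxq$atc_code)),
                      normalize_text(rxq$drug_name))
        table(unique(data.frame(id = rxq$patient_id, key = key))$id)
      },
      "distinct-date" = {
        table(unique(data.frame(id = rxq$patient_id,
                                d = as.character(rxq$date)))$id)
      }
    )
    n_rx[names(counts)] <- as.integer(counts)
  }

  data.frame(
    patient_id = ids,
    age_years = age,
    eligible_age = eligible,
    billing_hit = ids %in% b_hits,
    encounter_hit = ids %in% e_hits,
    condition_hit = ids %in% h_hits,
    n_prescriptions = unname(n_rx),
    stringsAsFactors = FALSE
  )
}

#' Classify every patient in a cohort
#'
#' Evaluates the criteria profiles and applies the combination rule,
#' returning one verdict per patient. Deterministic given the cohort and
#' configuration.
#'
#' @inheritParams evaluate_criteria
#' @return data frame: `patient_id`, `is_case`, `age_years`, `eligible_age`,
#'   `billing_hit`, `encounter_hit`, `condition_hit`, `n_prescriptions`.
#' @examples
#' cohort <- emr_cohort(
#'   patients = data.frame(patient_id = "p1", birth_date = "2007-01-15",
#'                         sex = "M"),
#'   encounters = data.frame(patient_id = "p1", date = "2014-05-02",
#'                           diagnosis_code = "", diagnosis_text = "asthma"),
#'   prescriptions = data.frame(patient_id = "p1", date = "2014-05-02",
#'                              drug_name = "Salbutamol", atc_code = "R03AC02")
#' )
#' classify_cohort(cohort)
#' @export
classify_cohort <- function(cohort, config = case_definition()) {
  prof <- evaluate_criteria(cohort, config)
  prof$is_case <- classify_case(prof$eligible_age, prof$billing_hit,
                                prof$encounter_hit, prof$condition_hit,
                                prof$n_prescriptions, config)
  prof[, c("patient_id", "is_case", "age_years", "eligible_age",
           "billing_hit", "encounter_hit", "condition_hit",
           "n_prescriptions")]
}

#' Read or write a classification table
#'
#' The classification output travels as delimited text with columns
#' `patient_id,is_case,age_years,billing_hit,encounter_hit,condition_hit,
#' n_prescriptions` (logicals coded 1/0).
#'
#' @param classification data frame from [classify_cohort()].
#' @param path file path.
#' @export
write_classification <- function(classification, path) {
  out <- classification
  for (col in c("is_case", "eligible_age", "billing_hit", "encounter_hit",
                "condition_hit")) {
    if (col %in% names(out)) out[[col]] <- as.integer(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_classification
#' @export
read_classification <- function(path) {
  if (!file.exists(path)) stop_input("classification file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = "", fileEncoding = "UTF-8")
  if (!all(c("patient_id", "is_case") %in% names(df))) {
    stop_input("file %s: expected at least columns patient_id, is_case", path)
  }
  df$is_case <- df$is_case == "1"
  for (col in c("eligible_age", "billing_hit", "encounter_hit",
                "condition_hit")) {
    if (col %in% names(df)) df[[col]] <- df[[col]] == "1"
  }
  for (col in c("age_years", "n_prescriptions")) {
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  }
  df
}
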