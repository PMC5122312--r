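# Synthetic CPCSSN-like cohorts with known gold-standard labels. Records are
# generated from per-arm documentation profiles (diagnosis-code rows, free
# text including capitalisation/punctuation variants and the query/uncertainty
# exclusion shapes, ATC-coded prescriptions), so the matcher's corner cases
# are exercised by default. An optional calibrated mode makes the classifier's
# expected sensitivity/specificity equal chosen targets exactly.

# text pools: inclusion variants, exclusion (uncertainty) variants, and
# benign respiratory/other labels that must never match
SYN_INCLUDE_TEXTS <- c(
  "asthma", "Asthma", "ASTHMA", "asthmatic bronchitis",
  "Asthma, mild intermittent", "asthma exacerbation", "allergic asthma"
)
SYN_EXCLUDE_TEXTS <- c(
  "asthma query", "query asthma", "?asthma", "asthma?",
  "Asthma - query", "query re asthma", "asthma ?"
)
SYN_BENIGN_TEXTS <- c(
  "acute bronchitis", "URTI", "otitis media",
  "gastroesophageal reflux", "croup", "bronchiolitis"
)
SYN_ICD9_VARIANTS <- c("493", "493.0", "493.9", "493.90", "493.02")
SYN_RELIEVER_POOL <- c("Salbutamol", "Terbutaline")

default_case_profile <- function() {
  list(
    p_billing = 0.50,        # probability of >=1 billing 493 row
    p_encounter = 0.75,      # probability of >=1 encounter diagnosis row
    p_condition = 0.50,      # probability of >=1 problem-list row
    p_text_given_row = 0.70, # diagnosis row carries free text (vs ICD-9 code)
    rx_dist = c("0" = 0.06, "1" = 0.14, "2" = 0.40, "3" = 0.25, "4" = 0.15)
  )
}

default_control_profile <- function() {
  list(
    p_excluded_text = 0.05, # "asthma query"/"?asthma"-style uncertainty rows
    p_benign_text = 0.15,   # concurrent labels such as "acute bronchitis"
    p_code = 0.004,         # stray 493 billing rows (documentation error)
    rx_dist = c("0" = 0.90, "1" = 0.09, "2" = 0.01) # lone-reliever tail
  )
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_patients number of patients to generate.
#' @param prevalence gold-positive proportion (default 0.143, the
#'   chart-review case prevalence in a 1000-record paediatric sample).
#' @param age_low,age_high completed-age range, sampled uniformly (default
#'   1-17).
#' @param seed integer seed; the run is fully determined by it.
#' @param case_profile documentation probabilities for gold-positives:
#'   `p_billing`, `p_encounter`, `p_condition`, `p_text_given_row` and the
#'   prescription-count distribution `rx_dist` (named by count, sums to 1).
#' @param control_profile generation probabilities for gold-negatives:
#'   `p_excluded_text`, `p_benign_text`, `p_code` and `rx_dist`.
#' @param target_sensitivity,target_specificity optional; when both set the
#'   profiles are overridden by a calibrated mixture of
#'   guaranteed-qualifying and guaranteed-sub-threshold records so the
#'   classifier's expected sensitivity/specificity (under the default
#'   [case_definition()]) equal the targets.
#' @param suspected_rate fraction of gold-positives flagged "suspected":
#'   very young (1-2 years) patients with sparse records, still
#'   gold-positive. In calibrated mode these are drawn from the
#'   sub-threshold arm so the calibration stays exact.
#' @param reference_date cohort reference date.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 1000,
                          prevalence = 0.143,
                          age_low = 1L, age_high = 17L,
                          seed = NULL,
                          case_profile = default_case_profile(),
                          control_profile = default_control_profile(),
                          target_sensitivity = NULL,
                          target_specificity = NULL,
                          suspected_rate = 0.06,
                          reference_date = DEFAULT_REFERENCE_DATE) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 0) stop_input("n_patients must be >= 0")
  check_prob <- function(p, what) {
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      stop_input("%s must be a probability in [0, 1]", what)
    }
  }
  check_prob(prevalence, "prevalence")
  check_prob(suspected_rate, "suspected_rate")
  check_dist <- function(d, what) {
    if (is.null(names(d)) || anyNA(suppressWarnings(as.integer(names(d))))) {
      stop_input("%s$rx_dist must be named by prescription count", what)
    }
    if (any(d < 0) || abs(sum(d) - 1) > 1e-8) {
      stop_input("%s$rx_dist must be a distribution summing to 1", what)
    }
  }
  for (p in c("p_billing", "p_encounter", "p_condition", "p_text_given_row")) {
    check_prob(case_profile[[p]], paste0("case_profile$", p))
  }
  check_dist(case_profile$rx_dist, "case_profile")
  for (p in c("p_excluded_text", "p_benign_text", "p_code")) {
    check_prob(control_profile[[p]], paste0("control_profile$", p))
  }
  check_dist(control_profile$rx_dist, "control_profile")
  if (xor(is.null(target_sensitivity), is.null(target_specificity))) {
    stop_input("set both target_sensitivity and target_specificity, or neither")
  }
  if (!is.null(target_sensitivity)) {
    check_prob(target_sensitivity, "target_sensitivity")
    check_prob(target_specificity, "target_specificity")
  }
  age_low <- as.integer(age_low); age_high <- as.integer(age_high)
  if (age_low > age_high || age_low < 0) stop_input("need 0 <= age_low <= age_high")
  structure(
    list(n_patients = n_patients, prevalence = prevalence,
         age_low = age_low, age_high = age_high,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         case_profile = case_profile, control_profile = control_profile,
         target_sensitivity = target_sensitivity,
         target_specificity = target_specificity,
         suspected_rate = suspected_rate,
         reference_date = as_reference_date(reference_date)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> n = %d, prevalence = %.3f, ages %d-%d, seed = %s\n",
              x$n_patients, x$prevalence, x$age_low, x$age_high,
              x$seed %||% "<unset>"))
  if (!is.null(x$target_sensitivity)) {
    cat(sprintf("  calibrated to sensitivity %.3f / specificity %.3f\n",
                x$target_sensitivity, x$target_specificity))
  }
  invisible(x)
}

#' Calibrate a generator configuration to an operating point
#'
#' Returns a copy of `base_config` whose generative mixture gives the
#' default classifier an expected per-patient true-positive probability of
#' `target_sensitivity` among gold-positives and false-positive probability
#' of `1 - target_specificity` among gold-negatives: each gold-positive is
#' generated fully qualifying with probability `target_sensitivity` and
#' sub-threshold otherwise, and symmetrically for gold-negatives.
#'
#' @param target_sensitivity,target_specificity proportions in \[0, 1\].
#' @param base_config a [cohort_config()] to start from.
#' @return a `cohort_config` with the targets set.
#' @export
calibrate_profiles <- function(target_sensitivity, target_specificity,
                               base_config = cohort_config()) {
  stopifnot(inherits(base_config, "cohort_config"))
  cfg <- base_config
  cfg$target_sensitivity <- target_sensitivity
  cfg$target_specificity <- target_specificity
  # revalidate through the constructor
  do.call(cohort_config, cfg[names(cfg) != "class"])
}

#' Read or write a cohort configuration as YAML
#'
#' @param path file path.
#' @param config a `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(cohort_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown)) {
    stop_input("unknown cohort-config key(s): %s",
               paste(unknown, collapse = ", "))
  }
  for (prof in c("case_profile", "control_profile")) {
    if (!is.null(vals[[prof]]$rx_dist)) {
      vals[[prof]]$rx_dist <- unlist(vals[[prof]]$rx_dist)
    }
  }
  do.call(cohort_config, vals)
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  out <- unclass(config)
  out$reference_date <- format(out$reference_date, "%Y-%m-%d")
  out$case_profile$rx_dist <- as.list(config$case_profile$rx_dist)
  out$control_profile$rx_dist <- as.list(config$control_profile$rx_dist)
  yaml::write_yaml(out, path)
  invisible(path)
}

sample_counts <- function(n, dist) {
  if (n == 0L) return(integer(0))
  vals <- as.integer(names(dist))
  vals[sample.int(length(vals), n, replace = TRUE, prob = dist)]
}

random_dates <- function(n, reference_date, span_days = 1095L) {
  reference_date - sample.int(span_days, n, replace = TRUE)
}

# Generate a synthetic cohort with known gold labels.
#
# Internal worker for generate_cohort(); operates on already-validated
# config with RNG state managed by the caller.
generate_impl <- function(config) {
  n <- config$n_patients
  ref <- config$reference_date
  ids <- sprintf("P%06d", seq_len(n))
  if (n == 0L) {
    return(list(
      cohort = emr_cohort(reference_date = ref),
      gold = setNames(logical(0), character(0)),
      suspected = setNames(logical(0), character(0))
    ))
  }
  gold <- stats::rbinom(n, 1L, config$prevalence) == 1L
  ages <- sample(seq(config$age_low, config$age_high), n, replace = TRUE)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  suspected <- rep(FALSE, n)

  calibrated <- !is.null(config$target_sensitivity)
  cp <- config$case_profile
  ctl <- config$control_profile

  # per-patient generation plan
  has_billing <- rep(FALSE, n)
  enc_kind <- rep("none", n)   # none | include_text | code | excluded_text | benign_text
  cond_kind <- rep("none", n)
  n_rx <- integer(n)
  rx_pool <- rep("any", n)     # any | reliever

  pos <- which(gold)
  neg <- which(!gold)

  plan_documented <- function(idx, force_qualifying = FALSE) {
    m <- length(idx)
    if (!m) return()
    has_billing[idx] <<- stats::runif(m) < cp$p_billing
    has_enc <- stats::runif(m) < cp$p_encounter
    has_cond <- stats::runif(m) < cp$p_condition
    k <- sample_counts(m, cp$rx_dist)
    if (force_qualifying) {
      # redraw zero-count patients from the >=1 part of the distribution,
      # and give single-script patients a qualifying encounter row
      dist1 <- cp$rx_dist[as.integer(names(cp$rx_dist)) >= 1L]
      zero <- k == 0L
      if (any(zero)) k[zero] <- sample_counts(sum(zero), dist1 / sum(dist1))
      has_enc[k == 1L] <- TRUE
    }
    enc_kind[idx] <<- ifelse(has_enc,
      ifelse(stats::runif(m) < cp$p_text_given_row, "include_text", "code"),
      "none")
    cond_kind[idx] <<- ifelse(has_cond,
      ifelse(stats::runif(m) < cp$p_text_given_row, "include_text", "code"),
      "none")
    n_rx[idx] <<- k
  }

  plan_subthreshold <- function(idx) {
    # gold-positives whose documentation never meets the rule: at most one
    # prescription, and a single script is never paired with a criterion
    m <- length(idx)
    if (!m) return()
    k <- ifelse(stats::runif(m) < 0.6, 0L, 1L)
    u <- stats::runif(m)
    enc_kind[idx] <<- ifelse(
      k == 0L & u < 0.5, "include_text",        # diagnosis-only record
      ifelse(u < 0.75, "excluded_text", "none") # uncertainty note or nothing
    )
    has_billing[idx] <<- FALSE
    cond_kind[idx] <<- "none"
    n_rx[idx] <<- k
    rx_pool[idx] <<- "reliever"
  }

  plan_control <- function(idx, allow_qualifying = TRUE) {
    m <- length(idx)
    if (!m) return()
    u1 <- stats::runif(m)
    enc_kind[idx] <<- ifelse(u1 < ctl$p_excluded_text, "excluded_text",
                      ifelse(u1 < ctl$p_excluded_text + ctl$p_benign_text,
                             "benign_text", "none"))
    has_billing[idx] <<- allow_qualifying & (stats::runif(m) < ctl$p_code)
    k <- sample_counts(m, ctl$rx_dist)
    if (!allow_qualifying) {
      k <- pmin(k, 1L)
      # a lone script must not combine with a stray 493 row into a case
      has_billing[idx] <<- FALSE
    }
    n_rx[idx] <<- k
    rx_pool[idx] <<- "reliever"
  }

  plan_false_positive <- function(idx) {
    # symptomatic child without an asthma label: repeated reliever scripts
    m <- length(idx)
    if (!m) return()
    two_scripts <- stats::runif(m) < 0.7
    n_rx[idx] <<- ifelse(two_scripts, 2L, 1L)
    has_billing[idx] <<- !two_scripts  # one script + stray 493 billing row
    rx_pool[idx] <<- "reliever"
    benign <- stats::runif(m) < ctl$p_benign_text
    enc_kind[idx] <<- ifelse(benign, "benign_text", "none")
  }

  if (calibrated) {
    doc <- stats::runif(length(pos)) < config$target_sensitivity
    plan_documented(pos[doc], force_qualifying = TRUE)
    sub <- pos[!doc]
    plan_subthreshold(sub)
    # suspected patients live in the sub-threshold arm: 1-2-year-olds with
    # very limited data
    n_susp <- min(length(sub),
                  stats::rbinom(1L, length(pos), config$suspected_rate))
    if (n_susp > 0L) {
      s_idx <- sub[seq_len(n_susp)]
      suspected[s_idx] <- TRUE
      ages[s_idx] <- sample(1:2, n_susp, replace = TRUE)
      enc_kind[s_idx] <- ifelse(stats::runif(n_susp) < 0.5,
                                "excluded_text", "none")
      n_rx[s_idx] <- 0L
    }
    fp <- stats::runif(length(neg)) < (1 - config$target_specificity)
    plan_false_positive(neg[fp])
    plan_control(neg[!fp], allow_qualifying = FALSE)
  } else {
    susp <- stats::runif(length(pos)) < config$suspected_rate
    plan_documented(pos[!susp])
    s_idx <- pos[susp]
    if (length(s_idx)) {
      suspected[s_idx] <- TRUE
      ages[s_idx] <- sample(1:2, length(s_idx), replace = TRUE)
      plan_subthreshold(s_idx)
    }
    plan_control(neg)
  }

  # keep suspected (1-2-year-old) ages inside the configured band
  ages[suspected] <- pmin(pmax(ages[suspected], config$age_low),
                          config$age_high)

  # birth dates back-computed from completed age with a uniform day offset,
  # so anniversary boundaries are exercised
  offset <- sample(0:364, n, replace = TRUE)
  birth <- years_before(ref, ages) - offset

  patients <- data.frame(patient_id = ids, birth_date = birth, sex = sex,
                         stringsAsFactors = FALSE)

  # billing rows
  b_idx <- which(has_billing)
  billing <- data.frame(
    patient_id = ids[b_idx],
    date = random_dates(length(b_idx), ref),
    diagnosis_code = sample(SYN_ICD9_VARIANTS, length(b_idx), replace = TRUE),
    stringsAsFactors = FALSE
  )

  encounter_row <- function(idx, kind) {
    m <- length(idx)
    if (!m) {
      return(data.frame(patient_id = character(0),
                        date = as.Date(character(0)),
                        diagnosis_code = character(0),
                        diagnosis_text = character(0)))
    }
    code <- rep("", m); text <- rep("", m)
    is_code <- kind == "code"
    code[is_code] <- sample(SYN_ICD9_VARIANTS, sum(is_code), replace = TRUE)
    pools <- list(include_text = SYN_INCLUDE_TEXTS,
                  excluded_text = SYN_EXCLUDE_TEXTS,
                  benign_text = SYN_BENIGN_TEXTS)
    for (k in names(pools)) {
      sel <- kind == k
      if (any(sel)) text[sel] <- sample(pools[[k]], sum(sel), replace = TRUE)
    }
    data.frame(patient_id = ids[idx], date = random_dates(m, ref),
               diagnosis_code = code, diagnosis_text = text,
               stringsAsFactors = FALSE)
  }

  e_idx <- which(enc_kind != "none")
  encounters <- encounter_row(e_idx, enc_kind[e_idx])

  c_idx <- which(cond_kind != "none")
  cond_rows <- encounter_row(c_idx, cond_kind[c_idx])
  conditions <- data.frame(
    patient_id = cond_rows$patient_id,
    date_onset = cond_rows$date,
    condition_code = cond_rows$diagnosis_code,
    condition_text = cond_rows$diagnosis_text,
    stringsAsFactors = FALSE
  )

  # prescriptions: expand per-patient counts
  rx_id <- rep(ids, n_rx)
  rx_owner <- rep(seq_len(n), n_rx)
  m_rx <- length(rx_id)
  if (m_rx) {
    pool_rel <- rx_pool[rx_owner] == "reliever"
    rel_rows <- match(SYN_RELIEVER_POOL, ASTHMA_MEDICATIONS$drug_name)
    pick <- integer(m_rx)
    pick[pool_rel] <- sample(rel_rows, sum(pool_rel), replace = TRUE,
                             prob = c(0.9, 0.1))
    pick[!pool_rel] <- sample.int(nrow(ASTHMA_MEDICATIONS), sum(!pool_rel),
                                  replace = TRUE)
    drug <- ASTHMA_MEDICATIONS$drug_name[pick]
    atc <- ASTHMA_MEDICATIONS$atc_code[pick]
    # some rows carry only the drug name, exercising the name fallback
    name_only <- stats::runif(m_rx) < 0.10
    atc[name_only] <- ""
    drug[name_only] <- paste(drug[name_only], "100mcg inhaler")
    prescriptions <- data.frame(
      patient_id = rx_id, date = random_dates(m_rx, ref),
      drug_name = drug, atc_code = atc, stringsAsFactors = FALSE
    )
  } else {
    prescriptions <- empty_cohort_table("prescriptions")
  }

  cohort <- emr_cohort(
    patients = patients, billing = billing, encounters = encounters,
    conditions = conditions, prescriptions = prescriptions,
    reference_date = ref
  )
  list(cohort = cohort,
       gold = setNames(gold, ids),
       suspected = setNames(suspected, ids))
}

#' Generate a synthetic labelled cohort
#'
#' Draws a cohort of `n_patients` from the configured generative profiles:
#' gold-positive status is Bernoulli at the configured prevalence, ages are
#' uniform over the configured band with birth dates back-computed from
#' completed age, gold-positives receive diagnosis rows and qualifying
#' prescriptions per `case_profile`, gold-negatives receive uncertainty
#' texts ("asthma query", "?asthma"), benign labels and a lone-reliever
#' prescription tail per `control_profile`. With calibration targets set,
#' the mixture of fully-qualifying and sub-threshold records makes the
#' classifier's expected sensitivity/specificity equal the targets. A
#' "suspected" subset of gold-positives (very young, sparse records) is
#' flagged. Fully deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return object of class `labelled_cohort`: list with `cohort`
#'   (an [emr_cohort()]), `gold` and `suspected` (named logical vectors),
#'   and `config`.
#' @examples
#' lc <- generate_cohort(cohort_config(n_patients = 50, seed = 42))
#' table(lc$gold)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(config$seed)
  }
  out <- generate_impl(config)
  structure(c(out, list(config = config)), class = "labelled_cohort")
}

#' @export
print.labelled_cohort <- function(x, ...) {
  cat(sprintf("<labelled_cohort> %d patients, %d gold-positive (%.1f%%), %d suspected\n",
              length(x$gold), sum(x$gold),
              if (length(x$gold)) 100 * mean(x$gold) else 0,
              sum(x$suspected)))
  print(x$cohort)
  invisible(x)
}
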