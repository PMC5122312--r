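# EMR data model: a cohort mirrors the slice of a CPCSSN-style extract that the
# asthma case definition reads -- demographics plus billing, encounter
# diagnosis, health condition (problem list) and prescribed medication rows.
# Tables travel as UTF-8 comma-separated text with a header row and ISO-8601
# dates.

#' @name emr_tables
#' @title Cohort table schemas
#' @description
#' An `emr_cohort` bundles five data frames:
#' \describe{
#'   \item{patients}{`patient_id`, `birth_date` (`Date`, may be `NA`), `sex`
#'     (`"M"`, `"F"` or `"U"` for other/unknown).}
#'   \item{billing}{`patient_id`, `date` (`Date`), `diagnosis_code` (ICD-9,
#'     non-empty).}
#'   \item{encounters}{`patient_id`, `date`, `diagnosis_code` (may be empty),
#'     `diagnosis_text` (free text, may be empty); at least one of the two is
#'     non-empty.}
#'   \item{conditions}{`patient_id`, `date_onset` (`Date`, may be `NA`),
#'     `condition_code`, `condition_text`; at least one of code/text
#'     non-empty.}
#'   \item{prescriptions}{`patient_id`, `date`, `drug_name`, `atc_code`
#'     (7-character ATC shape when non-empty).}
#' }
#' plus a `reference_date` (the extraction cut-off at which ages are
#' computed; default 2015-06-30).
NULL

DEFAULT_REFERENCE_DATE <- as.Date("2015-06-30")

ATC_SHAPE <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"

cohort_table_files <- c(
  patients      = "patient.csv",
  billing       = "billing.csv",
  encounters    = "encounter_diagnosis.csv",
  conditions    = "health_condition.csv",
  prescriptions = "medication.csv"
)

cohort_table_columns <- list(
  patients      = c("patient_id", "birth_date", "sex"),
  billing       = c("patient_id", "date", "diagnosis_code"),
  encounters    = c("patient_id", "date", "diagnosis_code", "diagnosis_text"),
  conditions    = c("patient_id", "date_onset", "condition_code", "condition_text"),
  prescriptions = c("patient_id", "date", "drug_name", "atc_code")
)

cohort_date_columns <- list(
  patients      = "birth_date",
  billing       = "date",
  encounters    = "date",
  conditions    = "date_onset",
  prescriptions = "date"
)

# date columns that may legitimately be missing
optional_date_columns <- c("birth_date", "date_onset")

empty_cohort_table <- function(table) {
  cols <- cohort_table_columns[[table]]
  df <- as.data.frame(
    setNames(lapply(cols, function(c) character(0)), cols),
    stringsAsFactors = FALSE
  )
  for (dc in intersect(cohort_date_columns[[table]], cols)) {
    df[[dc]] <- as.Date(character(0))
  }
  df
}

#' Construct an EMR cohort
#'
#' Assembles and validates the five linked tables of a CPCSSN-style extract.
#' Missing tables default to empty; all invariants (unique patient ids,
#' linked rows, non-empty codes, ATC code shape, birth dates not after the
#' reference date) are checked and violations raise an error naming the
#' offending table and row.
#'
#' @param patients data frame with columns `patient_id`, `birth_date`, `sex`.
#' @param billing,encounters,conditions,prescriptions row tables; see
#'   [emr_tables].
#' @param reference_date `Date` (or ISO string); the date at which ages are
#'   evaluated. Defaults to 2015-06-30, the extraction cut-off convention.
#' @return an object of class `emr_cohort`.
#' @seealso [read_cohort()], [write_cohort()], [age_in_years()]
#' @examples
#' pts <- data.frame(patient_id = "p1", birth_date = "2008-03-14", sex = "F")
#' emr_cohort(patients = pts)
#' @export
emr_cohort <- function(patients = empty_cohort_table("patients"),
                       billing = empty_cohort_table("billing"),
                       encounters = empty_cohort_table("encounters"),
                       conditions = empty_cohort_table("conditions"),
                       prescriptions = empty_cohort_table("prescriptions"),
                       reference_date = DEFAULT_REFERENCE_DATE) {
  tables <- list(
    patients = patients, billing = billing, encounters = encounters,
    conditions = conditions, prescriptions = prescriptions
  )
  reference_date <- as_reference_date(reference_date)
  tables <- lapply(names(tables), function(nm) {
    coerce_cohort_table(tables[[nm]], nm)
  })
  names(tables) <- names(cohort_table_columns)
  cohort <- structure(
    c(tables, list(reference_date = reference_date)),
    class = "emr_cohort"
  )
  validate_cohort(cohort)
  cohort
}

as_reference_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  d <- parse_iso_date(x)
  if (length(d) != 1L || is.na(d)) {
    stop_input("reference_date must be a single ISO-8601 date, got '%s'",
               paste(x, collapse = ","))
  }
  d
}

coerce_cohort_table <- function(df, table) {
  cols <- cohort_table_columns[[table]]
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_input("table '%s' lacks column(s): %s", table,
               paste(missing, collapse = ", "))
  }
  df <- df[, cols, drop = FALSE]
  for (col in cols) {
    if (col %in% cohort_date_columns[[table]]) {
      if (!inherits(df[[col]], "Date")) {
        raw <- as.character(df[[col]])
        parsed <- parse_iso_date(raw)
        bad <- !is.na(raw) & nzchar(trimws(raw)) & is.na(parsed)
        if (any(bad)) {
          stop_input("table '%s' row %d: malformed date '%s' in column %s",
                     table, which(bad)[1], raw[which(bad)[1]], col)
        }
        required <- !(col %in% optional_date_columns)
        empty <- is.na(parsed)
        if (required && any(empty)) {
          stop_input("table '%s' row %d: missing required date in column %s",
                     table, which(empty)[1], col)
        }
        df[[col]] <- parsed
      }
    } else {
      v <- as.character(df[[col]])
      v[is.na(v)] <- ""
      df[[col]] <- v
    }
  }
  rownames(df) <- NULL
  df
}

validate_cohort <- function(cohort) {
  p <- cohort$patients
  dup <- duplicated(p$patient_id)
  if (any(dup)) {
    stop_input("table 'patients' row %d: duplicate patient_id '%s'",
               which(dup)[1], p$patient_id[which(dup)[1]])
  }
  blank <- !nzchar(trimws(p$patient_id))
  if (any(blank)) {
    stop_input("table 'patients' row %d: empty patient_id", which(blank)[1])
  }
  late <- !is.na(p$birth_date) & p$birth_date > cohort$reference_date
  if (any(late)) {
    stop_input("table 'patients' row %d: birth_date %s is after reference_date %s",
               which(late)[1], p$birth_date[which(late)[1]],
               cohort$reference_date)
  }
  ids <- p$patient_id
  for (tab in c("billing", "encounters", "conditions", "prescriptions")) {
    df <- cohort[[tab]]
    orphan <- !(df$patient_id %in% ids)
    if (any(orphan)) {
      stop_input("table '%s' row %d: patient_id '%s' not present in patient table",
                 tab, which(orphan)[1], df$patient_id[which(orphan)[1]])
    }
  }
  b <- cohort$billing
  noc <- !nzchar(trimws(b$diagnosis_code))
  if (any(noc)) {
    stop_input("table 'billing' row %d: empty diagnosis_code", which(noc)[1])
  }
  e <- cohort$encounters
  empty_e <- !nzchar(trimws(e$diagnosis_code)) & !nzchar(trimws(e$diagnosis_text))
  if (any(empty_e)) {
    stop_input("table 'encounters' row %d: both diagnosis_code and diagnosis_text empty",
               which(empty_e)[1])
  }
  h <- cohort$conditions
  empty_h <- !nzchar(trimws(h$condition_code)) & !nzchar(trimws(h$condition_text))
  if (any(empty_h)) {
    stop_input("table 'conditions' row %d: both condition_code and condition_text empty",
               which(empty_h)[1])
  }
  rx <- cohort$prescriptions
  atc <- toupper(trimws(rx$atc_code))
  bad_atc <- nzchar(atc) & !grepl(ATC_SHAPE, atc)
  if (any(bad_atc)) {
    stop_input("table 'prescriptions' row %d: '%s' is not a 7-character ATC code",
               which(bad_atc)[1], rx$atc_code[which(bad_atc)[1]])
  }
  invisible(cohort)
}

#' Read a cohort from delimited-text tables
#'
#' Loads the five cohort tables from a directory (standard file names
#' `patient.csv`, `billing.csv`, `encounter_diagnosis.csv`,
#' `health_condition.csv`, `medication.csv`) or from explicit per-table
#' paths, and validates all invariants. Any missing file, malformed date,
#' duplicate patient id or row referencing an unknown patient is a fatal
#' error that names the table and row.
#'
#' @param dir directory containing the standard file names.
#' @param paths optional named list/vector overriding individual table paths
#'   (names among `patients`, `billing`, `encounters`, `conditions`,
#'   `prescriptions`).
#' @param reference_date cohort reference date (default 2015-06-30).
#' @return an `emr_cohort`.
#' @export
read_cohort <- function(dir = NULL, paths = NULL,
                        reference_date = DEFAULT_REFERENCE_DATE) {
  files <- if (!is.null(dir)) {
    setNames(file.path(dir, cohort_table_files), names(cohort_table_files))
  } else {
    setNames(rep(NA_character_, length(cohort_table_files)),
             names(cohort_table_files))
  }
  if (!is.null(paths)) {
    paths <- as.list(paths)
    unknown <- setdiff(names(paths), names(cohort_table_files))
    if (length(unknown)) {
      stop_input("unknown table name(s) in paths: %s",
                 paste(unknown, collapse = ", "))
    }
    files[names(paths)] <- unlist(paths)
  }
  tabs <- lapply(names(files), function(nm) {
    path <- files[[nm]]
    if (is.na(path) || !file.exists(path)) {
      stop_input("input file for table '%s' not found: %s", nm,
                 ifelse(is.na(path), "<unspecified>", path))
    }
    df <- utils::read.csv(path, colClasses = "character",
                          na.strings = character(0), check.names = TRUE,
                          fileEncoding = "UTF-8")
    missing <- setdiff(cohort_table_columns[[nm]], names(df))
    if (length(missing)) {
      stop_input("file %s: header lacks column(s) %s", path,
                 paste(missing, collapse = ", "))
    }
    df
  })
  names(tabs) <- names(files)
  emr_cohort(
    patients = tabs$patients, billing = tabs$billing,
    encounters = tabs$encounters, conditions = tabs$conditions,
    prescriptions = tabs$prescriptions, reference_date = reference_date
  )
}

#' Write a cohort as delimited-text tables
#'
#' Writes the five tables under their standard file names; reading them back
#' with [read_cohort()] reproduces the cohort field-for-field (dates are
#' ISO-8601, text fields are quoted, so delimiters and quotes in free text
#' survive).
#'
#' @param cohort an `emr_cohort`.
#' @param dir destination directory (created if absent).
#' @return invisibly, the named vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "emr_cohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_input("cannot create output directory %s", dir)
  }
  files <- setNames(file.path(dir, cohort_table_files),
                    names(cohort_table_files))
  for (nm in names(files)) {
    df <- cohort[[nm]]
    for (dc in cohort_date_columns[[nm]]) {
      df[[dc]] <- ifelse(is.na(df[[dc]]), "", format(df[[dc]], "%Y-%m-%d"))
    }
    utils::write.csv(df, files[[nm]], row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  }
  invisible(files)
}

#' Age in completed years
#'
#' Whole years elapsed between `birth_date` and `reference_date`, decremented
#' by one when the reference date falls before that year's birthday
#' anniversary (a Feb-29 birthday is treated as Feb 29, so it has not yet
#' occurred on Feb 28 of a common year). Vectorised; `NA` birth dates give
#' `NA` ages.
#'
#' @param birth_date `Date` vector (or ISO strings).
#' @param reference_date single `Date` (or ISO string) on/after every birth
#'   date.
#' @return integer vector of completed years (>= 0).
#' @examples
#' age_in_years("2014-06-30", "2015-06-30") # 1: exact anniversary
#' age_in_years("2014-07-01", "2015-06-30") # 0: day before anniversary
#' @export
age_in_years <- function(birth_date, reference_date = DEFAULT_REFERENCE_DATE) {
  if (!inherits(birth_date, "Date")) birth_date <- parse_iso_date(birth_date)
  reference_date <- as_reference_date(reference_date)
  if (any(!is.na(birth_date) & birth_date > reference_date)) {
    stop_input("birth_date after reference_date")
  }
  b <- as.POSIXlt(birth_date)
  r <- as.POSIXlt(reference_date)
  raw <- r$year - b$year
  before_anniv <- (r$mon < b$mon) | (r$mon == b$mon & r$mday < b$mday)
  out <- raw - as.integer(before_anniv)
  as.integer(out)
}

#' @export
print.emr_cohort <- function(x, ...) {
  cat(sprintf("<emr_cohort> %d patients (reference date %s)\n",
              nrow(x$patients), format(x$reference_date)))
  cat(sprintf("  billing: %d  encounters: %d  conditions: %d  prescriptions: %d\n",
              nrow(x$billing), nrow(x$encounters), nrow(x$conditions),
              nrow(x$prescriptions)))
  invisible(x)
}

#' @export
summary.emr_cohort <- function(object, ...) {
  ages <- age_in_years(object$patients$birth_date, object$reference_date)
  cat(sprintf("EMR cohort: %d patients, reference date %s\n",
              nrow(object$patients), format(object$reference_date)))
  if (length(ages)) {
    cat(sprintf("  ages (completed years): median %s, range %s-%s, %d missing\n",
                stats::median(ages, na.rm = TRUE),
                suppressWarnings(min(ages, na.rm = TRUE)),
                suppressWarnings(max(ages, na.rm = TRUE)),
                sum(is.na(ages))))
  }
  for (tab in c("billing", "encounters", "conditions", "prescriptions")) {
    cat(sprintf("  %-13s %6d rows\n", tab, nrow(object[[tab]])))
  }
  invisible(object)
}

#' Read and write gold-standard labels
#'
#' Gold labels are a two-column table `patient_id,gold_case` with
#' `gold_case` coded 1/0 (chart-review case or non-case).
#'
#' @param path file to read or write.
#' @param labels named logical vector (names are patient ids).
#' @return `read_gold_labels` returns a named logical vector.
#' @export
read_gold_labels <- function(path) {
  if (!file.exists(path)) stop_input("gold label file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = character(0), fileEncoding = "UTF-8")
  if (!all(c("patient_id", "gold_case") %in% names(df))) {
    stop_input("file %s: expected columns patient_id, gold_case", path)
  }
  val <- trimws(df$gold_case)
  if (any(!val %in% c("0", "1"))) {
    bad <- which(!val %in% c("0", "1"))[1]
    stop_input("file %s row %d: gold_case must be 0 or 1, got '%s'",
               path, bad, val[bad])
  }
  dup <- duplicated(df$patient_id)
  if (any(dup)) {
    stop_input("file %s row %d: duplicate patient_id '%s'",
               path, which(dup)[1], df$patient_id[which(dup)[1]])
  }
  setNames(val == "1", df$patient_id)
}

#' @rdname read_gold_labels
#' @export
write_gold_labels <- function(labels, path) {
  df <- data.frame(patient_id = names(labels),
                   gold_case = as.integer(labels))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
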