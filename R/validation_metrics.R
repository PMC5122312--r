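# Diagnostic-accuracy statistics for algorithm-vs-gold-standard comparison:
# 2x2 confusion matrices, sensitivity/specificity/PPV/NPV with exact
# (Clopper-Pearson) or Wilson score confidence intervals, percent agreement
# and Cohen's kappa, and the age-stratified validation report.

#' Confusion matrix for a binary case-finding comparison
#'
#' @param tp,fp,tn,fn non-negative integer counts (algorithm vs gold:
#'   true/false positives/negatives).
#' @return object of class `confusion_matrix`.
#' @examples
#' confusion_matrix(tp = 125, fp = 12, tn = 845, fn = 18)
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop_input("confusion counts must be non-negative integers")
  }
  structure(as.list(setNames(as.integer(counts), names(counts))),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(algorithm = c("case", "noncase"),
                              gold = c("case", "noncase")))
  cat(sprintf("<confusion_matrix> n = %d\n", cm_total(x)))
  print(m)
  invisible(x)
}

cm_total <- function(cm) cm$tp + cm$fp + cm$tn + cm$fn

#' Build a confusion matrix from paired labels
#'
#' Both inputs are named logical vectors (names are patient ids); the
#' patient sets must coincide and the comparison is made id-by-id.
#'
#' @param algorithm named logical vector of algorithm verdicts.
#' @param gold named logical vector of gold-standard labels.
#' @return a [confusion_matrix()].
#' @examples
#' alg <- c(a = TRUE, b = FALSE, c = TRUE)
#' gold <- c(a = TRUE, b = FALSE, c = FALSE)
#' build_confusion(alg, gold)
#' @export
build_confusion <- function(algorithm, gold) {
  if (is.null(names(algorithm)) || is.null(names(gold))) {
    stop_input("algorithm and gold labels must be named by patient_id")
  }
  only_a <- setdiff(names(algorithm), names(gold))
  only_g <- setdiff(names(gold), names(algorithm))
  if (length(only_a) || length(only_g)) {
    stop_input(
      "patient sets differ: %d only in algorithm (e.g. %s), %d only in gold (e.g. %s)",
      length(only_a), paste(utils::head(only_a, 3), collapse = ","),
      length(only_g), paste(utils::head(only_g, 3), collapse = ","))
  }
  g <- gold[names(algorithm)]
  a <- as.logical(algorithm)
  confusion_matrix(
    tp = sum(a & g), fp = sum(a & !g),
    tn = sum(!a & !g), fn = sum(!a & g)
  )
}

#' Binomial proportion confidence interval
#'
#' Two-sided interval for `successes / n`. `"clopper-pearson"` is the exact
#' interval from beta quantiles (lower bound 0 at zero successes, upper
#' bound 1 at n successes); `"wilson"` is the score interval.
#'
#' @param successes,n integer counts, `0 <= successes <= n`, `n >= 1`.
#' @param method `"clopper-pearson"` (default) or `"wilson"`.
#' @param level confidence level in (0, 1).
#' @return numeric `c(low, high)`.
#' @examples
#' binomial_ci(125, 143)
#' binomial_ci(125, 143, method = "wilson")
#' @export
binomial_ci <- function(successes, n, method = c("clopper-pearson", "wilson"),
                        level = 0.95) {
  method <- match.arg(method)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop_input("confidence level must be in (0, 1)")
  }
  if (n < 1 || successes < 0 || successes > n) {
    stop_input("need 0 <= successes <= n with n >= 1")
  }
  alpha <- 1 - level
  x <- successes
  if (method == "clopper-pearson") {
    low <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
    high <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    p <- x / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    low <- max(0, centre - half)
    high <- min(1, centre + half)
  }
  c(low = low, high = high)
}

metric_estimate <- function(numerator, denominator, method, level) {
  if (denominator == 0) {
    return(structure(list(point = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, numerator = numerator,
                          denominator = 0L, level = level, method = method),
                     class = "metric_estimate"))
  }
  ci <- binomial_ci(numerator, denominator, method = method, level = level)
  structure(
    list(point = numerator / denominator, ci_low = unname(ci["low"]),
         ci_high = unname(ci["high"]), numerator = as.integer(numerator),
         denominator = as.integer(denominator), level = level,
         method = method),
    class = "metric_estimate"
  )
}

#' @export
print.metric_estimate <- function(x, ...) {
  if (is.na(x$point)) {
    cat("<metric_estimate> undefined (zero denominator)\n")
  } else {
    cat(sprintf("<metric_estimate> %s (%s-%s) [%d/%d, %s, %.0f%% CI]\n",
                format_pct(x$point), format_pct(x$ci_low),
                format_pct(x$ci_high), x$numerator, x$denominator, x$method,
                100 * x$level))
  }
  invisible(x)
}

# one-decimal percentage, halves away from zero, as printed in validation
# tables
format_pct <- function(p) {
  ifelse(is.na(p), "--", sprintf("%.1f", round_half_away(100 * p, 1)))
}

metric_from_cm <- function(cm, which, method, level) {
  stopifnot(inherits(cm, "confusion_matrix"))
  num_den <- switch(which,
    sensitivity = c(cm$tp, cm$tp + cm$fn),
    specificity = c(cm$tn, cm$tn + cm$fp),
    ppv         = c(cm$tp, cm$tp + cm$fp),
    npv         = c(cm$tn, cm$tn + cm$fn)
  )
  metric_estimate(num_den[1], num_den[2], method = method, level = level)
}

#' Diagnostic accuracy metrics
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`, each with
#' a binomial confidence interval. A zero denominator yields an undefined
#' estimate (`NA`), never 0 or 1.
#'
#' @param cm a [confusion_matrix()].
#' @param method,level passed to [binomial_ci()].
#' @return a `metric_estimate` with fields `point`, `ci_low`, `ci_high`.
#' @examples
#' cm <- confusion_matrix(125, 12, 845, 18)
#' sensitivity(cm)
#' ppv(cm)
#' @export
sensitivity <- function(cm, method = "clopper-pearson", level = 0.95) {
  metric_from_cm(cm, "sensitivity", method, level)
}

#' @rdname sensitivity
#' @export
specificity <- function(cm, method = "clopper-pearson", level = 0.95) {
  metric_from_cm(cm, "specificity", method, level)
}

#' @rdname sensitivity
#' @export
ppv <- function(cm, method = "clopper-pearson", level = 0.95) {
  metric_from_cm(cm, "ppv", method, level)
}

#' @rdname sensitivity
#' @export
npv <- function(cm, method = "clopper-pearson", level = 0.95) {
  metric_from_cm(cm, "npv", method, level)
}

align_label_pair <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    only_a <- setdiff(names(labels_a), names(labels_b))
    only_b <- setdiff(names(labels_b), names(labels_a))
    if (length(only_a) || length(only_b)) {
      stop_input("label sets differ: %d only in first, %d only in second",
                 length(only_a), length(only_b))
    }
    labels_b <- labels_b[names(labels_a)]
  } else if (length(labels_a) != length(labels_b)) {
    stop_input("label vectors differ in length (%d vs %d)",
               length(labels_a), length(labels_b))
  }
  if (!length(labels_a)) stop_input("need at least one paired label")
  list(a = labels_a, b = labels_b)
}

#' Percent agreement between two raters
#'
#' Fraction of subjects on which two label vectors agree. Vectors are
#' aligned by name when both are named; otherwise by position.
#'
#' @param labels_a,labels_b label vectors (logical or factor-like).
#' @return proportion in \[0, 1\].
#' @export
percent_agreement <- function(labels_a, labels_b) {
  p <- align_label_pair(labels_a, labels_b)
  mean(p$a == p$b)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, with expected
#' agreement `p_e` from the product of the raters' marginal category
#' proportions. Works for any number of categories. Perfect observed
#' agreement returns 1 by convention, including the degenerate case where
#' both raters use a single category.
#'
#' @param labels_a,labels_b label vectors, aligned by name when both named.
#' @return kappa statistic in \[-1, 1\].
#' @examples
#' a <- rep(c(TRUE, TRUE, FALSE, FALSE), c(40, 10, 10, 40))
#' b <- rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 10, 10, 40))
#' cohen_kappa(a, b) # 0.6: p_o = 0.8, p_e = 0.5
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  p <- align_label_pair(labels_a, labels_b)
  a <- as.character(p$a)
  b <- as.character(p$b)
  n <- length(a)
  p_o <- mean(a == b)
  if (p_o == 1) return(1)
  cats <- union(unique(a), unique(b))
  p_e <- sum(vapply(cats, function(k) mean(a == k) * mean(b == k),
                    numeric(1)))
  (p_o - p_e) / (1 - p_e)
}

#' Age-stratified validation report
#'
#' For each inclusive age band, restricts the comparison to patients whose
#' completed age at the reference date falls in the band, builds the
#' confusion matrix against the gold standard, and computes sensitivity,
#' specificity, PPV and NPV with confidence intervals — the machine form of
#' a published validation table. An empty stratum reports undefined metrics
#' rather than failing.
#'
#' @param cohort an [emr_cohort()] (provides ages).
#' @param algorithm named logical vector of algorithm verdicts covering the
#'   cohort's patients.
#' @param gold named logical vector of gold labels covering the same
#'   patients.
#' @param age_bands list of `c(lo, hi)` inclusive completed-age bands
#'   (default 1-17, 3-17, 6-17).
#' @param method,level confidence-interval settings, see [binomial_ci()].
#' @return object of class `validation_report`: a list of strata, each with
#'   `label`, `n`, `cm` and the four `metric_estimate`s.
#' @export
stratified_report <- function(cohort, algorithm, gold,
                              age_bands = list(c(1, 17), c(3, 17), c(6, 17)),
                              method = "clopper-pearson", level = 0.95) {
  stopifnot(inherits(cohort, "emr_cohort"))
  ids <- cohort$patients$patient_id
  missing_alg <- setdiff(ids, names(algorithm))
  missing_gold <- setdiff(ids, names(gold))
  if (length(missing_alg) || length(missing_gold)) {
    stop_input("labels do not cover the cohort: %d missing from algorithm, %d from gold",
               length(missing_alg), length(missing_gold))
  }
  ages <- age_in_years(cohort$patients$birth_date, cohort$reference_date)
  names(ages) <- ids
  strata <- lapply(age_bands, function(band) {
    lo <- band[1]; hi <- band[2]
    keep <- ids[!is.na(ages) & ages >= lo & ages <= hi]
    label <- sprintf("%d-%d years", lo, hi)
    if (!length(keep)) {
      return(list(label = label, n = 0L, cm = NULL,
                  sensitivity = metric_estimate(0L, 0L, method, level),
                  specificity = metric_estimate(0L, 0L, method, level),
                  ppv = metric_estimate(0L, 0L, method, level),
                  npv = metric_estimate(0L, 0L, method, level)))
    }
    cm <- build_confusion(algorithm[keep], gold[keep])
    list(label = label, n = cm_total(cm), cm = cm,
         sensitivity = sensitivity(cm, method, level),
         specificity = specificity(cm, method, level),
         ppv = ppv(cm, method, level),
         npv = npv(cm, method, level))
  })
  structure(list(strata = strata, method = method, level = level),
            class = "validation_report")
}

#' Build a validation report directly from confusion matrices
#'
#' Convenience path used when the per-stratum 2x2 counts are already known
#' (for instance when re-deriving the metrics of a published validation
#' table from its printed counts).
#'
#' @param cms named list of [confusion_matrix()] objects; names are stratum
#'   labels.
#' @inheritParams stratified_report
#' @return a `validation_report`.
#' @examples
#' report_from_counts(list("1-17 years" = confusion_matrix(125, 12, 845, 18)))
#' @export
report_from_counts <- function(cms, method = "clopper-pearson", level = 0.95) {
  stopifnot(length(cms) >= 1)
  strata <- lapply(seq_along(cms), function(i) {
    cm <- cms[[i]]
    stopifnot(inherits(cm, "confusion_matrix"))
    list(label = names(cms)[i] %||% sprintf("stratum %d", i),
         n = cm_total(cm), cm = cm,
         sensitivity = sensitivity(cm, method, level),
         specificity = specificity(cm, method, level),
         ppv = ppv(cm, method, level),
         npv = npv(cm, method, level))
  })
  structure(list(strata = strata, method = method, level = level),
            class = "validation_report")
}

#' Tabulate a validation report
#'
#' @param x a `validation_report`.
#' @param ... unused.
#' @return data frame with one row per stratum: counts plus the four point
#'   estimates and CI bounds as proportions.
#' @export
as.data.frame.validation_report <- function(x, ...) {
  rows <- lapply(x$strata, function(s) {
    cm <- s$cm %||% confusion_matrix(0, 0, 0, 0)
    data.frame(
      stratum = s$label, n = s$n,
      tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
      sensitivity = s$sensitivity$point,
      sensitivity_low = s$sensitivity$ci_low,
      sensitivity_high = s$sensitivity$ci_high,
      specificity = s$specificity$point,
      specificity_low = s$specificity$ci_low,
      specificity_high = s$specificity$ci_high,
      ppv = s$ppv$point, ppv_low = s$ppv$ci_low, ppv_high = s$ppv$ci_high,
      npv = s$npv$point, npv_low = s$npv$ci_low, npv_high = s$npv$ci_high,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @export
format.validation_report <- function(x, ...) {
  fmt_est <- function(est) {
    if (is.na(est$point)) return("--")
    sprintf("%s (%s-%s)", format_pct(est$point), format_pct(est$ci_low),
            format_pct(est$ci_high))
  }
  header <- sprintf("%-12s %6s %5s %5s %5s %5s  %-18s %-18s %-18s %-18s",
                    "Age range", "n", "TP", "FP", "TN", "FN",
                    "Sensitivity", "Specificity", "PPV", "NPV")
  rows <- vapply(x$strata, function(s) {
    cm <- s$cm %||% confusion_matrix(0, 0, 0, 0)
    sprintf("%-12s %6d %5d %5d %5d %5d  %-18s %-18s %-18s %-18s",
            s$label, s$n, cm$tp, cm$fp, cm$tn, cm$fn,
            fmt_est(s$sensitivity), fmt_est(s$specificity),
            fmt_est(s$ppv), fmt_est(s$npv))
  }, character(1))
  c(header, rows)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report (%s, %.0f%% CI; %% to one decimal)\n",
              x$method, 100 * x$level))
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Write a validation report as delimited text
#'
#' Writes the tabular form (see [as.data.frame.validation_report()]) to
#' `path`, and optionally the aligned plain-text table next to it.
#'
#' @param report a `validation_report`.
#' @param path CSV destination.
#' @param text_path optional path for the aligned plain-text rendering.
#' @export
write_validation_report <- function(report, path, text_path = NULL) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  if (!is.null(text_path)) {
    writeLines(format(report), text_path)
  }
  invisible(path)
}
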