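test_that("confusion matrices are built correctly from paired labels", {
  eng <- labels_for_counts(125, 12, 845, 18)
  cm <- build_confusion(eng$algorithm, eng$gold)
  expect_identical(c(cm$tp, cm$fp, cm$tn, cm$fn), c(125L, 12L, 845L, 18L))
  # perfect agreement
  cm0 <- build_confusion(eng$gold, eng$gold)
  expect_identical(c(cm0$fp, cm0$fn), c(0L, 0L))
  # alignment is by patient id, not position
  shuffled <- sample(eng$algorithm)
  expect_identical(build_confusion(shuffled, eng$gold), cm)
  # random labels agree with a naive counting oracle
  set.seed(7)
  for (i in 1:5) {
    n <- 200
    ids <- sprintf("r%03d", 1:n)
    a <- setNames(runif(n) < 0.3, ids)
    g <- setNames(runif(n) < 0.2, ids)
    cmr <- build_confusion(a, g)
    expect_identical(cmr$tp, sum(a & g))
    expect_identical(cmr$fp, sum(a & !g))
    expect_identical(cmr$tn, sum(!a & !g))
    expect_identical(cmr$fn, sum(!a & g))
  }
  # mismatched patient sets are an error listing the difference
  expect_error(build_confusion(eng$algorithm[-1], eng$gold),
               "patient sets differ.*only in gold")
  expect_error(confusion_matrix(-1, 0, 0, 0), "non-negative")
})

test_that("metric points satisfy their defining ratios exactly", {
  set.seed(11)
  for (i in 1:20) {
    counts <- sample.int(400, 4)
    cm <- confusion_matrix(counts[1], counts[2], counts[3], counts[4])
    expect_equal(sensitivity(cm)$point * (cm$tp + cm$fn), cm$tp,
                 tolerance = 1e-12)
    expect_equal(specificity(cm)$point * (cm$tn + cm$fp), cm$tn,
                 tolerance = 1e-12)
    expect_equal(ppv(cm)$point * (cm$tp + cm$fp), cm$tp, tolerance = 1e-12)
    expect_equal(npv(cm)$point * (cm$tn + cm$fn), cm$tn, tolerance = 1e-12)
    for (est in list(sensitivity(cm), specificity(cm), ppv(cm), npv(cm))) {
      expect_true(est$ci_low <= est$point && est$point <= est$ci_high)
    }
  }
  # error-free matrices give perfect sensitivity and PPV
  cm <- confusion_matrix(40, 0, 60, 0)
  expect_identical(sensitivity(cm)$point, 1)
  expect_identical(ppv(cm)$point, 1)
})

test_that("undefined metrics are reported as missing, never 0 or 1", {
  cm <- confusion_matrix(0, 0, 10, 0)   # no gold-positives
  expect_true(is.na(sensitivity(cm)$point))
  expect_true(is.na(ppv(cm)$point))
  expect_identical(specificity(cm)$point, 1)
})

test_that("Clopper-Pearson intervals match the exact binomial oracle", {
  # frozen oracle value computed independently from the exact binomial test
  ci <- binomial_ci(125, 143)
  expect_equal(unname(ci), c(0.8083761523, 0.9236630968), tolerance = 1e-9)
  # and across a grid against stats::binom.test
  for (n in c(10, 50, 143)) {
    for (x in unique(c(0, 1, floor(n / 3), n - 1, n))) {
      got <- binomial_ci(x, n)
      want <- stats::binom.test(x, n)$conf.int
      expect_equal(unname(got), as.numeric(want), tolerance = 1e-10,
                   label = sprintf("x=%d n=%d", x, n))
    }
  }
  expect_identical(unname(binomial_ci(0, 25))[1], 0)
  expect_identical(unname(binomial_ci(25, 25))[2], 1)
  expect_error(binomial_ci(5, 10, level = 1.2), "level")
  expect_error(binomial_ci(11, 10), "successes")
})

test_that("Wilson intervals match the score-test oracle", {
  for (n in c(20, 143, 600)) {
    for (x in c(1, floor(n / 4), n - 1)) {
      got <- binomial_ci(x, n, method = "wilson")
      want <- stats::prop.test(x, n, correct = FALSE)$conf.int
      expect_equal(unname(got), as.numeric(want), tolerance = 1e-9)
    }
  }
})

test_that("interval width shrinks as n grows at fixed proportion", {
  for (method in c("clopper-pearson", "wilson")) {
    widths <- vapply(c(20, 80, 320, 1280), function(n) {
      ci <- binomial_ci(round(0.87 * n), n, method = method)
      ci["high"] - ci["low"]
    }, numeric(1))
    expect_true(all(diff(widths) < 0), label = method)
  }
})

test_that("percent agreement counts identical labels", {
  expect_identical(percent_agreement(c(a = TRUE, b = FALSE),
                                     c(a = TRUE, b = FALSE)), 1)
  x <- setNames(rep(TRUE, 100), sprintf("s%03d", 1:100))
  y <- x
  y[c(4, 40, 77)] <- FALSE
  expect_identical(percent_agreement(x, y), 0.97)
  set.seed(21)
  a <- runif(50) < 0.5
  b <- runif(50) < 0.5
  expect_identical(percent_agreement(a, b), mean(a == b))
  expect_error(percent_agreement(x, y[-1]), "label sets differ")
})

test_that("Cohen's kappa follows the chance-corrected agreement formula", {
  # hand-evaluated 2x2 table (40,10 / 10,40): p_o = 0.8, p_e = 0.5
  a <- rep(c(TRUE, TRUE, FALSE, FALSE), c(40, 10, 10, 40))
  b <- rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 10, 10, 40))
  expect_equal(cohen_kappa(a, b), 0.6, tolerance = 1e-12)
  # perfect agreement with both categories present
  expect_identical(cohen_kappa(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE)), 1)
  # degenerate single-category agreement returns 1 by convention
  expect_identical(cohen_kappa(rep(TRUE, 5), rep(TRUE, 5)), 1)
  # total disagreement on a symmetric table reaches -1
  expect_equal(cohen_kappa(c(TRUE, FALSE), c(FALSE, TRUE)), -1,
               tolerance = 1e-12)
})

test_that("kappa is near zero for independent raters", {
  set.seed(33)
  kappas <- replicate(40, {
    a <- runif(400) < 0.5
    b <- runif(400) < 0.5
    cohen_kappa(a, b)
  })
  # each kappa has SE ~ 1/sqrt(n) = 0.05; the mean of 40 replicates ~ 0.008
  expect_lt(abs(mean(kappas)), 0.025)
  expect_true(all(abs(kappas) < 0.25))
})

test_that("stratified reports partition the cohort by completed age", {
  lc <- generate_cohort(cohort_config(n_patients = 600, seed = 12))
  cls <- classify_cohort(lc$cohort)
  alg <- setNames(cls$is_case, cls$patient_id)
  report <- stratified_report(lc$cohort, alg, lc$gold)
  df <- as.data.frame(report)
  expect_identical(df$stratum, c("1-17 years", "3-17 years", "6-17 years"))
  # band n values are non-increasing as the lower bound rises
  expect_true(all(diff(df$n) <= 0))
  # the 1-17 counts equal the 3-17 counts plus patients aged 1-2
  ages <- age_in_years(lc$cohort$patients$birth_date,
                       lc$cohort$reference_date)
  names(ages) <- lc$cohort$patients$patient_id
  young <- names(ages)[ages %in% 1:2]
  expect_identical(df$n[1], df$n[2] + length(young))
  cm_young <- build_confusion(alg[young], lc$gold[young])
  expect_identical(df$tp[1], df$tp[2] + cm_young$tp)
  expect_identical(df$fn[1], df$fn[2] + cm_young$fn)
  # a single band covering everyone equals the unstratified computation
  single <- as.data.frame(stratified_report(lc$cohort, alg, lc$gold,
                                            age_bands = list(c(1, 17))))
  expect_identical(single$tp, df$tp[1])
  expect_identical(single$sensitivity, df$sensitivity[1])
})

test_that("an empty stratum reports undefined metrics, not an error", {
  lc <- generate_cohort(cohort_config(n_patients = 50, seed = 2))
  cls <- classify_cohort(lc$cohort)
  alg <- setNames(cls$is_case, cls$patient_id)
  report <- stratified_report(lc$cohort, alg, lc$gold,
                              age_bands = list(c(40, 50)))
  s <- report$strata[[1]]
  expect_identical(s$n, 0L)
  expect_true(is.na(s$sensitivity$point))
  expect_true(is.na(s$npv$point))
})

test_that("reports format percentages to one decimal, halves away from zero", {
  expect_identical(round_half_away(91.85, 1), 91.9)
  expect_identical(round_half_away(87.45, 1), 87.5)
  expect_identical(round_half_away(-0.15, 1), -0.2)
  report <- report_from_counts(list("1-17 years" = confusion_matrix(125, 12, 845, 18)))
  txt <- format(report)
  expect_match(txt[2], "87.4 \\(", all = FALSE)
  expect_match(txt[2], "91.2 \\(", all = FALSE)
  # delimited + aligned text outputs
  csv <- withr::local_tempfile(fileext = ".csv")
  txt_path <- withr::local_tempfile(fileext = ".txt")
  write_validation_report(report, csv, text_path = txt_path)
  expect_identical(nrow(utils::read.csv(csv)), 1L)
  expect_length(readLines(txt_path), 2L)
})
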