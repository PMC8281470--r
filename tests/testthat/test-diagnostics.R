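# Diagnostic-metric unit tests. Derived expectations are hand arithmetic on
# integer tables (e.g. 40/143 = 0.27972...), computed independently of the
# implementation.

test_that("confusion matrix counts ENT/AT cells and excludes missing outcomes", {
  dest <- c("ENT", "ENT", "ENT", "respirology", "respirology", "respirology")
  out <- c(TRUE, TRUE, FALSE, TRUE, FALSE, NA)
  cm <- confusion_matrix(dest, out)
  expect_equal(cm[c("tp", "fp", "fn", "tn")],
               list(tp = 2L, fp = 1L, fn = 1L, tn = 1L))
  expect_equal(cm$n_excluded, 1L)

  cm <- confusion_matrix(rep("ENT", 5), rep(TRUE, 5))
  expect_equal(cm[c("tp", "fp", "fn", "tn")],
               list(tp = 5L, fp = 0L, fn = 0L, tn = 0L))

  cm <- confusion_matrix(character(), logical())
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 0L)
  expect_error(confusion_matrix(rep("ENT", 3), TRUE), "differ in length")
})

test_that("diagnostic metrics match hand-computed values and limits", {
  cm <- structure(list(tp = 40, fp = 27, fn = 103, tn = 273, n_excluded = 0L),
                  class = "confusion_matrix")
  m <- diagnostic_metrics(cm)
  expect_equal(m$sensitivity, 40 / 143)
  expect_equal(m$specificity, 273 / 300)
  expect_equal(m$ppv, 40 / 67)
  expect_equal(m$npv, 273 / 376)
  expect_equal(m$diagnostic_or, (40 * 273) / (27 * 103))

  perfect <- confusion_matrix(c(rep("ENT", 10), rep("respirology", 10)),
                              c(rep(TRUE, 10), rep(FALSE, 10)))
  m <- diagnostic_metrics(perfect)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_identical(m$diagnostic_or, Inf)
  expect_identical(m$lr_positive, Inf)

  empty <- confusion_matrix(rep("ENT", 2), c(NA, NA))
  m <- diagnostic_metrics(empty)
  expect_true(is.na(m$sensitivity))
  expect_equal(m$n_excluded, 2L)
})

test_that("rate-only metrics reproduce the closed-form identities", {
  m <- metrics_from_rates(0.28, 0.91)
  expect_equal(m$lr_negative, 0.72 / 0.91)
  expect_equal(m$fpr, 0.09)
  m <- metrics_from_rates(0.5, 0.5)
  expect_equal(m$lr_positive, 1)
  expect_equal(m$lr_negative, 1)
  expect_equal(m$diagnostic_or, 1)
  m <- metrics_from_rates(0.72, 0.78)
  expect_equal(m$fpr, 0.22)
  # boundary limits
  expect_identical(metrics_from_rates(1, 1)$lr_positive, Inf)
  expect_identical(metrics_from_rates(1, 0.5)$diagnostic_or, Inf)
})

test_that("2x2 odds ratio matches the cross-product with and without Haldane", {
  or <- odds_ratio_2x2(38, 27, 10, 50)
  expect_equal(or$estimate, 38 * 50 / (27 * 10))
  expect_false(or$correction_applied)
  expect_lt(or$ci_low, or$estimate)
  expect_gt(or$ci_high, or$estimate)

  expect_equal(odds_ratio_2x2(5, 5, 5, 5)$estimate, 1)

  or <- odds_ratio_2x2(3, 0, 2, 10, correction = "haldane")
  expect_true(or$correction_applied)
  expect_equal(or$estimate, (3.5 * 10.5) / (0.5 * 2.5))

  # two zero cells sharing a margin, uncorrected -> undefined
  expect_true(is.na(odds_ratio_2x2(0, 0, 2, 10)$estimate))
  expect_identical(odds_ratio_2x2(3, 0, 2, 10)$estimate, Inf)
  expect_error(odds_ratio_2x2(-1, 2, 3, 4), "non-negative")

  # invariances: double swap preserves, single swap reciprocates
  set.seed(11)
  for (i in 1:50) {
    cells <- rpois(4, 20) + 1
    base <- odds_ratio_2x2(cells[1], cells[2], cells[3], cells[4])$estimate
    swapped <- odds_ratio_2x2(cells[4], cells[3], cells[2], cells[1])$estimate
    rows <- odds_ratio_2x2(cells[3], cells[4], cells[1], cells[2])$estimate
    expect_equal(swapped, base)
    expect_equal(rows, 1 / base)
  }
})

test_that("metric identities hold to 1e-12 on random matrices", {
  set.seed(21)
  for (i in 1:200) {
    cm <- structure(as.list(setNames(rpois(4, 40) + 1,
                                     c("tp", "fp", "fn", "tn"))),
                    class = "confusion_matrix")
    cm$n_excluded <- 0L
    m <- diagnostic_metrics(cm)
    expect_equal(m$tpr + m$fnr, 1, tolerance = 1e-12)
    expect_equal(m$tnr + m$fpr, 1, tolerance = 1e-12)
    expect_equal(m$diagnostic_or, m$lr_positive / m$lr_negative,
                 tolerance = 1e-12)
    expect_equal(m$diagnostic_or, (cm$tp * cm$tn) / (cm$fp * cm$fn),
                 tolerance = 1e-12)
  }
})

test_that("logistic fit agrees with the 2x2 oracle and flags degeneracy", {
  # single binary predictor, no covariate: analytic equivalence to the
  # cross-product odds ratio
  tab <- c(30, 45, 25, 60)  # exposed AT / exposed no-AT / unexposed AT / unexposed no-AT
  co <- make_records(sum(tab),
    at_outcome = rep(c(TRUE, FALSE, TRUE, FALSE), tab),
    prior_at = rep(c(TRUE, TRUE, FALSE, FALSE), tab))
  fit <- fit_logistic_adjusted(co, "prior_at")
  expect_equal(fit$estimate, odds_ratio_2x2(tab[1], tab[2], tab[3], tab[4])$estimate,
               tolerance = 1e-6)

  expect_error(fit_logistic_adjusted(make_records(20, at_outcome = TRUE,
                                                  prior_at = FALSE),
                                     "prior_at"),
               "degenerate|separation")
  expect_error(fit_logistic_adjusted(co, "no_such_column"), "configuration error")
})

test_that("adjusted logistic fit recovers a known odds ratio with surgeon effects", {
  # simulate: logit P(AT) = -0.5 + log(2) * x + surgeon offsets
  n <- 5000
  reps <- 40
  covered <- 0
  set.seed(77)
  for (r in seq_len(reps)) {
    x <- runif(n) < 0.4
    surgeon <- sample(paste0("S", 1:4), n, replace = TRUE)
    eta <- -0.5 + log(2) * x + c(S1 = 0, S2 = 0.6, S3 = -0.4, S4 = 0.2)[surgeon]
    co <- make_records(n, prior_at = x, surgeon_id = surgeon,
                       at_outcome = runif(n) < plogis(eta))
    fit <- fit_logistic_adjusted(co, "prior_at", covariate = "surgeon_id")
    if (fit$ci_low <= 2 && 2 <= fit$ci_high) covered <- covered + 1
  }
  # Wald 95% CI should cover the true OR of 2 in at least ~93% of replicates
  expect_gte(covered, ceiling(0.93 * reps) - 1)
})

test_that("evaluate_algorithm reproduces an engineered confusion matrix", {
  co <- make_records(20,
    tonsil_grade = rep(c(3, 3, 1, 1), c(8, 2, 2, 8)),
    at_outcome = rep(c(TRUE, FALSE, TRUE, FALSE), c(8, 2, 2, 8)))
  ev <- evaluate_algorithm(co, "tonsil")
  expect_equal(ev$confusion[c("tp", "fp", "fn", "tn")],
               list(tp = 8L, fp = 2L, fn = 2L, tn = 8L))
  expect_equal(ev$metrics$sensitivity, 0.8)
  expect_equal(ev$metrics$specificity, 0.8)

  # prior-AT-only cohort with no AT outcomes: sensitivity undefined
  ev_prior <- evaluate_algorithm(make_records(5, prior_at = TRUE,
                                              at_outcome = FALSE), "tonsil")
  expect_true(all(ev_prior$decisions$destination == "respirology"))
  expect_true(is.na(ev_prior$metrics$sensitivity))

  # record order does not change the metrics
  perm <- sample(nrow(co))
  ev2 <- evaluate_algorithm(co[perm, ], "tonsil")
  expect_equal(ev2$metrics, ev$metrics)

  rep_tab <- metrics_report(evaluate_algorithm(co, "tonsil"),
                            evaluate_algorithm(co, "psq"))
  expect_named(rep_tab, c("metric", "tonsil", "psq"))
  expect_equal(rep_tab$tonsil[rep_tab$metric == "sensitivity"], 0.8)
})
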