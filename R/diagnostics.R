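# Diagnostic-performance evaluation of a triage algorithm against observed
# adenotonsillectomy (AT) outcomes. Convention throughout: positive
# prediction = ENT referral, positive outcome = AT received — the only
# convention under which the published PPV equals the printed AT rate among
# ENT-routed children. Records with a missing AT outcome are excluded from
# the 2x2 with a reported tally.

#' Confusion matrix for triage decisions
#'
#' @param decisions an `osa_triage` data frame (or vector of destinations).
#' @param outcomes logical vector of observed AT outcomes, aligned to
#'   decisions; `NA` outcomes are excluded and counted.
#' @return list of class `confusion_matrix` with integer cells `tp` (ENT and
#'   AT), `fp` (ENT, no AT), `fn` (respirology, AT), `tn` (respirology, no
#'   AT) and `n_excluded`.
#' @export
confusion_matrix <- function(decisions, outcomes) {
  dest <- if (is.data.frame(decisions)) decisions$destination else decisions
  if (length(dest) != length(outcomes)) {
    stop("validation error: decisions and outcomes differ in length", call. = FALSE)
  }
  keep <- !is.na(outcomes)
  pos <- dest[keep] == "ENT"
  at <- outcomes[keep]
  structure(list(tp = sum(pos & at), fp = sum(pos & !at),
                 fn = sum(!pos & at), tn = sum(!pos & !at),
                 n_excluded = sum(!keep)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2,
              dimnames = list(triage = c("ENT", "respirology"),
                              outcome = c("AT", "no AT")))
  print(m)
  if (x$n_excluded > 0) cat(x$n_excluded, "record(s) excluded (missing outcome)\n")
  invisible(x)
}

.metric_set <- c("sensitivity", "specificity", "ppv", "npv", "fpr", "tnr",
                 "tpr", "fnr", "lr_positive", "lr_negative", "diagnostic_or")

#' Diagnostic metrics from a confusion matrix
#'
#' Computes the full metric set: sensitivity = tp/(tp+fn), specificity =
#' tn/(tn+fp), PPV = tp/(tp+fp), NPV = tn/(tn+fn), the rate aliases
#' (tpr/tnr/fpr/fnr), LR+ = sens/(1-spec), LR- = (1-sens)/spec, and the
#' diagnostic odds ratio (tp*tn)/(fp*fn) (`Inf` when fp*fn = 0 with a
#' positive numerator). A metric whose denominator is zero is returned as
#' `NA` (undefined, never fabricated).
#'
#' @param cm a [confusion_matrix()].
#' @return list of class `diagnostic_metrics`.
#' @export
diagnostic_metrics <- function(cm) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(cm$tp, cm$tp + cm$fn)
  spec <- ratio(cm$tn, cm$tn + cm$fp)
  dor <- if (cm$fp * cm$fn == 0) {
    if (cm$tp * cm$tn > 0) Inf else NA_real_
  } else (cm$tp * cm$tn) / (cm$fp * cm$fn)
  out <- list(
    sensitivity = sens, specificity = spec,
    ppv = ratio(cm$tp, cm$tp + cm$fp), npv = ratio(cm$tn, cm$tn + cm$fn),
    fpr = 1 - spec, tnr = spec, tpr = sens, fnr = 1 - sens,
    lr_positive = if (is.na(sens) || is.na(spec)) NA_real_
                  else if (spec < 1) sens / (1 - spec)
                  else if (sens > 0) Inf else NA_real_,
    lr_negative = if (is.na(sens) || is.na(spec)) NA_real_
                  else if (spec > 0) (1 - sens) / spec else NA_real_,
    diagnostic_or = dor,
    n_excluded = cm$n_excluded)
  class(out) <- "diagnostic_metrics"
  out
}

#' Diagnostic metrics implied by a sensitivity/specificity pair
#'
#' Closed-form identities that hold for any 2x2 table: the rate aliases,
#' LR+ = sens/(1-spec), LR- = (1-sens)/spec, and the diagnostic odds ratio
#' LR+/LR-. PPV and NPV are prevalence-dependent and therefore omitted.
#' Boundary values 0 and 1 give the forced limits (infinities where forced).
#'
#' @param sensitivity,specificity rates in \[0, 1\].
#' @return list of class `diagnostic_metrics` (ppv/npv absent).
#' @export
metrics_from_rates <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  lr_pos <- if (specificity < 1) sensitivity / (1 - specificity)
            else if (sensitivity > 0) Inf else NA_real_
  lr_neg <- if (specificity > 0) (1 - sensitivity) / specificity else NA_real_
  dor <- if (is.na(lr_neg) || is.na(lr_pos)) NA_real_
         else if (lr_neg > 0) lr_pos / lr_neg
         else if (lr_pos > 0) Inf else NA_real_
  out <- list(sensitivity = sensitivity, specificity = specificity,
              fpr = 1 - specificity, tnr = specificity,
              tpr = sensitivity, fnr = 1 - sensitivity,
              lr_positive = lr_pos, lr_negative = lr_neg,
              diagnostic_or = dor)
  class(out) <- "diagnostic_metrics"
  out
}

#' @export
print.diagnostic_metrics <- function(x, digits = 2, ...) {
  cat("Diagnostic metrics (positive = ENT referral, outcome = AT):\n")
  for (m in intersect(.metric_set, names(x))) {
    v <- x[[m]]
    cat(sprintf("  %-22s %s\n", m,
                if (is.na(v)) "undefined" else format(round_away(v, digits),
                                                      nsmall = digits)))
  }
  if (!is.null(x$n_excluded) && x$n_excluded > 0) {
    cat("  (", x$n_excluded, " record(s) excluded: missing outcome)\n", sep = "")
  }
  invisible(x)
}

#' Odds ratio from a 2x2 table
#'
#' Cross-product estimate `(a*d)/(b*c)` with a Wald confidence interval on
#' the log scale (standard error `sqrt(1/a+1/b+1/c+1/d)`). With
#' `correction = "haldane"` and any zero cell, 0.5 is added to every cell
#' before both the estimate and the interval.
#'
#' @param a,b,c,d cell counts: `a` exposed cases, `b` exposed non-cases,
#'   `c` unexposed cases, `d` unexposed non-cases. Alternatively `a` may be
#'   a length-4 vector or a `confusion_matrix` (cells tp, fp, fn, tn).
#' @param correction `"none"` or `"haldane"`.
#' @param alpha two-sided error rate for the interval (default 0.05).
#' @return list of class `odds_ratio` with `estimate`, `ci_low`, `ci_high`,
#'   `alpha`, `method`, `correction_applied`. With `correction = "none"` and
#'   two zero cells in the same margin the estimate is `NA` (undefined).
#' @export
odds_ratio_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                           correction = c("none", "haldane"), alpha = 0.05) {
  correction <- match.arg(correction)
  if (inherits(a, "confusion_matrix")) {
    cells <- c(a$tp, a$fp, a$fn, a$tn)
  } else if (length(a) == 4 && is.null(b)) {
    cells <- as.numeric(a)
  } else {
    cells <- c(a, b, c, d)
  }
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("validation error: cell counts must be non-negative", call. = FALSE)
  }
  applied <- correction == "haldane" && any(cells == 0)
  if (applied) cells <- cells + 0.5
  est <- if (cells[2] * cells[3] == 0) {
    if (cells[1] * cells[4] > 0) Inf else NA_real_
  } else (cells[1] * cells[4]) / (cells[2] * cells[3])
  if (!is.finite(est) || any(cells == 0)) {
    ci <- c(NA_real_, NA_real_)
  } else {
    se <- sqrt(sum(1 / cells))
    z <- qnorm(1 - alpha / 2)
    ci <- exp(log(est) + c(-1, 1) * z * se)
  }
  structure(list(estimate = est, ci_low = ci[1], ci_high = ci[2],
                 alpha = alpha, method = "cross_product",
                 correction_applied = applied),
            class = "odds_ratio")
}

#' @export
print.odds_ratio <- function(x, ...) {
  cat(sprintf("OR %s (%.0f%% CI %s-%s)%s [%s]\n",
              format(round_away(x$estimate, 2)), 100 * (1 - x$alpha),
              format(round_away(x$ci_low, 2)), format(round_away(x$ci_high, 2)),
              if (isTRUE(x$correction_applied)) " [Haldane-corrected]" else "",
              x$method))
  invisible(x)
}

#' Covariate-adjusted odds ratio by logistic regression
#'
#' Fits a maximum-likelihood logistic regression of the AT outcome on a
#' binary/categorical predictor, optionally adjusting for a categorical
#' covariate (the referring ENT surgeon, in the source setting) encoded as
#' indicator contrasts. Returns the exponentiated predictor coefficient with
#' a Wald 95% interval. Records with a missing outcome, predictor or
#' covariate are dropped.
#'
#' @param cohort an `osa_cohort` (or data frame with the columns).
#' @param predictor name of the predictor column.
#' @param covariate optional name of the adjustment covariate column.
#' @param alpha two-sided error rate for the interval.
#' @return list of class `odds_ratio` with `method = "logistic_adjusted"`.
#' @export
fit_logistic_adjusted <- function(cohort, predictor, covariate = NULL,
                                  alpha = 0.05) {
  df <- as.data.frame(cohort)
  for (col in c("at_outcome", predictor, covariate)) {
    if (!col %in% names(df)) {
      stop("configuration error: column '", col, "' not found", call. = FALSE)
    }
  }
  keep <- !is.na(df$at_outcome) & !is.na(df[[predictor]])
  if (!is.null(covariate)) keep <- keep & !is.na(df[[covariate]])
  df <- df[keep, , drop = FALSE]
  x <- df[[predictor]]
  if (!is.logical(x) && !is.factor(x)) x <- factor(x)
  if (length(unique(x)) < 2) {
    stop("degenerate predictor '", predictor,
         "': fewer than two observed levels", call. = FALSE)
  }
  dat <- data.frame(y = as.integer(df$at_outcome), x = x)
  form <- y ~ x
  if (!is.null(covariate)) {
    dat$z <- factor(df[[covariate]])
    form <- y ~ x + z
  }
  fit <- glm(form, family = binomial(), data = dat,
             control = list(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) {
    stop("logistic fit did not converge in ", fit$iter, " iterations",
         call. = FALSE)
  }
  beta <- coef(fit)[2]
  if (!is.finite(beta) || abs(beta) > 15) {
    stop("separation detected for predictor '", predictor,
         "' (|log-OR| > 15); odds ratio not estimable", call. = FALSE)
  }
  se <- sqrt(diag(vcov(fit)))[2]
  z <- qnorm(1 - alpha / 2)
  structure(list(estimate = unname(exp(beta)),
                 ci_low = unname(exp(beta - z * se)),
                 ci_high = unname(exp(beta + z * se)),
                 alpha = alpha, method = "logistic_adjusted",
                 correction_applied = FALSE, n = nrow(dat)),
            class = "odds_ratio")
}

#' Evaluate a triage algorithm on a cohort
#'
#' Composition of [apply_algorithm()], [confusion_matrix()] and
#' [diagnostic_metrics()], producing the published model-metrics layout.
#'
#' @param cohort an `osa_cohort` with observed `at_outcome` (missing outcomes
#'   are excluded with a reported tally).
#' @param algorithm `"psq"`, `"tonsil"` or `"tonsil_oximetry"`.
#' @return list of class `osa_evaluation`: `algorithm`, `decisions`,
#'   `confusion` and `metrics`.
#' @export
evaluate_algorithm <- function(cohort, algorithm = c("psq", "tonsil", "tonsil_oximetry")) {
  decisions <- apply_algorithm(cohort, algorithm)
  cm <- confusion_matrix(decisions, cohort$at_outcome)
  structure(list(algorithm = decisions$algorithm[1] %||% algorithm[1],
                 decisions = decisions, confusion = cm,
                 metrics = diagnostic_metrics(cm)),
            class = "osa_evaluation")
}

#' @export
print.osa_evaluation <- function(x, ...) {
  cat("Evaluation of the", x$algorithm, "triage algorithm\n")
  print(x$confusion)
  print(x$metrics)
  invisible(x)
}

# Table-shaped export of one or more evaluations (rows = metric names,
# columns = algorithms), values rounded half away from zero to 2 d.p. for
# display; full precision stays in the evaluation objects.
#' Metric report table
#'
#' @param ... one or more `osa_evaluation` objects.
#' @param digits display rounding (half away from zero).
#' @return data frame with one row per metric, one column per algorithm.
#' @export
metrics_report <- function(..., digits = 2) {
  evals <- list(...)
  cols <- lapply(evals, function(e) {
    vapply(.metric_set, function(m) {
      v <- e$metrics[[m]]
      if (is.null(v) || is.na(v)) NA_real_ else round_away(v, digits)
    }, 0)
  })
  out <- data.frame(metric = .metric_set)
  for (i in seq_along(evals)) out[[evals[[i]]$algorithm]] <- cols[[i]]
  out
}
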