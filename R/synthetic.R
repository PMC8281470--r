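# Calibrated synthetic cohort generator. The defaults emulate the published
# clinic sample: its marginal prevalences (47% female, mean age 8.19 y,
# 89% ever snore, 18/469 prior AT), the tonsil-grade and oximetry strata of
# the published tree figures, the per-stratum AT probabilities (78%/50%/71%
# within tonsil 2-4 by MOS; 17% for grades 0-1), and the per-outcome screen
# positivity rates of the demographics table. Screen flags are drawn
# conditionally on the AT outcome because those conditional proportions are
# the only joint information the source reports.

#' Cohort calibration
#'
#' All prevalence and conditional-probability parameters the synthetic
#' generator draws from. Every field is overridable; the defaults are the
#' published cohort's values, with gaps filled by documented choices (see
#' the methods vignette).
#'
#' @param n cohort size.
#' @param p_female probability of female sex.
#' @param age_mean,age_sd years; ages are drawn truncated-normal on
#'   \[0.5, 18).
#' @param p_prior_at probability of a prior adenotonsillectomy.
#' @param p_ever_snore_given_at length-2 vector: P(ever snore | AT),
#'   P(ever snore | no AT).
#' @param p_snore_half_given_ever P(snores > half the night | ever snores).
#' @param tonsil_grade_probs probability vector over grades 0-4 and missing
#'   (names `g0`..`g4`, `missing`), summing to 1.
#' @param mos_probs_tonsil24 probability vector (`mos2plus`, `mos1`,
#'   `missing`) for children with tonsil grade 2-4.
#' @param mos_probs_other same three probabilities outside tonsil 2-4.
#' @param mos2plus_split probabilities over MOS 2/3/4 within "2 or more".
#' @param at_rates named list of per-stratum AT probabilities:
#'   `tonsil24_mos24`, `tonsil24_mos1`, `tonsil24_mos_missing`, `tonsil01`,
#'   `tonsil_missing`, `prior_at`.
#' @param screen_rates named list; each element a length-2 vector
#'   c(P(positive | AT), P(positive | no AT)) for `struggle`, `apneas`,
#'   `mouth_breathe`, `dry_mouth`, `rls`, `gerd`, `nose`.
#' @param psq_item_corr exchangeable pairwise correlation among the four PSQ
#'   item draws within an outcome stratum (Gaussian-copula; default 0,
#'   i.e. conditionally independent).
#' @param psq_stratum_weights,psq_stratum_rates routing-stratum weights and
#'   AT rates of the PSQ tree, used only by [stratum_expected_metrics()]
#'   (defaults: the published stratum sizes 18/66/318/33/3/31 over 469 and
#'   rates 0/.56/.25/.32/.50/.10).
#' @param n_surgeons number of referring-surgeon levels (uniform).
#' @param seed integer seed; all randomness flows from it through a
#'   documented per-field sub-seeding scheme.
#' @return list of class `cohort_calibration`.
#' @export
cohort_calibration <- function(
    n = 469,
    p_female = 0.47,
    age_mean = 8.19, age_sd = 3.59,
    p_prior_at = 18 / 469,
    p_ever_snore_given_at = c(134 / 143, 261 / 300),
    p_snore_half_given_ever = 306 / 418,
    tonsil_grade_probs = c(g0 = 3, g1 = 60, g2 = 80, g3 = 52, g4 = 35,
                           missing = 239) / 469,
    mos_probs_tonsil24 = c(mos2plus = 21, mos1 = 122, missing = 24) / 167,
    mos_probs_other = c(mos2plus = 0.03, mos1 = 0.47, missing = 0.50),
    mos2plus_split = c(0.60, 0.25, 0.15),
    at_rates = list(tonsil24_mos24 = 0.78, tonsil24_mos1 = 0.50,
                    tonsil24_mos_missing = 0.71, tonsil01 = 0.17,
                    tonsil_missing = 0.17, prior_at = 0),
    screen_rates = list(struggle = c(80 / 143, 113 / 300),
                        apneas = c(66 / 143, 81 / 300),
                        mouth_breathe = c(107 / 143, 169 / 300),
                        dry_mouth = c(89 / 143, 144 / 300),
                        rls = c(122 / 143, 247 / 300),
                        gerd = c(28 / 143, 79 / 300),
                        nose = c(117 / 143, 201 / 300)),
    psq_item_corr = 0,
    psq_stratum_weights = c(prior_at = 18, psq_4of4 = 66, rls = 318,
                            gerd_nose = 33, psq_3of4 = 3, residual = 31) / 469,
    psq_stratum_rates = c(prior_at = 0, psq_4of4 = 0.56, rls = 0.25,
                          gerd_nose = 0.32, psq_3of4 = 0.50, residual = 0.10),
    n_surgeons = 4,
    seed = 1) {
  probs <- c(p_female, p_prior_at, p_ever_snore_given_at,
             p_snore_half_given_ever, tonsil_grade_probs, mos_probs_tonsil24,
             mos_probs_other, mos2plus_split, unlist(at_rates),
             unlist(screen_rates), psq_stratum_weights, psq_stratum_rates)
  if (any(is.na(probs)) || any(probs < 0 | probs > 1)) {
    stop("validation error: all calibration probabilities must be in [0, 1]",
         call. = FALSE)
  }
  for (v in list(tonsil_grade_probs, mos_probs_tonsil24, mos_probs_other,
                 mos2plus_split, psq_stratum_weights)) {
    if (abs(sum(v) - 1) > 1e-12) {
      stop("validation error: probability vector does not sum to 1", call. = FALSE)
    }
  }
  stopifnot(n >= 0, n_surgeons >= 1, psq_item_corr >= 0, psq_item_corr < 1)
  structure(as.list(environment())[c(
    "n", "p_female", "age_mean", "age_sd", "p_prior_at",
    "p_ever_snore_given_at", "p_snore_half_given_ever", "tonsil_grade_probs",
    "mos_probs_tonsil24", "mos_probs_other", "mos2plus_split", "at_rates",
    "screen_rates", "psq_item_corr", "psq_stratum_weights",
    "psq_stratum_rates", "n_surgeons", "seed")],
    class = "cohort_calibration")
}

# Correlated Bernoulli items via an exchangeable Gaussian copula; rho = 0
# reduces to independent draws.
.draw_items <- function(p_matrix, rho) {
  n <- nrow(p_matrix); k <- ncol(p_matrix)
  if (rho <= 0) {
    m <- matrix(runif(n * k), n, k) < p_matrix
  } else {
    common <- rnorm(n)
    z <- sqrt(rho) * common + sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
    m <- pnorm(z) < p_matrix
  }
  m
}

#' Generate a synthetic cohort
#'
#' Draws `n` independent records: demographics from the stated marginals;
#' tonsil grade from the grade distribution; MOS conditional on the tonsil
#' stratum; the AT outcome Bernoulli from the record's (prior-AT, tonsil,
#' MOS) stratum probability; screen answers conditional on the drawn
#' outcome. A fixed seed reproduces the cohort exactly, and each field block
#' has its own derived sub-seed so individual fields are reproducible in
#' isolation.
#'
#' @param calibration a [cohort_calibration()].
#' @return an [as_cohort()] cohort with provenance recording the seed.
#' @export
generate_cohort <- function(calibration = cohort_calibration()) {
  stopifnot(inherits(calibration, "cohort_calibration"))
  cal <- calibration
  n <- cal$n
  if (n == 0) {
    return(as_cohort(data.frame(patient_id = character()),
                     provenance = paste0("synthetic(seed=", cal$seed, ")")))
  }
  blk <- function(k, code) with_seed(derive_seed(cal$seed, k), code)

  sex <- blk(1, ifelse(runif(n) < cal$p_female, "female", "male"))
  age <- blk(2, {
    lo <- stats::pnorm(0.5, cal$age_mean, cal$age_sd)
    hi <- stats::pnorm(18, cal$age_mean, cal$age_sd)
    stats::qnorm(runif(n, lo, hi), cal$age_mean, cal$age_sd)
  })
  prior_at <- blk(3, runif(n) < cal$p_prior_at)
  grade_lv <- c(0, 1, 2, 3, 4, NA)
  tonsil <- blk(4, grade_lv[sample.int(6, n, replace = TRUE,
                                       prob = cal$tonsil_grade_probs)])
  t24 <- !is.na(tonsil) & tonsil >= 2
  mos <- blk(5, {
    cat3 <- integer(n)  # 1 = MOS 2+, 2 = MOS 1, 3 = missing
    cat3[t24] <- sample.int(3, sum(t24), replace = TRUE,
                            prob = cal$mos_probs_tonsil24)
    cat3[!t24] <- sample.int(3, sum(!t24), replace = TRUE,
                             prob = cal$mos_probs_other)
    m <- rep(NA_integer_, n)
    m[cat3 == 2] <- 1L
    k1 <- sum(cat3 == 1)
    m[cat3 == 1] <- c(2L, 3L, 4L)[sample.int(3, k1, replace = TRUE,
                                             prob = cal$mos2plus_split)]
    m
  })
  p_at <- numeric(n)
  p_at[t24 & !is.na(mos) & mos >= 2] <- cal$at_rates$tonsil24_mos24
  p_at[t24 & !is.na(mos) & mos == 1] <- cal$at_rates$tonsil24_mos1
  p_at[t24 & is.na(mos)] <- cal$at_rates$tonsil24_mos_missing
  p_at[!is.na(tonsil) & tonsil <= 1] <- cal$at_rates$tonsil01
  p_at[is.na(tonsil)] <- cal$at_rates$tonsil_missing
  p_at[prior_at] <- cal$at_rates$prior_at
  at <- blk(6, runif(n) < p_at)

  sr <- cal$screen_rates
  pick <- function(rates) ifelse(at, rates[1], rates[2])
  psq <- blk(7, .draw_items(cbind(pick(sr$struggle), pick(sr$apneas),
                                  pick(sr$mouth_breathe), pick(sr$dry_mouth)),
                            cal$psq_item_corr))
  screens <- blk(8, {
    rls_pos <- runif(n) < pick(sr$rls)
    gerd_pos <- runif(n) < pick(sr$gerd)
    nose_pos <- runif(n) < pick(sr$nose)
    list(
      rls = ifelse(rls_pos, 1L + rbinom(n, 2, 0.3), 0L),
      gerd = ifelse(gerd_pos, 2L + rbinom(n, 3, 0.3), rbinom(n, 1, 0.4)),
      nose = ifelse(nose_pos, 10L + as.integer(floor(runif(n, 0, 91))),
                    as.integer(floor(runif(n, 0, 10)))))
  })
  snore <- blk(9, {
    ever <- runif(n) < pick(cal$p_ever_snore_given_at)
    half <- ever & (runif(n) < cal$p_snore_half_given_ever)
    list(ever = ever, half = half)
  })
  surgeon <- blk(10, paste0("S", sample.int(cal$n_surgeons, n, replace = TRUE)))

  as_cohort(data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    age_years = round(age, 2), sex = sex, prior_at = prior_at,
    ever_snore = snore$ever, snore_half_night = snore$half,
    psq_struggle_breathe = psq[, 1], psq_witnessed_apneas = psq[, 2],
    psq_daytime_mouth_breathing = psq[, 3], psq_am_dry_mouth = psq[, 4],
    rls_symptom_count = screens$rls, gerd_symptom_count = screens$gerd,
    nose_score = screens$nose, tonsil_grade = tonsil, mos = mos,
    surgeon_id = surgeon, at_outcome = at,
    stringsAsFactors = FALSE),
    provenance = paste0("synthetic(seed=", cal$seed, ", n=", n, ")"))
}

#' Generate a synthetic oximetry trace for a target McGill score
#'
#' Builds an overnight SpO2 trace (baseline near 97% with physiologic noise)
#' that scores to `target_mos` under the supplied configuration: for targets
#' 2-4 it inserts the required number of desaturation clusters, each with
#' one event more than the per-cluster minimum, with nadirs strictly inside
#' the target tier's band (86-89 for 2, 81-84 for 3, 72-79 for 4 under the
#' defaults); for target 1 no qualifying structure is inserted.
#'
#' @param target_mos integer 1-4.
#' @param duration trace length, seconds (default 2 h of synthetic night).
#' @param seed integer seed (deterministic output).
#' @param config an [mos_config()].
#' @param sampling_interval seconds between samples (default 2).
#' @return an [oximetry_trace()].
#' @export
generate_trace <- function(target_mos, duration = 7200, seed = 1,
                           config = mos_config(), sampling_interval = 2) {
  stopifnot(target_mos %in% 1:4)
  n_ev <- config$min_events_per_cluster + 1L
  ev_len <- 30; ev_gap <- 60
  cl_len <- n_ev * ev_len + (n_ev - 1) * ev_gap
  cl_gap <- config$cluster_window + 300
  lead <- max(2 * config$baseline_window, 300)
  needed <- lead + config$required_clusters * cl_len +
    (config$required_clusters - 1) * cl_gap + lead
  if (target_mos > 1 && duration < needed) {
    stop("validation error: duration ", duration, " s too short; need >= ",
         ceiling(needed), " s for ", config$required_clusters, " clusters",
         call. = FALSE)
  }
  with_seed(seed, {
    time <- seq(0, duration - sampling_interval, by = sampling_interval)
    n <- length(time)
    spo2 <- pmin(100, pmax(94, 97 + rnorm(n, 0, 0.4)))
    if (target_mos > 1) {
      dt <- config$depth_thresholds
      band <- switch(as.character(target_mos),
                     "2" = c(dt[["mos3"]] + 1, dt[["mos2"]] - 1),
                     "3" = c(dt[["mos4"]] + 1, dt[["mos3"]] - 1),
                     "4" = c(dt[["mos4"]] - 8, dt[["mos4"]] - 1))
      for (ci in seq_len(config$required_clusters)) {
        cl_start <- lead + (ci - 1) * (cl_len + cl_gap)
        for (ei in seq_len(n_ev)) {
          t0 <- cl_start + (ei - 1) * (ev_len + ev_gap)
          nadir <- runif(1, band[1], band[2])
          idx <- which(time >= t0 & time < t0 + ev_len)
          if (!length(idx)) next
          # trapezoid dip: 8 s descent, nadir plateau, 8 s recovery
          tt <- time[idx] - t0
          frac <- pmin(1, pmin(tt / 8, (ev_len - tt) / 8))
          frac <- pmax(0, frac)
          spo2[idx] <- 97 - frac * (97 - nadir)
        }
      }
    }
    oximetry_trace(time, spo2, sampling_interval)
  })
}

#' Population diagnostic metrics implied by a calibration
#'
#' Closed-form sensitivity, specificity, PPV and NPV of a triage algorithm
#' under the calibration's stratum structure, by total probability over the
#' routing strata. This is the analytic oracle that empirical metrics on
#' large generated cohorts converge to (for the tonsil-based algorithms,
#' whose strata the generator parameterises directly; for the PSQ tree the
#' published stratum weights/rates are used — see the methods vignette).
#'
#' @param calibration a [cohort_calibration()].
#' @param algorithm `"psq"`, `"tonsil"` or `"tonsil_oximetry"`.
#' @return list of class `diagnostic_metrics` with an attached `strata`
#'   attribute (weight, AT rate and destination per stratum).
#' @export
stratum_expected_metrics <- function(calibration = cohort_calibration(),
                                     algorithm = c("psq", "tonsil", "tonsil_oximetry")) {
  algorithm <- match.arg(algorithm)
  cal <- calibration
  if (algorithm == "psq") {
    w <- cal$psq_stratum_weights
    r <- cal$psq_stratum_rates[names(w)]
    if (anyNA(r)) stop("configuration error: psq stratum rates do not cover weights",
                       call. = FALSE)
    ent <- names(w) %in% c("psq_4of4", "psq_3of4")
    strata <- data.frame(stratum = names(w), weight = as.numeric(w),
                         at_rate = as.numeric(r),
                         destination = ifelse(ent, "ENT", "respirology"))
  } else {
    pp <- cal$p_prior_at
    tg <- cal$tonsil_grade_probs
    p24 <- sum(tg[c("g2", "g3", "g4")])
    p01 <- sum(tg[c("g0", "g1")])
    pm <- tg[["missing"]]
    m24 <- cal$mos_probs_tonsil24
    strata <- data.frame(
      stratum = c("prior_at", "tonsil24_mos24", "tonsil24_mos1",
                  "tonsil24_mos_missing", "tonsil01", "tonsil_missing"),
      weight = c(pp, (1 - pp) * p24 * m24[["mos2plus"]],
                 (1 - pp) * p24 * m24[["mos1"]],
                 (1 - pp) * p24 * m24[["missing"]],
                 (1 - pp) * p01, (1 - pp) * pm),
      at_rate = c(cal$at_rates$prior_at, cal$at_rates$tonsil24_mos24,
                  cal$at_rates$tonsil24_mos1, cal$at_rates$tonsil24_mos_missing,
                  cal$at_rates$tonsil01, cal$at_rates$tonsil_missing),
      destination = c("respirology", "ENT", "ENT", "ENT",
                      "respirology", "respirology"))
  }
  if (abs(sum(strata$weight) - 1) > 1e-9) {
    stop("configuration error: routing strata do not cover the population",
         call. = FALSE)
  }
  p_at <- sum(strata$weight * strata$at_rate)
  ent <- strata$destination == "ENT"
  p_ent_at <- sum(strata$weight[ent] * strata$at_rate[ent])
  p_ent <- sum(strata$weight[ent])
  clamp01 <- function(x) min(1, max(0, x))
  sens <- if (p_at > 0) clamp01(p_ent_at / p_at) else NA_real_
  spec <- if (p_at < 1) clamp01((1 - p_ent - (p_at - p_ent_at)) / (1 - p_at))
          else NA_real_
  out <- if (!is.na(sens) && !is.na(spec)) {
    metrics_from_rates(sens, spec)
  } else {
    structure(list(sensitivity = sens, specificity = spec),
              class = "diagnostic_metrics")
  }
  out$ppv <- if (p_ent > 0) p_ent_at / p_ent else NA_real_
  out$npv <- if (p_ent < 1) 1 - (p_at - p_ent_at) / (1 - p_ent) else NA_real_
  attr(out, "strata") <- strata
  out
}
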