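# Deterministic scoring of the questionnaire screens into the binary flags
# the triage trees consume. Missingness propagates; no imputation here — the
# triage module decides how a missing flag routes.

.psq_items <- c("psq_struggle_breathe", "psq_witnessed_apneas",
                "psq_daytime_mouth_breathing", "psq_am_dry_mouth")

#' Score the four discriminative PSQ items
#'
#' Counts "yes" answers among the four Pediatric Sleep Questionnaire items
#' that discriminate for adenotonsillectomy: struggles to breathe at night,
#' witnessed apneas, daytime mouth breathing, and morning dry mouth. Items
#' with missing answers count in neither the positive nor the answered tally,
#' so `positive <= answered <= 4` always holds.
#'
#' @param record one-row data frame (or a cohort; then vectors are returned).
#' @return list with integer elements `positive` and `answered`.
#' @export
score_psq_four <- function(record) {
  yes <- rep(0L, nrow(as.data.frame(record)))
  ans <- yes
  for (item in .psq_items) {
    x <- record[[item]]
    if (is.null(x)) x <- rep(NA, length(yes))
    yes <- yes + as.integer(!is.na(x) & x)
    ans <- ans + as.integer(!is.na(x))
  }
  list(positive = yes, answered = ans)
}

#' Restless-leg-syndrome screen flag
#'
#' Positive when at least one RLS symptom is endorsed.
#'
#' @param rls_symptom_count non-negative integer symptom count (vectorised);
#'   missing propagates.
#' @return logical (or NA).
#' @export
rls_flag <- function(rls_symptom_count) {
  if (any(!is.na(rls_symptom_count) & rls_symptom_count < 0)) {
    stop("validation error: rls_symptom_count must be non-negative", call. = FALSE)
  }
  rls_symptom_count >= 1
}

#' Gastroesophageal-reflux screen flag
#'
#' Positive when two or more GERD symptoms are endorsed.
#'
#' @param gerd_symptom_count non-negative integer symptom count (vectorised);
#'   missing propagates.
#' @return logical (or NA).
#' @export
gerd_flag <- function(gerd_symptom_count) {
  if (any(!is.na(gerd_symptom_count) & gerd_symptom_count < 0)) {
    stop("validation error: gerd_symptom_count must be non-negative", call. = FALSE)
  }
  gerd_symptom_count >= 2
}

#' Nasal-obstruction (NOSE) screen flag
#'
#' Positive at a NOSE score of 10 or greater (significant rhinitis symptoms).
#' The instrument range is 0-100.
#'
#' @param nose_score integer score 0-100 (vectorised); missing propagates.
#' @return logical (or NA).
#' @export
nose_flag <- function(nose_score) {
  if (any(!is.na(nose_score) & (nose_score < 0 | nose_score > 100))) {
    stop("validation error: nose_score must be in 0-100", call. = FALSE)
  }
  nose_score >= 10
}

#' Compute all screen flags for a cohort
#'
#' @param cohort an `osa_cohort` (or any data frame with the screen columns).
#' @return data frame with one row per record: `psq_positive_count`,
#'   `psq_answered_count`, `rls_positive`, `gerd_positive`, `nose_positive`.
#' @export
screen_flags <- function(cohort) {
  psq <- score_psq_four(cohort)
  data.frame(
    psq_positive_count = psq$positive,
    psq_answered_count = psq$answered,
    rls_positive = rls_flag(cohort$rls_symptom_count),
    gerd_positive = gerd_flag(cohort$gerd_symptom_count),
    nose_positive = nose_flag(cohort$nose_score)
  )
}
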