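# The three published triage decision trees mapping a child's screening data
# to a referral destination (ENT vs pediatric respirology), a risk stratum,
# and an auditable rule path.
#
# All three trees start with the same rule: a child with a prior
# adenotonsillectomy (AT) goes to respirology, because no child with a prior
# AT required a second one in the source cohort.
#
# Published stratum AT rates are attached to decisions as reporting metadata
# (expected_at_rate); they never influence routing.

.stratum_meta <- data.frame(
  label = c("prior_at", "psq_4of4", "rls", "gerd_nose", "psq_3of4", "residual",
            "tonsil_2to4", "tonsil_0or1", "tonsil_missing",
            "tonsil24_mos24", "tonsil24_mos1", "tonsil24_mos_missing"),
  destination = c("respirology", "ENT", "respirology", "respirology", "ENT",
                  "respirology", "ENT", "respirology", "respirology",
                  "ENT", "ENT", "ENT"),
  risk_stratum = c("not_applicable", "not_applicable", "not_applicable",
                   "not_applicable", "not_applicable", "not_applicable",
                   "not_applicable", "low", "not_applicable",
                   "high", "intermediate", "unknown_oximetry"),
  expected_at_rate = c(0.00, 0.56, 0.25, 0.32, 0.50, 0.10,
                       0.56, 0.17, NA,
                       0.78, 0.50, 0.71),
  stringsAsFactors = FALSE
)

.tree_rules <- list(
  psq = c("prior_at", "psq_4of4", "rls", "gerd_nose", "psq_3of4", "residual"),
  tonsil = c("prior_at", "tonsil_2to4", "tonsil_0or1", "tonsil_missing"),
  # destination rules identical to the tonsil tree; the MOS rules only
  # stratify risk within the ENT arm
  tonsil_oximetry = c("prior_at", "tonsil_2to4", "tonsil_0or1", "tonsil_missing",
                      "tonsil24_mos24", "tonsil24_mos1", "tonsil24_mos_missing")
)

# Single-record rule predicates; missing screen flags are "not positive"
# (the rule does not fire), pushing the child toward later rules — every
# child is routed, none excluded for missing questionnaires.
.rule_predicate <- function(rule, record, flags) {
  tg <- record$tonsil_grade
  mos <- record$mos
  switch(rule,
    prior_at = isTRUE(record$prior_at),
    psq_4of4 = flags$psq_positive_count == 4,
    rls = isTRUE(flags$rls_positive),
    gerd_nose = isTRUE(flags$gerd_positive) || isTRUE(flags$nose_positive),
    psq_3of4 = flags$psq_positive_count == 3,
    residual = TRUE,
    tonsil_2to4 = !is.na(tg) && tg >= 2,
    tonsil_0or1 = !is.na(tg) && tg <= 1,
    tonsil_missing = is.na(tg),
    tonsil24_mos24 = !is.na(mos) && mos >= 2,
    tonsil24_mos1 = !is.na(mos) && mos == 1,
    tonsil24_mos_missing = is.na(mos),
    stop("unknown rule: ", rule, call. = FALSE))
}

.path_string <- function(rules, fired_at) {
  paste0(rules[seq_len(fired_at)], "=",
         c(rep(0L, fired_at - 1L), 1L), collapse = ";")
}

.decision_frame <- function(cohort, algorithm, label, rule_path) {
  meta <- .stratum_meta[match(label, .stratum_meta$label), ]
  structure(
    data.frame(patient_id = cohort$patient_id,
               algorithm = rep(algorithm, length(label)),
               destination = meta$destination,
               risk_stratum = meta$risk_stratum,
               stratum_label = label,
               expected_at_rate = meta$expected_at_rate,
               rule_path = rule_path,
               stringsAsFactors = FALSE),
    class = c("osa_triage", "data.frame"))
}

triage_psq_cohort <- function(cohort, flags = screen_flags(cohort)) {
  prior <- !is.na(cohort$prior_at) & cohort$prior_at
  p4 <- flags$psq_positive_count == 4
  rls <- !is.na(flags$rls_positive) & flags$rls_positive
  gn <- (!is.na(flags$gerd_positive) & flags$gerd_positive) |
        (!is.na(flags$nose_positive) & flags$nose_positive)
  p3 <- flags$psq_positive_count == 3
  fired <- ifelse(prior, 1L,
           ifelse(p4, 2L,
           ifelse(rls, 3L,
           ifelse(gn, 4L,
           ifelse(p3, 5L, 6L)))))
  rules <- .tree_rules$psq
  paths <- vapply(1:6, function(k) .path_string(rules, k), "")
  .decision_frame(cohort, "psq", rules[fired], paths[fired])
}

triage_tonsil_cohort <- function(cohort) {
  prior <- !is.na(cohort$prior_at) & cohort$prior_at
  tg <- cohort$tonsil_grade
  fired <- ifelse(prior, 1L,
           ifelse(!is.na(tg) & tg >= 2, 2L,
           ifelse(!is.na(tg), 3L, 4L)))
  rules <- .tree_rules$tonsil
  paths <- vapply(1:4, function(k) .path_string(rules, k), "")
  .decision_frame(cohort, "tonsil", rules[fired], paths[fired])
}

triage_tonsil_oximetry_cohort <- function(cohort) {
  base <- triage_tonsil_cohort(cohort)
  ent <- base$destination == "ENT"
  mos <- cohort$mos
  label <- base$stratum_label
  label[ent] <- ifelse(!is.na(mos[ent]) & mos[ent] >= 2, "tonsil24_mos24",
                ifelse(!is.na(mos[ent]), "tonsil24_mos1", "tonsil24_mos_missing"))
  mos_rules <- c("tonsil24_mos24", "tonsil24_mos1", "tonsil24_mos_missing")
  mos_paths <- vapply(1:3, function(k) .path_string(mos_rules, k), "")
  path <- base$rule_path
  path[ent] <- paste(path[ent], mos_paths[match(label[ent], mos_rules)], sep = ";")
  .decision_frame(cohort, "tonsil_oximetry", label, path)
}

#' Triage by the four-item PSQ tree
#'
#' Fixed rule order: (1) prior AT -> respirology; (2) 4/4 PSQ items positive
#' -> ENT; (3) at least one RLS symptom -> respirology; (4) GERD screen or
#' NOSE screen positive -> respirology; (5) 3/4 PSQ items positive -> ENT;
#' (6) otherwise respirology. Missing screen flags count as "not positive".
#'
#' @param record a one-row cohort data frame.
#' @param flags optional precomputed [screen_flags()] row for the record.
#' @return one-row decision data frame (class `osa_triage`) with destination,
#'   risk stratum, terminal stratum label, the published stratum AT rate as
#'   `expected_at_rate`, and the evaluated `rule_path`.
#' @export
triage_psq <- function(record, flags = screen_flags(record)) {
  triage_psq_cohort(record, flags)
}

#' Triage by the tonsil-size tree
#'
#' Prior AT -> respirology; Brodsky tonsil grade 2-4 -> ENT; grade 0-1 ->
#' respirology; missing grade -> respirology.
#'
#' @inheritParams triage_psq
#' @return one-row `osa_triage` decision.
#' @export
triage_tonsil <- function(record) {
  triage_tonsil_cohort(record)
}

#' Triage by the tonsil-size tree with oximetry risk stratification
#'
#' The destination is identical to [triage_tonsil()] for every input —
#' oximetry never changes which specialty a child is referred to. Within the
#' ENT arm the McGill oximetry score stratifies AT risk: MOS 2-4 is the
#' high-risk stratum (published AT rate 78%), MOS 1 intermediate (50%), and
#' missing oximetry an unknown-oximetry stratum (71%).
#'
#' @inheritParams triage_psq
#' @return one-row `osa_triage` decision.
#' @export
triage_tonsil_oximetry <- function(record) {
  triage_tonsil_oximetry_cohort(record)
}

#' Apply a triage algorithm to a whole cohort
#'
#' @param cohort an `osa_cohort`.
#' @param algorithm one of `"psq"`, `"tonsil"`, `"tonsil_oximetry"`.
#' @return data frame of class `osa_triage`, one decision per record in
#'   cohort order, with destination/stratum summary counts attached as the
#'   `"summary"` attribute.
#' @export
apply_algorithm <- function(cohort, algorithm = c("psq", "tonsil", "tonsil_oximetry")) {
  if (length(algorithm) == 1 && !algorithm %in% .algorithms()) {
    stop("configuration error: unknown algorithm '", algorithm,
         "'; valid choices: ", paste(.algorithms(), collapse = ", "),
         call. = FALSE)
  }
  algorithm <- match.arg(algorithm)
  if (nrow(cohort) == 0) {
    out <- .decision_frame(cohort, algorithm, character(), character())
  } else {
    out <- switch(algorithm,
                  psq = triage_psq_cohort(cohort),
                  tonsil = triage_tonsil_cohort(cohort),
                  tonsil_oximetry = triage_tonsil_oximetry_cohort(cohort))
  }
  attr(out, "summary") <- table(destination = out$destination,
                                stratum = out$stratum_label)
  out
}

.algorithms <- function() c("psq", "tonsil", "tonsil_oximetry")

#' Replay a recorded rule path
#'
#' Re-evaluates every rule recorded in a decision's `rule_path` against the
#' record it was produced from and checks that each recorded outcome and the
#' final destination are reproduced. Used to audit decisions.
#'
#' @param record the one-row cohort data frame the decision came from.
#' @param decision the corresponding one-row `osa_triage` decision.
#' @return `TRUE` if the replay reproduces the decision, else `FALSE`.
#' @export
replay_rule_path <- function(record, decision) {
  flags <- screen_flags(record)
  steps <- strsplit(decision$rule_path, ";", fixed = TRUE)[[1]]
  parts <- strsplit(steps, "=", fixed = TRUE)
  for (p in parts) {
    got <- .rule_predicate(p[1], record, flags)
    if (!identical(as.integer(got), as.integer(p[2] == "1"))) return(FALSE)
  }
  terminal <- parts[[length(parts)]][1]
  identical(.stratum_meta$destination[.stratum_meta$label == terminal],
            decision$destination)
}

#' @export
print.osa_triage <- function(x, ...) {
  cat(sprintf("Triage decisions (%s algorithm): %d children\n",
              if (nrow(x)) x$algorithm[1] else "?", nrow(x)))
  if (nrow(x)) print(table(x$destination))
  invisible(x)
}
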