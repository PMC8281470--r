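# Cohort container: a data.frame of one row per child with the canonical
# columns below, classed "osa_cohort". All screening inputs are optional and
# may be missing; analysis-time pooling (e.g. tonsil grades 3+4) happens in
# the modules that need it, never at storage time.

.cohort_columns <- c(
  "patient_id", "age_years", "sex", "prior_at",
  "ever_snore", "snore_half_night",
  "psq_struggle_breathe", "psq_witnessed_apneas",
  "psq_daytime_mouth_breathing", "psq_am_dry_mouth",
  "rls_symptom_count", "gerd_symptom_count", "nose_score",
  "tonsil_grade", "mos", "surgeon_id", "at_outcome"
)

.ternary_columns <- c(
  "prior_at", "ever_snore", "snore_half_night",
  "psq_struggle_breathe", "psq_witnessed_apneas",
  "psq_daytime_mouth_breathing", "psq_am_dry_mouth", "at_outcome"
)

.count_columns <- c("rls_symptom_count", "gerd_symptom_count", "nose_score",
                    "tonsil_grade", "mos")

#' Construct a cohort from a data frame
#'
#' Coerces a data frame to the canonical cohort layout: one row per child,
#' columns for demographics, the four discriminative PSQ items, RLS/GERD/NOSE
#' screen raw values, Brodsky tonsil grade (0-4), McGill oximetry score (1-4),
#' prior adenotonsillectomy (AT) flag, referring surgeon id and the observed
#' AT outcome. Missing columns are created as all-missing; extra columns are
#' dropped. Out-of-range tonsil grades or MOS values are rejected.
#'
#' @param df data frame with any subset of the canonical columns (plus
#'   `patient_id`, which is required and must be unique).
#' @param provenance free-text label recording where the cohort came from
#'   (file path, or generator seed).
#' @return An object of class `osa_cohort` (a data frame).
#' @export
as_cohort <- function(df, provenance = "unspecified") {
  stopifnot(is.data.frame(df))
  if (!"patient_id" %in% names(df)) {
    stop("configuration error: required column 'patient_id' is missing", call. = FALSE)
  }
  n <- nrow(df)
  out <- data.frame(patient_id = parse_chr(df$patient_id),
                    stringsAsFactors = FALSE)
  out$age_years <- if ("age_years" %in% names(df)) parse_num(df$age_years) else rep(NA_real_, n)
  out$sex <- if ("sex" %in% names(df)) {
    s <- tolower(parse_chr(df$sex))
    s[!s %in% c("female", "male")] <- "unknown"
    s
  } else rep("unknown", n)
  for (col in .ternary_columns) {
    out[[col]] <- if (col %in% names(df)) {
      v <- df[[col]]
      if (is.logical(v)) v else parse_ternary(v, col)
    } else rep(NA, n)
  }
  for (col in .count_columns) {
    v <- if (col %in% names(df)) parse_num(df[[col]]) else rep(NA_real_, n)
    out[[col]] <- as.integer(round(v))
  }
  out$surgeon_id <- if ("surgeon_id" %in% names(df)) parse_chr(df$surgeon_id) else rep(NA_character_, n)
  out <- out[, .cohort_columns]

  if (anyNA(out$patient_id)) {
    stop("validation error: missing patient_id at row ",
         which(is.na(out$patient_id))[1], call. = FALSE)
  }
  if (anyDuplicated(out$patient_id)) {
    stop("validation error: duplicate patient_id '",
         out$patient_id[anyDuplicated(out$patient_id)], "'", call. = FALSE)
  }
  bad_tonsil <- which(!is.na(out$tonsil_grade) & !(out$tonsil_grade %in% 0:4))
  if (length(bad_tonsil)) {
    stop("validation error: tonsil_grade out of range 0-4 at row ", bad_tonsil[1],
         " (value ", out$tonsil_grade[bad_tonsil[1]], ")", call. = FALSE)
  }
  bad_mos <- which(!is.na(out$mos) & !(out$mos %in% 1:4))
  if (length(bad_mos)) {
    stop("validation error: mos out of range 1-4 at row ", bad_mos[1],
         " (value ", out$mos[bad_mos[1]], ")", call. = FALSE)
  }
  structure(out, class = c("osa_cohort", "data.frame"), provenance = provenance)
}

#' Read a cohort from CSV
#'
#' Reads a UTF-8 comma-separated file with one header row. Empty cells and
#' the literal `NA` both map to missing. Column names may be remapped through
#' `dialect`, a named character vector `c(canonical = "source_column")`, so
#' clinic exports with local headers can be ingested without editing.
#'
#' @param path path to the CSV file.
#' @param dialect optional named character vector mapping canonical column
#'   names to the names used in the file.
#' @return An [as_cohort()] cohort; row order follows the file.
#' @export
read_cohort_csv <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = character())
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(raw)) {
        stop("configuration error: dialect maps '", canon, "' to column '",
             src, "', which is not in the file", call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  as_cohort(raw, provenance = path)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort_csv()]: canonical columns, one header row, missing
#' values as empty cells. Reading the file back reproduces the cohort
#' field-for-field.
#'
#' @param cohort an `osa_cohort`.
#' @param path destination path.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "osa_cohort"))
  write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate one patient record
#'
#' Checks the domain invariants (tonsil grade 0-4, MOS 1-4, pediatric age
#' below 18 years, NOSE score 0-100, non-negative symptom counts) and returns
#' a character vector of violations, one per failed check, each naming the
#' offending field. Never raises, whatever the missingness pattern.
#'
#' @param record a one-row data frame (or list) with cohort columns.
#' @return character vector of violation descriptions; empty if valid.
#' @export
validate_record <- function(record) {
  v <- character()
  chk <- function(cond, msg) if (isTRUE(cond)) c(v, msg) else v
  g <- function(f) {
    x <- record[[f]]
    if (is.null(x) || length(x) == 0) NA else x[1]
  }
  age <- g("age_years")
  v <- chk(!is.na(age) && age < 0, "age_years: must be non-negative")
  v <- chk(!is.na(age) && age >= 18, "age_years: must be below 18 (pediatric cohort)")
  tg <- g("tonsil_grade")
  v <- chk(!is.na(tg) && !(tg %in% 0:4), "tonsil_grade: must be in 0-4 (Brodsky scale)")
  mos <- g("mos")
  v <- chk(!is.na(mos) && !(mos %in% 1:4), "mos: must be in 1-4")
  nose <- g("nose_score")
  v <- chk(!is.na(nose) && (nose < 0 || nose > 100), "nose_score: must be in 0-100")
  for (f in c("rls_symptom_count", "gerd_symptom_count")) {
    x <- g(f)
    v <- chk(!is.na(x) && x < 0, paste0(f, ": must be non-negative"))
  }
  v
}

#' Validate every record of a cohort
#'
#' @param cohort an `osa_cohort`.
#' @return data frame with columns `row`, `patient_id`, `violation`; zero rows
#'   if the whole cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    v <- validate_record(cohort[i, ])
    if (length(v)) data.frame(row = i, patient_id = cohort$patient_id[i],
                              violation = v, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(row = integer(), patient_id = character(),
                                      violation = character())
  out
}

#' @export
print.osa_cohort <- function(x, ...) {
  cat(sprintf("OSA clinic cohort: %d children (provenance: %s)\n",
              nrow(x), attr(x, "provenance") %||% "unspecified"))
  NextMethod()
}

#' Summarise a cohort
#'
#' Marginal summaries in the layout clinical papers report: percentage (and
#' count) snoring ever and over half the night, percent female, age mean and
#' SD, prior-AT count, tonsil grade distribution and observed AT rate.
#' Percentages are over non-missing denominators.
#'
#' @param object an `osa_cohort`.
#' @param ... unused.
#' @return A list of class `osa_cohort_summary`.
#' @export
summary.osa_cohort <- function(object, ...) {
  pct <- function(flag) {
    n <- sum(!is.na(flag))
    k <- sum(flag, na.rm = TRUE)
    list(n = n, k = k, pct = if (n > 0) round(100 * k / n) else NA_real_)
  }
  out <- list(
    n = nrow(object),
    ever_snore = pct(object$ever_snore),
    snore_half_night = pct(object$snore_half_night),
    female = pct(object$sex == "female" & object$sex != "unknown"),
    prior_at = pct(object$prior_at),
    at_outcome = pct(object$at_outcome),
    age_mean = mean(object$age_years, na.rm = TRUE),
    age_sd = sd(object$age_years, na.rm = TRUE),
    tonsil_grades = table(factor(object$tonsil_grade, levels = 0:4), useNA = "always")
  )
  class(out) <- "osa_cohort_summary"
  out
}

#' @export
print.osa_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d children\n", x$n))
  line <- function(lbl, p) {
    cat(sprintf("  %-28s %3.0f%% (%d/%d)\n", lbl, p$pct, p$k, p$n))
  }
  line("Ever snore:", x$ever_snore)
  line("Snore > half the night:", x$snore_half_night)
  line("Female:", x$female)
  line("Prior AT:", x$prior_at)
  line("Received AT:", x$at_outcome)
  cat(sprintf("  %-28s %.2f (SD %.2f)\n", "Age, years:", x$age_mean, x$age_sd))
  cat("  Tonsil grade 0-4 / missing: ",
      paste(as.integer(x$tonsil_grades), collapse = " / "), "\n", sep = "")
  invisible(x)
}
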