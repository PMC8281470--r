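# Fixture builders shared across test files. All fixtures are constructed in
# code; nothing is read from disk except files the tests themselves write.

# Strip class/provenance so two cohorts can be compared field-for-field.
plain_df <- function(x) {
  x <- as.data.frame(x)
  attr(x, "provenance") <- NULL
  class(x) <- "data.frame"
  rownames(x) <- NULL
  x
}

# One-row (or n-row) cohort with sensible defaults, overridable per field.
make_records <- function(n = 1, ...) {
  if (n == 0) return(make_records(1)[0, ])
  over <- list(...)
  base <- data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    age_years = 8, sex = "female", prior_at = FALSE,
    ever_snore = TRUE, snore_half_night = FALSE,
    psq_struggle_breathe = FALSE, psq_witnessed_apneas = FALSE,
    psq_daytime_mouth_breathing = FALSE, psq_am_dry_mouth = FALSE,
    rls_symptom_count = 0, gerd_symptom_count = 0, nose_score = 0,
    tonsil_grade = NA, mos = NA, surgeon_id = "S1", at_outcome = NA,
    stringsAsFactors = FALSE)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  as_cohort(base, provenance = "test fixture")
}

make_record <- function(...) make_records(1, ...)

# Set all four PSQ items at once from a count of positives (0-4); remaining
# items answered "no".
with_psq_count <- function(n = 1, count, ...) {
  items <- c("psq_struggle_breathe", "psq_witnessed_apneas",
             "psq_daytime_mouth_breathing", "psq_am_dry_mouth")
  args <- list(...)
  for (i in seq_along(items)) args[[items[i]]] <- i <= count
  do.call(make_records, c(list(n = n), args))
}

# Hand-built desaturation event table (for clustering / scoring unit tests).
make_events <- function(start, end = start + 30, nadir = 88, baseline = 97) {
  if (!length(start)) {
    return(data.frame(start_time = numeric(), end_time = numeric(),
                      baseline = numeric(), nadir = numeric(),
                      depth = numeric()))
  }
  data.frame(start_time = start, end_time = end, baseline = baseline,
             nadir = nadir, depth = baseline - nadir)
}

# The full discrete routing lattice the tonsil trees see:
# tonsil in {0..4, NA} x mos in {1..4, NA} x prior_at in {T, F}.
routing_lattice <- function() {
  grid <- expand.grid(tonsil_grade = c(0:4, NA), mos = c(1:4, NA),
                      prior_at = c(TRUE, FALSE))
  make_records(nrow(grid), tonsil_grade = grid$tonsil_grade, mos = grid$mos,
               prior_at = grid$prior_at)
}
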