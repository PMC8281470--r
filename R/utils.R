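#' @keywords internal
"_PACKAGE"

#' @importFrom stats glm binomial coef median pnorm qnorm rbinom rnorm runif sd vcov
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Round half away from zero (display convention for reports; base round()
# rounds half to even).
round_away <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# Parse a yes/no style answer vector into logical. Accepted (case-insensitive):
# yes/no/true/false/1/0. Anything else becomes NA; unrecognised non-empty
# values trigger one warning naming the column.
parse_ternary <- function(x, column = "value") {
  x <- trimws(as.character(x))
  low <- tolower(x)
  out <- rep(NA, length(x))
  out[low %in% c("yes", "true", "1")] <- TRUE
  out[low %in% c("no", "false", "0")] <- FALSE
  bad <- !is.na(x) & x != "" & !(low %in% c("yes", "no", "true", "false", "1", "0", "na"))
  if (any(bad)) {
    warning(sprintf("column '%s': %d unrecognised answer(s) treated as missing (e.g. '%s')",
                    column, sum(bad), x[which(bad)[1]]), call. = FALSE)
  }
  out
}

parse_num <- function(x) {
  x <- trimws(as.character(x))
  x[x == "" | toupper(x) == "NA"] <- NA
  suppressWarnings(as.numeric(x))
}

parse_chr <- function(x) {
  x <- trimws(as.character(x))
  x[x == "" | toupper(x) == "NA"] <- NA
  x
}

# Deterministic sub-seed derivation so each generated field block has its own
# reproducible stream. Keeps results inside the 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483587) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
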