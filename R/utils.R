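# Shared helpers: presentation rounding, FAERS-style date handling, and the
# controlled vocabularies used across modules.

SEX_LEVELS <- c("female", "male", "unspecified")
ROLE_LEVELS <- c("primary suspect", "secondary suspect", "concomitant", "interacting")
REPORTER_LEVELS <- c("physician", "pharmacist", "other health-professional",
                     "consumer", "lawyer", "unspecified")
OUTCOME_LEVELS <- c("death", "life-threatening", "hospitalization", "disability",
                    "congenital anomaly", "required intervention", "other")
AGE_GROUP_LEVELS <- c("<18", "18-44", "45-64", ">=65", "unspecified")

# FAERS-style two-letter codes used in the delimited table dialect.
ROLE_CODES <- c("primary suspect" = "PS", "secondary suspect" = "SS",
                "concomitant" = "C", "interacting" = "I")
OUTCOME_CODES <- c("death" = "DE", "life-threatening" = "LT",
                   "hospitalization" = "HO", "disability" = "DS",
                   "congenital anomaly" = "CA", "required intervention" = "RI",
                   "other" = "OT")
REPORTER_CODES <- c("physician" = "MD", "pharmacist" = "PH",
                    "other health-professional" = "HP", "consumer" = "CN",
                    "lawyer" = "LW", "unspecified" = "")
SEX_CODES <- c("female" = "F", "male" = "M", "unspecified" = "")

#' Round half away from zero
#'
#' Presentation rounding used for all reported percentages: ties round up
#' (2.675 -> 2.68), unlike [base::round()]'s round-half-even. A small guard
#' offset absorbs binary floating-point representation error.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Parse a FAERS-style date string (YYYYMMDD). Partial dates (YYYY, YYYYMM),
# empty strings and impossible calendar dates all map to NA; callers count
# the NAs they care about and warn.
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | x == ""] <- NA_character_
  out <- rep(as.Date(NA), length(x))
  full <- !is.na(x) & grepl("^[0-9]{8}$", x)
  out[full] <- as.Date(x[full], format = "%Y%m%d")
  out
}

format_faers_date <- function(d) {
  ifelse(is.na(d), "", format(d, "%Y%m%d"))
}

# Named-lookup with default for multiplier maps.
lookup_or <- function(map, key, default) {
  if (is.null(map) || is.na(match(key, names(map)))) default else unname(map[[key]])
}

# data.frame constructor without the validation overhead of data.frame();
# used where corpora assemble tens of thousands of small exposure frames.
quick_df <- function(cols) {
  structure(cols, class = "data.frame",
            row.names = c(NA_integer_, -length(cols[[1]])))
}

stop_config <- function(msg, field = NULL) {
  rlang::abort(msg, class = "pvsignal_config_error", field = field)
}

stop_input <- function(msg) {
  rlang::abort(msg, class = "pvsignal_input_error")
}

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_config(sprintf("'%s' must contain probabilities in [0, 1]", name),
                field = name)
  }
  invisible(x)
}

check_sums_to_one <- function(x, name, tol = 1e-9) {
  if (abs(sum(x) - 1) > tol) {
    stop_config(sprintf("'%s' probabilities must sum to 1 (got %.12f)",
                        name, sum(x)), field = name)
  }
  invisible(x)
}
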