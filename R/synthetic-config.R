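# Configuration of the synthetic spontaneous-reporting-system generator.
#
# The generator emulates the structure of a FAERS-like corpus restricted to a
# drug universe of interest: each report carries one primary-suspect drug,
# one or more MedDRA-style preferred terms (PTs), demographics, dates and
# outcomes. Association strength between a drug and a PT is controlled by a
# multiplier lambda on the joint reporting probability above independence, so
# every contingency-table cell has an analytically computable expectation
# (see ground_truth_tables()).

#' Configure the synthetic spontaneous-reporting-system generator
#'
#' Builds and validates the full parameterization of a simulated reporting
#' system. The defaults describe a corpus patterned on post-marketing
#' antiplatelet surveillance: four study drugs (aspirin, clopidogrel,
#' ticagrelor, prasugrel), an anticoagulant positive control (warfarin), a
#' statin negative control (rosuvastatin), and a background of common drugs
#' and adverse events. Target PTs are central-nervous-system hematoma terms;
#' their drug-specific signal multipliers default to the reporting-odds-ratio
#' scale observed for these drugs, sex/age strata carry their own
#' multipliers, and per-drug Weibull onset models default to early-failure
#' shapes (beta < 1).
#'
#' @param n_reports number of raw cases before duplication (>= 1).
#' @param drugs data frame with columns `drug`, `prob`: the primary-suspect
#'   drug marginal (probabilities sum to 1).
#' @param events data frame with columns `pt`, `prob`, `target`: per-PT
#'   baseline reporting probabilities (independent Bernoulli marginals, each
#'   in \[0, 1\]) and a logical flag marking the target event set.
#' @param signal_multipliers data frame with columns `drug`, `pt`, `lambda`:
#'   multiplier (> 0) on the joint drug-PT reporting probability above
#'   independence. Pairs not listed have lambda = 1.
#' @param strata_effects data frame with columns `dimension` (`"sex"` or
#'   `"age_group"`), `level`, `drug`, `multiplier`: extra multiplier (> 0)
#'   applied to lambda for the listed drug's signal pairs within that
#'   stratum.
#' @param age_distribution data frame with columns `band`, `prob`, `lo`,
#'   `hi`: mixture over age bands with uniform sampling inside each band.
#' @param sex_distribution named numeric over
#'   `c("female", "male", "unspecified")`, summing to 1.
#' @param onset_models data frame with columns `drug`, `alpha`, `beta`:
#'   Weibull scale (days) and shape for time from drug start to event.
#'   Drugs not listed use `default_onset`.
#' @param default_onset length-2 named numeric `c(alpha=, beta=)` fallback
#'   onset model.
#' @param dup_rate probability in \[0, 1) that a case is emitted twice (a
#'   later-received resubmission with a perturbed reporter field).
#' @param missing_rates named list of per-field missing-completely-at-random
#'   probabilities: `age`, `sex`, `event_date`, `start_date`.
#' @param reporter_distribution,country_distribution named probability
#'   vectors for the reporter occupation and reporting country.
#' @param outcome_rates named numeric over the seven regulatory outcome
#'   categories; each outcome is drawn independently per report.
#' @param p_serious probability a report is flagged serious.
#' @param p_concomitant probability a report carries one extra
#'   non-suspect (concomitant) drug exposure.
#' @param seed integer random seed; a fixed seed makes [generate_corpus()]
#'   byte-reproducible.
#' @return a validated object of class `synthetic_config`.
#' @seealso [generate_corpus()], [ground_truth_tables()]
#' @export
synthetic_config <- function(n_reports = 20000,
                             drugs = default_drug_marginals(),
                             events = default_event_marginals(),
                             signal_multipliers = default_signal_multipliers(),
                             strata_effects = default_strata_effects(),
                             age_distribution = default_age_distribution(),
                             sex_distribution = c(female = 0.322, male = 0.578,
                                                  unspecified = 0.100),
                             onset_models = default_onset_models(),
                             default_onset = c(alpha = 180, beta = 1),
                             dup_rate = 0.05,
                             missing_rates = list(age = 0.134, sex = 0,
                                                  event_date = 0.45,
                                                  start_date = 0.55),
                             reporter_distribution = default_reporter_distribution(),
                             country_distribution = default_country_distribution(),
                             outcome_rates = default_outcome_rates(),
                             p_serious = 0.9982,
                             p_concomitant = 0.3,
                             seed = 1L) {
  cfg <- structure(
    list(n_reports = n_reports,
         drugs = tibble::as_tibble(drugs),
         events = tibble::as_tibble(events),
         signal_multipliers = tibble::as_tibble(signal_multipliers),
         strata_effects = tibble::as_tibble(strata_effects),
         age_distribution = tibble::as_tibble(age_distribution),
         sex_distribution = sex_distribution,
         onset_models = tibble::as_tibble(onset_models),
         default_onset = default_onset,
         dup_rate = dup_rate,
         missing_rates = missing_rates,
         reporter_distribution = reporter_distribution,
         country_distribution = country_distribution,
         outcome_rates = outcome_rates,
         p_serious = p_serious,
         p_concomitant = p_concomitant,
         seed = as.integer(seed)),
    class = "synthetic_config")
  validate_synthetic_config(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat(sprintf("  n_reports: %d   seed: %d   dup_rate: %.3f\n",
              x$n_reports, x$seed, x$dup_rate))
  cat(sprintf("  drugs: %d (%s, ...)\n", nrow(x$drugs),
              paste(utils::head(x$drugs$drug, 4), collapse = ", ")))
  cat(sprintf("  events: %d (%d target)\n", nrow(x$events),
              sum(x$events$target)))
  cat(sprintf("  signal pairs: %d; strata effects: %d\n",
              nrow(x$signal_multipliers), nrow(x$strata_effects)))
  invisible(x)
}

validate_synthetic_config <- function(cfg) {
  if (!is.numeric(cfg$n_reports) || length(cfg$n_reports) != 1 ||
      is.na(cfg$n_reports) || cfg$n_reports < 1 ||
      cfg$n_reports != floor(cfg$n_reports)) {
    stop_config("'n_reports' must be a positive integer", "n_reports")
  }
  cfg$n_reports <- as.integer(cfg$n_reports)

  req_cols <- function(df, cols, name) {
    if (!all(cols %in% names(df))) {
      stop_config(sprintf("'%s' must have columns %s", name,
                          paste(cols, collapse = ", ")), field = name)
    }
  }
  req_cols(cfg$drugs, c("drug", "prob"), "drugs")
  req_cols(cfg$events, c("pt", "prob", "target"), "events")
  req_cols(cfg$signal_multipliers, c("drug", "pt", "lambda"), "signal_multipliers")
  req_cols(cfg$strata_effects, c("dimension", "level", "drug", "multiplier"),
           "strata_effects")
  req_cols(cfg$age_distribution, c("band", "prob", "lo", "hi"), "age_distribution")
  req_cols(cfg$onset_models, c("drug", "alpha", "beta"), "onset_models")

  if (anyDuplicated(cfg$drugs$drug)) stop_config("duplicate drug labels", "drugs")
  if (anyDuplicated(cfg$events$pt)) stop_config("duplicate PT labels", "events")
  check_prob(cfg$drugs$prob, "drugs$prob")
  check_sums_to_one(cfg$drugs$prob, "drugs$prob")
  check_prob(cfg$events$prob, "events$prob")
  if (!any(cfg$events$target) || !any(!cfg$events$target)) {
    stop_config("'events' must contain both target and background PTs", "events")
  }
  if (any(!is.finite(cfg$signal_multipliers$lambda)) ||
      any(cfg$signal_multipliers$lambda <= 0)) {
    stop_config("all 'lambda' must be > 0", "signal_multipliers")
  }
  bad_pair <- !(cfg$signal_multipliers$drug %in% cfg$drugs$drug) |
    !(cfg$signal_multipliers$pt %in% cfg$events$pt)
  if (any(bad_pair)) {
    stop_config("signal_multipliers refer to unknown drug or PT labels",
                "signal_multipliers")
  }
  if (any(!is.finite(cfg$strata_effects$multiplier)) ||
      any(cfg$strata_effects$multiplier <= 0)) {
    stop_config("all strata multipliers must be > 0", "strata_effects")
  }
  if (!all(cfg$strata_effects$dimension %in% c("sex", "age_group"))) {
    stop_config("strata dimension must be 'sex' or 'age_group'", "strata_effects")
  }
  check_prob(cfg$age_distribution$prob, "age_distribution$prob")
  check_sums_to_one(cfg$age_distribution$prob, "age_distribution$prob")
  if (any(cfg$age_distribution$lo < 0) ||
      any(cfg$age_distribution$hi > 130) ||
      any(cfg$age_distribution$lo > cfg$age_distribution$hi)) {
    stop_config("age bands must satisfy 0 <= lo <= hi <= 130", "age_distribution")
  }
  if (!setequal(names(cfg$sex_distribution), SEX_LEVELS)) {
    stop_config("sex_distribution must be named female/male/unspecified",
                "sex_distribution")
  }
  check_prob(cfg$sex_distribution, "sex_distribution")
  check_sums_to_one(cfg$sex_distribution, "sex_distribution")
  if (any(cfg$onset_models$alpha <= 0) || any(cfg$onset_models$beta <= 0) ||
      cfg$default_onset[["alpha"]] <= 0 || cfg$default_onset[["beta"]] <= 0) {
    stop_config("Weibull onset parameters must be positive", "onset_models")
  }
  if (cfg$dup_rate < 0 || cfg$dup_rate >= 1) {
    stop_config("'dup_rate' must lie in [0, 1)", "dup_rate")
  }
  mr <- cfg$missing_rates
  if (!all(c("age", "sex", "event_date", "start_date") %in% names(mr))) {
    stop_config("missing_rates needs age, sex, event_date, start_date",
                "missing_rates")
  }
  check_prob(unlist(mr), "missing_rates")
  check_prob(cfg$reporter_distribution, "reporter_distribution")
  check_sums_to_one(cfg$reporter_distribution, "reporter_distribution")
  if (!all(names(cfg$reporter_distribution) %in% REPORTER_LEVELS)) {
    stop_config("unknown reporter categories", "reporter_distribution")
  }
  check_prob(cfg$country_distribution, "country_distribution")
  check_sums_to_one(cfg$country_distribution, "country_distribution")
  if (!all(names(cfg$outcome_rates) %in% OUTCOME_LEVELS)) {
    stop_config("outcome_rates must be named by the seven regulatory categories",
                "outcome_rates")
  }
  check_prob(cfg$outcome_rates, "outcome_rates")
  check_prob(c(cfg$p_serious, cfg$p_concomitant), "p_serious/p_concomitant")
  if (!is.finite(cfg$seed)) stop_config("'seed' must be a finite integer", "seed")
  cfg
}

#' @rdname synthetic_config
#' @export
default_drug_marginals <- function() {
  tibble::tibble(
    drug = c("aspirin", "clopidogrel", "ticagrelor", "prasugrel",
             "warfarin", "rosuvastatin",
             "metformin", "lisinopril", "atorvastatin", "omeprazole",
             "sertraline"),
    prob = c(0.030, 0.025, 0.008, 0.004,
             0.020, 0.015,
             0.250, 0.200, 0.180, 0.150,
             0.118))
}

#' @rdname synthetic_config
#' @export
default_event_marginals <- function() {
  tibble::tibble(
    pt = c("Subdural hematoma", "Cerebral hematoma", "Extradural hematoma",
           "Spinal epidural hematoma",
           "Nausea", "Headache", "Dizziness", "Rash", "Fatigue",
           "Dyspnoea", "Diarrhoea", "Pruritus"),
    prob = c(0.0040, 0.0008, 0.0006, 0.0004,
             0.08, 0.07, 0.06, 0.05, 0.05, 0.04, 0.03, 0.02),
    target = c(rep(TRUE, 4), rep(FALSE, 8)))
}

#' @rdname synthetic_config
#' @export
default_signal_multipliers <- function() {
  pts <- c("Subdural hematoma", "Cerebral hematoma", "Extradural hematoma",
           "Spinal epidural hematoma")
  # per-drug association scale for the whole hematoma PT set; warfarin is a
  # strong positive control, rosuvastatin a (protective-looking) negative one
  lam <- c(aspirin = 22, clopidogrel = 27, ticagrelor = 8, prasugrel = 17,
           warfarin = 38, rosuvastatin = 0.4)
  tibble::tibble(
    drug = rep(names(lam), each = length(pts)),
    pt = rep(pts, times = length(lam)),
    lambda = rep(unname(lam), each = length(pts)))
}

#' @rdname synthetic_config
#' @export
default_strata_effects <- function() {
  study <- c("aspirin", "clopidogrel", "ticagrelor", "prasugrel")
  dplyr::bind_rows(
    tibble::tibble(dimension = "sex", level = "female", drug = study,
                   multiplier = 1.6),
    tibble::tibble(dimension = "age_group", level = ">=65", drug = study,
                   multiplier = 1.2))
}

#' @rdname synthetic_config
#' @export
default_age_distribution <- function() {
  tibble::tibble(
    band = c("<18", "18-44", "45-64", ">=65"),
    prob = c(0.006, 0.029, 0.174, 0.791),
    lo = c(1, 18, 45, 65),
    hi = c(17, 44, 64, 95))
}

#' @rdname synthetic_config
#' @export
default_onset_models <- function() {
  tibble::tibble(
    drug = c("aspirin", "clopidogrel", "ticagrelor", "prasugrel", "warfarin"),
    alpha = c(930, 397, 66, 137, 400),
    beta = c(0.62, 0.58, 0.51, 0.65, 0.60))
}

default_reporter_distribution <- function() {
  c("physician" = 0.3615, "pharmacist" = 0.2188,
    "other health-professional" = 0.2058, "consumer" = 0.1792,
    "lawyer" = 0.0050, "unspecified" = 0.0297)
}

default_country_distribution <- function() {
  c("United States" = 0.3404, "France" = 0.1409, "Italy" = 0.0999,
    "United Kingdom" = 0.0873, "Japan" = 0.0626, "Other" = 0.2689)
}

default_outcome_rates <- function() {
  c("death" = 0.2341, "life-threatening" = 0.1612, "hospitalization" = 0.6664,
    "disability" = 0.0603, "congenital anomaly" = 0,
    "required intervention" = 0.0095, "other" = 0.4592)
}
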