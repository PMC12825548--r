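# Independent closed-form oracles and small fixture builders shared across
# test files. The oracle implementations deliberately spell the formulas out
# step by step, separately from the package's code paths.

oracle_ror <- function(a, b, c, d) {
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(est = est, low = exp(log(est) - 1.96 * se), high = exp(log(est) + 1.96 * se))
}

oracle_prr <- function(a, b, c, d) {
  est <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  c(est = est, low = exp(log(est) - 1.96 * se), high = exp(log(est) + 1.96 * se))
}

oracle_ic <- function(a, b, c, d) {
  n <- a + b + c + d
  g <- (n + 2) * (n + 2) / ((a + b + 1) * (a + c + 1))
  eic <- log2((a + 1) * (n + 2) * (n + 2) /
                ((n + g) * (a + b + 1) * (a + c + 1)))
  vic <- ((n - a + g - 1) / ((a + 1) * (1 + n + g)) +
            (n - a - b + 1) / ((a + b + 1) * (1 + n + 2)) +
            (n - a - c + 1) / ((a + c + 1) * (1 + n + 2))) / (log(2)^2)
  c(ic = eic, ic025 = eic - 2 * sqrt(vic), ic975 = eic + 2 * sqrt(vic))
}

# E[ln lambda | n] under a two-gamma prior and a Poisson likelihood, by
# numerical integration of the prior density itself (no conjugate shortcut).
oracle_elog_lambda <- function(prior, n, E) {
  dens <- function(l) {
    (prior$P * stats::dgamma(l, prior$alpha1, rate = prior$beta1) +
       (1 - prior$P) * stats::dgamma(l, prior$alpha2, rate = prior$beta2)) *
      stats::dpois(n, l * E)
  }
  upper <- max(5 * (n + 10) / E, 50)
  z <- stats::integrate(dens, 0, upper, rel.tol = 1e-10)$value
  num <- stats::integrate(function(l) log(l) * dens(l), 0, upper,
                          rel.tol = 1e-10)$value
  num / z
}

# One-row report record with sensible defaults; override what matters.
make_record <- function(case_id, drug = "aspirin", role = "primary suspect",
                        pts = "Subdural hematoma", sex = "male", age = 70,
                        receipt = "2020-06-01", version = 1L,
                        event = NA, start = NA, reporter = "physician",
                        country = "United States", serious = TRUE,
                        outcomes = "hospitalization", source = "synthetic") {
  tibble::tibble(
    case_id = case_id,
    version_id = as.integer(version),
    receipt_date = as.Date(receipt),
    sex = sex,
    age_years = age,
    age_group = derive_age_group(age),
    reporter = reporter,
    country = country,
    serious = serious,
    outcomes = list(outcomes),
    reactions = list(pts),
    drugs = list(data.frame(drug_name = drug, role = role,
                            start_date = as.Date(start))),
    event_date = as.Date(event),
    source = source)
}

# Config shrunk for unit tests: no duplication/missingness unless asked.
test_config <- function(n_reports = 2000, seed = 7, lambda_pairs = NULL,
                        strata = NULL, dup_rate = 0, missing = 0) {
  synthetic_config(
    n_reports = n_reports, seed = seed,
    signal_multipliers = lambda_pairs %||% data.frame(
      drug = "aspirin", pt = "Subdural hematoma", lambda = 1),
    strata_effects = strata %||% data.frame(
      dimension = character(), level = character(), drug = character(),
      multiplier = numeric()),
    dup_rate = dup_rate,
    missing_rates = list(age = missing, sex = 0, event_date = missing,
                         start_date = missing))
}

target_pts4 <- c("Subdural hematoma", "Cerebral hematoma",
                 "Extradural hematoma", "Spinal epidural hematoma")

`%||%` <- function(x, y) if (is.null(x)) y else x
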