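# Synthetic corpus generation.
#
# Sampling scheme (chosen so that every 2x2 cell expectation is available in
# closed form): each report draws one primary-suspect drug from the drug
# marginal, then demographics, then each PT independently with probability
# min(1, base_pt * lambda(drug, pt) * stratum multipliers). Reports that draw
# no PT at all receive a single *background* PT from the renormalized
# background marginal, so membership in the target-event cell is untouched
# and ground_truth_tables() stays exact. No renormalization is applied, which
# lets large lambdas drift the realized PT marginals slightly upward.

# Internal: per-config multiplier lookups shared by the sampler and the
# closed-form expectations.
effect_maps <- function(cfg) {
  D <- nrow(cfg$drugs); E <- nrow(cfg$events)
  drugs <- cfg$drugs$drug; pts <- cfg$events$pt
  lam <- matrix(1, D, E, dimnames = list(drugs, pts))
  listed <- matrix(FALSE, D, E, dimnames = list(drugs, pts))
  for (i in seq_len(nrow(cfg$signal_multipliers))) {
    d <- cfg$signal_multipliers$drug[i]; p <- cfg$signal_multipliers$pt[i]
    lam[d, p] <- cfg$signal_multipliers$lambda[i]
    listed[d, p] <- TRUE
  }
  bands <- cfg$age_distribution$band
  sexm <- matrix(1, length(SEX_LEVELS), D, dimnames = list(SEX_LEVELS, drugs))
  agem <- matrix(1, length(bands), D, dimnames = list(bands, drugs))
  for (i in seq_len(nrow(cfg$strata_effects))) {
    se <- cfg$strata_effects[i, ]
    if (!se$drug %in% drugs) next
    if (se$dimension == "sex" && se$level %in% SEX_LEVELS) {
      sexm[se$level, se$drug] <- se$multiplier
    } else if (se$dimension == "age_group" && se$level %in% bands) {
      agem[se$level, se$drug] <- se$multiplier
    }
  }
  list(lam = lam, listed = listed, sexm = sexm, agem = agem)
}

#' Generate a synthetic spontaneous-report corpus
#'
#' Draws `n_reports` cases under the configured generative model, then
#' applies field-level missingness and case duplication. Duplicated cases
#' are emitted as an extra version with the same `case_id`, `version_id`
#' incremented, receipt date one day later, and the reporter field
#' perturbed, emulating a resubmission.
#'
#' The returned tibble has one row per report *version* with list-columns
#' `drugs` (exposures: `drug_name`, `role`, `start_date`), `reactions`
#' (PT labels) and `outcomes`. Attributes `onset_truth` (the pre-rounding
#' Weibull onset draws per case) and `dup_cases` (case ids emitted twice)
#' record the generator's ground truth for validation.
#'
#' @param config a [synthetic_config()].
#' @return tibble of report records; attributes `onset_truth`, `dup_cases`.
#' @export
generate_corpus <- function(config) {
  cfg <- validate_synthetic_config(config)
  withr::with_seed(cfg$seed, generate_corpus_impl(cfg))
}

generate_corpus_impl <- function(cfg) {
  n <- cfg$n_reports
  drugs <- cfg$drugs$drug; pts <- cfg$events$pt
  E <- length(pts)
  maps <- effect_maps(cfg)
  base <- cfg$events$prob
  target_idx <- which(cfg$events$target)
  bg_idx <- which(!cfg$events$target)

  drug_i <- sample.int(length(drugs), n, TRUE, prob = cfg$drugs$prob)
  sex_i <- sample.int(3L, n, TRUE, prob = cfg$sex_distribution[SEX_LEVELS])
  band_i <- sample.int(nrow(cfg$age_distribution), n, TRUE,
                       prob = cfg$age_distribution$prob)
  # two-decimal ages survive the serialized table format exactly
  age <- round(runif(n, cfg$age_distribution$lo[band_i],
                     cfg$age_distribution$hi[band_i]), 2)

  # per-report PT probabilities
  P <- matrix(base, n, E, byrow = TRUE)
  for (i in seq_len(nrow(cfg$signal_multipliers))) {
    d <- cfg$signal_multipliers$drug[i]; p <- cfg$signal_multipliers$pt[i]
    di <- match(d, drugs); ei <- match(p, pts)
    rows <- which(drug_i == di)
    if (!length(rows)) next
    P[rows, ei] <- base[ei] * maps$lam[di, ei] *
      maps$sexm[cbind(sex_i[rows], di)] * maps$agem[cbind(band_i[rows], di)]
  }
  X <- matrix(runif(n * E), n, E) < pmin(P, 1)

  # empty reaction sets get one background PT (keeps target cells exact)
  none <- which(rowSums(X) == 0L)
  if (length(none)) {
    fb <- bg_idx[sample.int(length(bg_idx), length(none), TRUE,
                            prob = base[bg_idx] / sum(base[bg_idx]))]
    X[cbind(none, fb)] <- TRUE
  }
  has_target <- rowSums(X[, target_idx, drop = FALSE]) > 0L

  # onset model for the sampled primary-suspect drug
  om <- cfg$onset_models
  alpha <- rep(cfg$default_onset[["alpha"]], length(drugs))
  beta <- rep(cfg$default_onset[["beta"]], length(drugs))
  hit <- match(om$drug, drugs)
  alpha[hit[!is.na(hit)]] <- om$alpha[!is.na(hit)]
  beta[hit[!is.na(hit)]] <- om$beta[!is.na(hit)]
  onset_raw <- rweibull(n, shape = beta[drug_i], scale = alpha[drug_i])
  onset_days <- floor(onset_raw + 0.5)  # round half-up; zero days kept

  start_date <- as.Date("2004-01-01") + (sample.int(7305L, n, TRUE) - 1L)
  bg_lag <- sample.int(365L, n, TRUE)
  event_offset <- ifelse(has_target, onset_days, bg_lag)
  event_date <- start_date + event_offset
  receipt_date <- event_date + sample.int(60L, n, TRUE)

  reporter <- sample(names(cfg$reporter_distribution), n, TRUE,
                     prob = cfg$reporter_distribution)
  country <- sample(names(cfg$country_distribution), n, TRUE,
                    prob = cfg$country_distribution)
  serious <- runif(n) < cfg$p_serious
  OM <- matrix(runif(n * length(cfg$outcome_rates)), n) <
    matrix(cfg$outcome_rates, n, length(cfg$outcome_rates), byrow = TRUE)
  outc_names <- names(cfg$outcome_rates)

  has_con <- runif(n) < cfg$p_concomitant
  con_i <- sample.int(length(drugs), n, TRUE, prob = cfg$drugs$prob)

  # missingness (MCAR, after generation)
  mr <- cfg$missing_rates
  age[runif(n) < mr$age] <- NA_real_
  sex <- SEX_LEVELS[sex_i]
  sex[runif(n) < mr$sex] <- "unspecified"
  event_date[runif(n) < mr$event_date] <- NA
  start_obs <- start_date
  start_obs[runif(n) < mr$start_date] <- NA

  case_id <- sprintf("C%07d", seq_len(n))
  sex <- factor(sex, SEX_LEVELS)

  # plain data frames: cheap to build and subset at corpus scale
  na_date <- as.Date(NA)
  drug_col <- lapply(seq_len(n), function(i) {
    if (has_con[i] && con_i[i] != drug_i[i]) {
      quick_df(list(
        drug_name = c(drugs[drug_i[i]], drugs[con_i[i]]),
        role = c("primary suspect", "concomitant"),
        start_date = c(start_obs[i], na_date)))
    } else {
      quick_df(list(drug_name = drugs[drug_i[i]], role = "primary suspect",
                    start_date = start_obs[i]))
    }
  })
  reac_col <- lapply(seq_len(n), function(i) pts[X[i, ]])
  outc_col <- lapply(seq_len(n), function(i) outc_names[OM[i, ]])

  corpus <- tibble::tibble(
    case_id = case_id,
    version_id = 1L,
    receipt_date = receipt_date,
    sex = as.character(sex),
    age_years = age,
    age_group = derive_age_group(age),
    reporter = reporter,
    country = country,
    serious = serious,
    outcomes = outc_col,
    reactions = reac_col,
    drugs = drug_col,
    event_date = event_date,
    source = "synthetic")

  dup <- which(runif(n) < cfg$dup_rate)
  if (length(dup)) {
    extra <- corpus[dup, ]
    extra$version_id <- 2L
    extra$receipt_date <- extra$receipt_date + 1L
    extra$reporter <- ifelse(extra$reporter == "consumer",
                             "unspecified", "consumer")
    corpus <- dplyr::bind_rows(corpus, extra)
  }
  corpus <- dplyr::arrange(corpus, .data$case_id, .data$version_id)

  attr(corpus, "onset_truth") <- tibble::tibble(
    case_id = case_id, drug = drugs[drug_i],
    onset_raw = onset_raw, onset_days = onset_days, target = has_target)
  attr(corpus, "dup_cases") <- case_id[dup]
  corpus
}

#' Expected contingency tables under the generative model
#'
#' Computes, in closed form, the expected 2x2 cell counts (a, b, c, d) for
#' each drug against the target event set, under case counting and before
#' duplication. These real-valued expectations are exact for the sampling
#' scheme of [generate_corpus()]: a report contributes to the target-event
#' column iff at least one target PT is drawn, the background-PT fallback
#' never alters that, and strata multipliers are marginalized over the
#' sex-by-age-band mixture.
#'
#' @param config a [synthetic_config()].
#' @param drugs optional character subset of drugs to tabulate (default all).
#' @return tibble with columns `drug`, `a`, `b`, `c`, `d`, `n` where
#'   `a + b + c + d == n_reports` for every row.
#' @export
ground_truth_tables <- function(config, drugs = NULL) {
  cfg <- validate_synthetic_config(config)
  maps <- effect_maps(cfg)
  all_drugs <- cfg$drugs$drug
  drugs <- drugs %||% all_drugs
  if (!all(drugs %in% all_drugs)) stop_config("unknown drug in 'drugs'", "drugs")
  q <- cfg$events$prob
  t_idx <- which(cfg$events$target)
  bands <- seq_len(nrow(cfg$age_distribution))
  w_sex <- cfg$sex_distribution[SEX_LEVELS]
  w_age <- cfg$age_distribution$prob

  # P(report for drug d carries >= 1 target PT), marginalized over strata
  pi_target <- vapply(seq_along(all_drugs), function(di) {
    acc <- 0
    for (s in 1:3) for (b in bands) {
      p_eff <- pmin(1, q[t_idx] * maps$lam[di, t_idx] *
                      maps$sexm[s, di] * maps$agem[b, di])
      acc <- acc + w_sex[s] * w_age[b] * (1 - prod(1 - p_eff))
    }
    acc
  }, numeric(1))

  N <- cfg$n_reports
  p_drug <- cfg$drugs$prob
  out <- lapply(drugs, function(d) {
    di <- match(d, all_drugs)
    a <- N * p_drug[di] * pi_target[di]
    b <- N * p_drug[di] - a
    c <- N * sum(p_drug[-di] * pi_target[-di])
    tibble::tibble(drug = d, a = a, b = b, c = c, d = N - a - b - c, n = N)
  })
  dplyr::bind_rows(out)
}
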