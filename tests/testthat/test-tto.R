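# Time-to-onset extraction, Weibull fitting and classification, the
# Kruskal-Wallis comparison and cumulative curves.

test_that("onset is whole-day date arithmetic with tallied exclusions", {
  records <- dplyr::bind_rows(
    make_record("A", start = "2020-01-01", event = "2020-01-15"),
    make_record("B", start = "2020-02-01", event = NA),
    make_record("C", start = NA, event = "2020-03-01"),
    make_record("D", start = "2020-04-10", event = "2020-04-01"),
    make_record("E", start = "2020-05-01", event = "2020-05-01"))
  s <- compute_tto(records, "aspirin")
  expect_equal(s$onsets_days, c(14, 0.5))  # zero-day recoded by default
  expect_equal(unname(s$excluded["missing_event_date"]), 1)
  expect_equal(unname(s$excluded["missing_start_date"]), 1)
  expect_equal(unname(s$excluded["negative_interval"]), 1)
  sx <- compute_tto(records, "aspirin", zero_day = "exclude")
  expect_equal(sx$onsets_days, 14)
  expect_equal(unname(sx$excluded["zero_day"]), 1)
})

test_that("onsets recovered from a synthetic corpus equal the generator draws", {
  cfg <- test_config(n_reports = 4000, seed = 29,
                     lambda_pairs = data.frame(drug = "aspirin",
                                               pt = target_pts4, lambda = 25))
  corpus <- deduplicate(generate_corpus(cfg))
  truth <- attr(generate_corpus(cfg), "onset_truth")
  sel <- select_analysis_set(corpus, analysis_config())
  s <- compute_tto(sel$sets$aspirin, "aspirin")
  expected <- truth$onset_days[match(sel$sets$aspirin$case_id, truth$case_id)]
  expected[expected == 0] <- 0.5
  expect_equal(sort(s$onsets_days), sort(expected))
})

test_that("the Weibull fit recovers known parameters with honest intervals", {
  set.seed(11)
  x <- stats::rweibull(500, shape = 0.6, scale = 100)
  f <- fit_weibull(list(drug = "synthetic", onsets_days = x))
  expect_gt(f$beta, 0.5); expect_lt(f$beta, 0.7)
  expect_gt(f$alpha, 85); expect_lt(f$alpha, 115)
  expect_lt(f$alpha_low, f$alpha); expect_gt(f$alpha_high, f$alpha)
  expect_equal(f$median_days, stats::median(x))
  # exponential data: the shape CI must cover 1
  set.seed(12)
  e <- stats::rexp(1000, rate = 1 / 50)
  fe <- fit_weibull(list(drug = "exp", onsets_days = e))
  expect_lt(fe$beta_low, 1); expect_gt(fe$beta_high, 1)
  expect_equal(fe$failure_type, "random failure")
})

test_that("shape-CI coverage sits near nominal over repeated simulation", {
  set.seed(99)
  cover <- 0
  for (i in 1:100) {
    x <- stats::rweibull(200, shape = 0.6, scale = 150)
    f <- fit_weibull(list(drug = "sim", onsets_days = x))
    cover <- cover + (f$beta_low <= 0.6 && 0.6 <= f$beta_high)
  }
  expect_gte(cover, 90); expect_lte(cover, 99)
})

test_that("the in-package MLE agrees with an independent fitter", {
  skip_if_not_installed("MASS")
  set.seed(31)
  x <- stats::rweibull(300, shape = 0.7, scale = 200)
  f <- fit_weibull(list(drug = "x", onsets_days = x))
  m <- MASS::fitdistr(x, "weibull")
  # the two optimizers stop at slightly different points near the optimum
  expect_equal(f$beta, unname(m$estimate["shape"]), tolerance = 0.02)
  expect_equal(f$alpha, unname(m$estimate["scale"]), tolerance = 0.02)
  # and ours attains at least as good a likelihood
  expect_lte(pvsignal:::weibull_negloglik(log(c(f$alpha, f$beta)), x),
             pvsignal:::weibull_negloglik(log(unname(
               m$estimate[c("scale", "shape")])), x) + 1e-6)
})

test_that("degenerate and under-sized samples fail loudly, not silently", {
  expect_error(fit_weibull(list(drug = "x", onsets_days = rep(5, 50))),
               class = "pvsignal_fit_error")
  expect_error(fit_weibull(list(drug = "x", onsets_days = c(1, 2, 3))),
               class = "pvsignal_smallsample_error")
})

test_that("failure-type rules follow the shape parameter and its CI", {
  mk <- function(b, lo, hi) list(beta = b, beta_low = lo, beta_high = hi)
  expect_equal(classify_failure(mk(0.62, 0.54, 0.71)), "early failure")
  expect_equal(classify_failure(mk(1.02, 0.91, 1.14)), "random failure")
  expect_equal(classify_failure(mk(1.40, 1.21, 1.62)), "wear-out failure")
  expect_warning(out <- classify_failure(mk(0.9, 1.05, 1.2)), "inconsistent")
  expect_equal(out, "random failure")
})

test_that("the Kruskal-Wallis comparison matches a rank-based brute force", {
  brute_H <- function(groups) {
    x <- unlist(groups)
    g <- rep(seq_along(groups), lengths(groups))
    r <- rank(x)
    n <- length(x)
    H <- 12 / (n * (n + 1)) *
      sum(tapply(r, g, sum)^2 / tapply(r, g, length)) - 3 * (n + 1)
    ties <- table(x)
    H / (1 - sum(ties^3 - ties) / (n^3 - n))
  }
  set.seed(55)
  for (i in 1:20) {
    groups <- lapply(1:3, function(k)
      round(stats::rweibull(30, shape = 0.8, scale = 50 * k)))
    res <- compare_medians(groups)
    expect_equal(res$H, brute_H(groups), tolerance = 1e-9)
    expect_equal(res$df, 2)
  }
  # identical groups carry no evidence
  same <- compare_medians(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_medians(list(c(1, 2))), class = "pvsignal_input_error")
})

test_that("widely separated onset medians are detected decisively", {
  set.seed(77)
  g1 <- stats::rweibull(100, shape = 0.8, scale = 12 / log(2)^(1 / 0.8))
  g2 <- stats::rweibull(100, shape = 0.8, scale = 442 / log(2)^(1 / 0.8))
  res <- compare_medians(list(g1, g2))
  expect_lt(res$p_value, 0.001)
})

test_that("cumulative onset curves are proper step functions ending at 1", {
  s <- list(drug = "x", onsets_days = c(1, 2, 3))
  curve <- cumulative_curves(list(s))
  expect_equal(curve$days, c(1, 2, 3))
  expect_equal(curve$cum_prop, c(1 / 3, 2 / 3, 1))
  set.seed(3)
  w <- list(drug = "w", onsets_days = stats::rweibull(400, 0.7, 80))
  cw <- cumulative_curves(list(w))
  expect_true(all(diff(cw$cum_prop) > 0))
  expect_equal(cw$cum_prop[nrow(cw)], 1)
  # ECDF tracks the true distribution on well-specified draws
  ks <- max(abs(cw$cum_prop -
                  stats::pweibull(cw$days, 0.7, 80)))
  expect_lt(ks, 1.628 / sqrt(400))
})
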