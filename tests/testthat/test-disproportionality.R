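# Four-grid construction and the ROR / PRR / BCPNN statistics, their
# continuity-correction policy, threshold flags and the joint criterion.

test_that("2x2 tables enumerate case-counted corpora correctly", {
  corpus <- dplyr::bind_rows(
    make_record("A", drug = "drugA", pts = "PT1"),
    make_record("B", drug = "drugA", pts = "Other"),
    make_record("C", drug = "drugX", pts = "PT1"),
    make_record("D", drug = "drugX", pts = "Other"))
  tab <- build_table(corpus, "drugA", "PT1")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 1, 1, 1))
  expect_equal(tab$n, 4)
  expect_error(build_table(corpus[0, ], "drugA", "PT1"),
               class = "pvsignal_input_error")
})

test_that("pair counting expands multi-PT records into drug-event units", {
  corpus <- dplyr::bind_rows(
    make_record("A", drug = "drugA", pts = c("PT1", "PT2", "Other")),
    make_record("B", drug = "drugX", pts = c("PT1", "Other")))
  tab <- build_table(corpus, "drugA", c("PT1", "PT2"), counting_unit = "pair")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2, 1, 1, 1))
  # under case counting, per-PT a-values sum to >= the full-set a
  full <- build_table(corpus, "drugA", c("PT1", "PT2"))$a
  per_pt <- build_table(corpus, "drugA", "PT1")$a +
    build_table(corpus, "drugA", "PT2")$a
  expect_gte(per_pt, full)
})

test_that("tables match a brute-force double loop on a synthetic corpus", {
  cfg <- test_config(n_reports = 800, seed = 31)
  corpus <- generate_corpus(cfg)
  tab <- build_table(corpus, "aspirin", target_pts4)
  counts <- c(a = 0, b = 0, c = 0, d = 0)
  for (i in seq_len(nrow(corpus))) {
    dr <- corpus$drugs[[i]]
    has_d <- "aspirin" %in% dr$drug_name[dr$role == "primary suspect"]
    has_e <- any(corpus$reactions[[i]] %in% target_pts4)
    cell <- if (has_d && has_e) "a" else if (has_d) "b"
    else if (has_e) "c" else "d"
    counts[cell] <- counts[cell] + 1
  }
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), unname(counts))
})

test_that("symmetric tables give ROR = PRR = 1", {
  tab <- contingency_table(10, 10, 10, 10)
  expect_equal(ror(tab)$ror, 1)
  expect_equal(prr(tab)$prr, 1)
})

test_that("worked example (25, 75, 100, 900) matches the closed forms", {
  tab <- contingency_table(25, 75, 100, 900)
  r <- ror(tab)
  expect_equal(r$ror, 3)
  o <- oracle_ror(25, 75, 100, 900)
  expect_equal(r$ror_low, unname(o["low"]))
  expect_equal(r$ror_high, unname(o["high"]))
  expect_equal(round(c(r$ror_low, r$ror_high), 2), c(1.82, 4.93))
  p <- prr(tab)
  expect_equal(p$prr, 2.5)
  po <- oracle_prr(25, 75, 100, 900)
  expect_equal(p$prr_low, unname(po["low"]))
  expect_equal(p$prr_high, unname(po["high"]))
})

test_that("ROR/PRR/IC agree with independent oracles on random tables", {
  set.seed(123)
  for (i in 1:200) {
    cells <- stats::rpois(4, lambda = c(20, 200, 200, 5000)) + 1
    tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    r <- ror(tab); p <- prr(tab); ic <- bcpnn_ic(tab)
    o_r <- oracle_ror(cells[1], cells[2], cells[3], cells[4])
    o_p <- oracle_prr(cells[1], cells[2], cells[3], cells[4])
    o_i <- oracle_ic(cells[1], cells[2], cells[3], cells[4])
    expect_equal(r$ror, unname(o_r["est"]), tolerance = 1e-10)
    expect_equal(p$prr, unname(o_p["est"]), tolerance = 1e-10)
    expect_equal(ic$ic, unname(o_i["ic"]), tolerance = 1e-10)
    expect_equal(ic$ic025, unname(o_i["ic025"]), tolerance = 1e-10)
    # multiplicative identity of the odds ratio
    expect_equal(r$ror * cells[2] * cells[3], cells[1] * cells[4],
                 tolerance = 1e-9)
  }
})

test_that("zero cells trigger the all-cell 0.5 correction, and only then", {
  tab <- contingency_table(0, 10, 5, 100)
  r <- ror(tab)
  expect_true(r$corrected)
  expect_equal(r$ror, (0.5 * 100.5) / (10.5 * 5.5))
  clean <- ror(contingency_table(5, 10, 5, 100))
  expect_false(clean$corrected)
  p <- prr(tab)
  expect_true(p$corrected)
  expect_equal(p$prr, (0.5 / 11) / (5.5 / 106))
})

test_that("the information component vanishes at independence and is finite at a = 0", {
  ic <- bcpnn_ic(contingency_table(100, 900, 900, 8100))
  expect_lt(abs(ic$ic), 0.05)
  z <- bcpnn_ic(contingency_table(0, 500, 500, 19000))
  expect_true(is.finite(z$ic) && is.finite(z$ic025))
  expect_lt(z$ic, 0)
})

test_that("the information component increases strictly with a", {
  prev <- -Inf
  for (a in c(1, 3, 10, 30, 100)) {
    ic <- bcpnn_ic(contingency_table(a, 500, 500, 19000))$ic
    expect_gt(ic, prev)
    prev <- ic
  }
})

test_that("threshold flags follow the a >= 3 rule and the IC strength bands", {
  # enormous disproportionality but a = 2: never a joint signal
  tab <- contingency_table(2, 1, 1, 10000)
  res <- evaluate_signal(tab, ror(tab), prr(tab), bcpnn_ic(tab),
                         ebgm = 50, ebgm05 = 30)
  expect_false(res$ror_flag)
  expect_false(res$prr_flag)
  expect_false(res$joint_signal)
  # IC category bands on the lower bound
  expect_equal(pvsignal:::ic_category(-0.2), "none")
  expect_equal(pvsignal:::ic_category(0), "none")
  expect_equal(pvsignal:::ic_category(1.2), "weak")
  expect_equal(pvsignal:::ic_category(1.5), "weak")
  expect_equal(pvsignal:::ic_category(2.9), "medium")
  expect_equal(pvsignal:::ic_category(3.2), "strong")
  # joint signal is the conjunction of the four flags
  big <- contingency_table(40, 200, 100, 20000)
  all4 <- evaluate_signal(big, ror(big), prr(big), bcpnn_ic(big),
                          ebgm = 10, ebgm05 = 5)
  expect_true(all4$joint_signal)
  expect_equal(all4$joint_signal,
               all4$ror_flag && all4$prr_flag && all4$bcpnn_flag &&
                 all4$mgps_flag)
})

test_that("positive and negative controls behave as designed on study-scale corpora", {
  ac <- analysis_config()
  fired_pos <- 0; fired_neg <- 0
  for (s in 1:3) {
    cfg <- synthetic_config(n_reports = 20000, seed = 100 + s)
    sel <- select_analysis_set(deduplicate(generate_corpus(cfg)), ac)
    sig <- signal_table(sel, ac)
    fired_pos <- fired_pos + sig$joint_signal[sig$drug == "warfarin"]
    fired_neg <- fired_neg + sig$joint_signal[sig$drug == "rosuvastatin"]
  }
  expect_equal(fired_pos, 3)
  expect_equal(fired_neg, 0)
})

test_that("the PT-level matrix matches brute-force pair tallies", {
  cfg <- test_config(n_reports = 1500, seed = 17,
                     lambda_pairs = data.frame(drug = "aspirin",
                                               pt = "Subdural hematoma",
                                               lambda = 12))
  corpus <- deduplicate(generate_corpus(cfg))
  m <- pt_level_matrix(corpus, c("aspirin", "clopidogrel"),
                       c("Subdural hematoma", "Cerebral hematoma"))
  expect_equal(nrow(m), 4)
  for (i in seq_len(nrow(m))) {
    brute <- sum(vapply(seq_len(nrow(corpus)), function(k) {
      dr <- corpus$drugs[[k]]
      (m$drug[i] %in% dr$drug_name[dr$role == "primary suspect"]) &&
        m$pt[i] %in% corpus$reactions[[k]]
    }, TRUE))
    expect_equal(m$n[i], brute)
  }
  # an empty PT column still yields a defined, negative IC025
  e <- pt_level_matrix(corpus, "aspirin", "No such PT")
  expect_equal(e$n, 0)
  expect_true(is.finite(e$ic025) && e$ic025 < 0)
})
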