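# Report-table reading, date handling, deduplication and analysis-set
# selection.

write_fixture_tables <- function(dir, demo, drug, reac, ther = NULL,
                                 outc = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(demo, file.path(dir, "DEMO.txt"))
  writeLines(drug, file.path(dir, "DRUG.txt"))
  writeLines(reac, file.path(dir, "REAC.txt"))
  if (!is.null(ther)) writeLines(ther, file.path(dir, "THER.txt"))
  if (!is.null(outc)) writeLines(outc, file.path(dir, "OUTC.txt"))
  dir
}

demo_header <- "primaryid$caseid$caseversion$fda_dt$event_dt$sex$age$age_cod$occp_cod$occr_country$serious$source"

test_that("a one-case fixture joins across all five tables", {
  dir <- write_fixture_tables(
    withr::local_tempdir(),
    demo = c(demo_header,
             "X1-1$X1$1$20200610$20200601$F$66.00$YR$MD$France$Y$FAERS-like"),
    drug = c("primaryid$drug_seq$drugname$role_cod",
             "X1-1$1$clopidogrel$PS", "X1-1$2$aspirin$C"),
    reac = c("primaryid$pt", "X1-1$Subdural hematoma", "X1-1$Nausea"),
    ther = c("primaryid$dsg_drug_seq$start_dt", "X1-1$1$20200101", "X1-1$2$"),
    outc = c("primaryid$outc_cod", "X1-1$HO", "X1-1$DE"))
  rec <- read_report_tables(dir)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$case_id, "X1")
  expect_equal(rec$sex, "female")
  expect_equal(rec$age_years, 66)
  expect_equal(rec$age_group, ">=65")
  expect_equal(rec$reporter, "physician")
  expect_setequal(rec$reactions[[1]], c("Subdural hematoma", "Nausea"))
  expect_setequal(rec$outcomes[[1]], c("hospitalization", "death"))
  d <- rec$drugs[[1]]
  expect_equal(d$drug_name, c("clopidogrel", "aspirin"))
  expect_equal(d$role, c("primary suspect", "concomitant"))
  expect_equal(d$start_date, as.Date(c("2020-01-01", NA)))
  expect_equal(rec$event_date, as.Date("2020-06-01"))
})

test_that("malformed and partial dates become missing with a warning", {
  dir <- write_fixture_tables(
    withr::local_tempdir(),
    demo = c(demo_header,
             "X1-1$X1$1$20200610$20201301$M$70.00$YR$MD$Italy$Y$FAERS-like",
             "X2-1$X2$1$20200611$202006$F$60.00$YR$PH$Italy$Y$FAERS-like"),
    drug = c("primaryid$drug_seq$drugname$role_cod",
             "X1-1$1$aspirin$PS", "X2-1$1$aspirin$PS"),
    reac = c("primaryid$pt", "X1-1$Nausea", "X2-1$Nausea"))
  expect_warning(rec <- read_report_tables(dir), "2 unparseable or partial")
  expect_equal(nrow(rec), 2)  # records retained
  expect_true(all(is.na(rec$event_date)))
})

test_that("a duplicated (case, version) key is a data-integrity error", {
  dir <- write_fixture_tables(
    withr::local_tempdir(),
    demo = c(demo_header,
             "X1-1$X1$1$20200610$$M$70.00$YR$MD$Italy$Y$FAERS-like",
             "X1-1$X1$1$20200611$$M$70.00$YR$MD$Italy$Y$FAERS-like"),
    drug = c("primaryid$drug_seq$drugname$role_cod", "X1-1$1$aspirin$PS"),
    reac = c("primaryid$pt", "X1-1$Nausea"))
  expect_error(read_report_tables(dir), class = "pvsignal_integrity_error")
})

test_that("a missing mandatory table is an input error", {
  expect_error(read_report_tables(list(demo = "nope", reac = "nope")),
               class = "pvsignal_input_error")
})

test_that("corpus write -> read round-trips in memory and is byte-stable on disk", {
  cfg <- test_config(n_reports = 300, seed = 21, dup_rate = 0.05,
                     missing = 0.3)
  corpus <- generate_corpus(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_corpus(corpus, d1)
  back <- read_report_tables(d1)
  expect_equal(as.data.frame(back), as.data.frame(corpus),
               ignore_attr = TRUE)
  write_corpus(back, d2)
  for (f in c("DEMO.txt", "DRUG.txt", "REAC.txt", "THER.txt", "OUTC.txt")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("deduplication keeps the latest (receipt, version) and is idempotent", {
  two <- dplyr::bind_rows(
    make_record("A", receipt = "2020-01-01", version = 1),
    make_record("A", receipt = "2020-03-01", version = 2, reporter = "consumer"),
    make_record("B", receipt = "2021-01-01", version = 1))
  dd <- deduplicate(two)
  expect_equal(nrow(dd), 2)
  expect_equal(dd$version_id[dd$case_id == "A"], 2L)
  expect_identical(as.data.frame(deduplicate(dd)), as.data.frame(dd))
  # receipt date dominates version id in the ordering
  swapped <- dplyr::bind_rows(
    make_record("C", receipt = "2020-05-01", version = 2),
    make_record("C", receipt = "2020-06-01", version = 1))
  expect_equal(deduplicate(swapped)$version_id, 1L)
})

test_that("analysis-set selection honors role and PT filters", {
  ac <- analysis_config()
  corpus <- dplyr::bind_rows(
    make_record("A", drug = "clopidogrel", pts = "Subdural hematoma"),
    make_record("B", drug = "aspirin", role = "concomitant",
                pts = "Subdural hematoma"),
    make_record("C", drug = "aspirin", pts = "Nausea"),
    make_record("D", drug = "Plavix", pts = "Cerebral haematoma"),
    make_record("E", drug = "warfarin", pts = "Subdural hematoma"))
  sel <- select_analysis_set(corpus, ac)
  expect_setequal(sel$sets$clopidogrel$case_id, c("A", "D"))  # synonym mapped
  expect_equal(nrow(sel$sets$aspirin), 0)  # concomitant role excluded
  expect_equal(sel$sets$warfarin$case_id, "E")
  expect_equal(nrow(sel$corpus), 5)
  # per-drug sets are subsets of the corpus
  for (s in sel$sets) expect_true(all(s$case_id %in% corpus$case_id))
})

test_that("selection counts on a synthetic corpus match a brute-force tally", {
  cfg <- test_config(n_reports = 3000, seed = 9,
                     lambda_pairs = data.frame(drug = "clopidogrel",
                                               pt = "Subdural hematoma",
                                               lambda = 15))
  corpus <- deduplicate(generate_corpus(cfg))
  ac <- analysis_config()
  sel <- select_analysis_set(corpus, ac)
  brute <- function(d) {
    sum(vapply(seq_len(nrow(corpus)), function(i) {
      dr <- corpus$drugs[[i]]
      d %in% dr$drug_name[dr$role == "primary suspect"] &&
        any(corpus$reactions[[i]] %in% ac$target_pt_set)
    }, TRUE))
  }
  for (d in c("aspirin", "clopidogrel", "warfarin", "rosuvastatin")) {
    expect_equal(nrow(sel$sets[[d]]), brute(d))
  }
})

test_that("receipt-date windows filter the denominator corpus", {
  corpus <- dplyr::bind_rows(
    make_record("A", receipt = "2010-01-01"),
    make_record("B", receipt = "2020-01-01"))
  ac <- analysis_config(date_window = as.Date(c("2015-01-01", "2024-12-31")))
  sel <- select_analysis_set(corpus, ac)
  expect_equal(sel$corpus$case_id, "B")
})

test_that("age bands are closed on the left as printed", {
  expect_equal(derive_age_group(c(17.9, 18, 44.99, 45, 64.9, 65, 90)),
               c("<18", "18-44", "18-44", "45-64", "45-64", ">=65", ">=65"))
  expect_equal(derive_age_group(NA_real_), "unspecified")
  expect_error(derive_age_group(-1), class = "pvsignal_input_error")
})
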