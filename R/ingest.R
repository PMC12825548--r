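# Reading FAERS-style report tables, case deduplication, and selection of the
# analysis set (primary-suspect exposures to study drugs carrying a target
# PT).
#
# The on-disk dialect mirrors FAERS quarterly files: `$`-delimited ASCII
# tables DEMO (one row per case version), DRUG (one row per drug exposure),
# REAC (one row per reaction PT), THER (start dates per exposure) and OUTC
# (one row per regulatory outcome). Dates are YYYYMMDD; FAERS-style partial
# dates (YYYY, YYYYMM) and impossible dates are mapped to missing with a
# warning.

#' Configure the analysis set
#'
#' Defines the target event set, the study and control drugs, the counting
#' unit, and the optional receipt-date window. Defaults follow an
#' antiplatelet / CNS-hematoma surveillance design: four antiplatelet study
#' drugs, warfarin as positive control, rosuvastatin as negative control,
#' and a flat target PT list covering subdural, cerebral, extradural and
#' spinal epidural hematomas in both English spellings.
#'
#' @param target_pt_set character set of PT labels defining the target event.
#' @param study_drugs character set of study drug labels.
#' @param positive_control,negative_control single drug labels, not among
#'   the study drugs.
#' @param counting_unit `"case"` (one deduplicated case is one unit) or
#'   `"pair"` (one primary-suspect drug-event pair is one unit).
#' @param date_window optional length-2 `Date` vector filtering on receipt
#'   date, or `NULL`.
#' @param synonyms named character vector mapping alternative drug spellings
#'   (names) to canonical labels (values); matching is case-insensitive and
#'   exact, never fuzzy.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(target_pt_set = default_target_pts(),
                            study_drugs = c("aspirin", "clopidogrel",
                                            "ticagrelor", "prasugrel"),
                            positive_control = "warfarin",
                            negative_control = "rosuvastatin",
                            counting_unit = c("case", "pair"),
                            date_window = NULL,
                            synonyms = c("acetylsalicylic acid" = "aspirin",
                                         "plavix" = "clopidogrel",
                                         "brilinta" = "ticagrelor",
                                         "effient" = "prasugrel",
                                         "coumadin" = "warfarin",
                                         "crestor" = "rosuvastatin")) {
  counting_unit <- match.arg(counting_unit)
  if (!length(target_pt_set)) stop_config("'target_pt_set' must be non-empty",
                                          "target_pt_set")
  if (!length(study_drugs)) stop_config("'study_drugs' must be non-empty",
                                        "study_drugs")
  controls <- c(positive_control, negative_control)
  if (any(controls %in% study_drugs)) {
    stop_config("control drugs must not be study drugs", "positive_control")
  }
  if (!is.null(date_window) &&
      (length(date_window) != 2 || !inherits(date_window, "Date"))) {
    stop_config("'date_window' must be NULL or two Dates", "date_window")
  }
  structure(list(target_pt_set = unique(target_pt_set),
                 study_drugs = unique(study_drugs),
                 positive_control = positive_control,
                 negative_control = negative_control,
                 counting_unit = counting_unit,
                 date_window = date_window,
                 synonyms = synonyms),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @export
default_target_pts <- function() {
  c("Subdural hematoma", "Subdural haematoma",
    "Cerebral hematoma", "Cerebral haematoma",
    "Extradural hematoma", "Extradural haematoma",
    "Spinal epidural hematoma", "Spinal epidural haematoma")
}

normalize_drug <- function(x, synonyms = NULL) {
  x <- tolower(trimws(x))
  if (length(synonyms)) {
    hit <- match(x, tolower(names(synonyms)))
    x[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  }
  x
}

# Per-record normalized primary-suspect drug names (character list).
# Flattened once and re-split so cost stays linear in the exposure count.
primary_suspects <- function(corpus, synonyms = NULL) {
  dl <- corpus$drugs
  nd <- vapply(dl, function(d) length(d[["role"]]), 0L)
  nm <- unlist(lapply(dl, `[[`, "drug_name"), use.names = FALSE)
  rl <- unlist(lapply(dl, `[[`, "role"), use.names = FALSE)
  keep <- rl == "primary suspect"
  rec <- rep.int(seq_along(dl), nd)
  out <- unname(split(normalize_drug(nm[keep], synonyms),
                      factor(rec[keep], seq_along(dl))))
  out
}

#' Derive the age band of a report
#'
#' Bands are closed on the left: `<18`, `18-44`, `45-64`, `>=65`; a missing
#' age maps to `"unspecified"`.
#'
#' @param age_years numeric vector of ages in years (NA allowed).
#' @return character vector of band labels.
#' @export
derive_age_group <- function(age_years) {
  if (any(age_years < 0, na.rm = TRUE)) {
    stop_input("negative age is invalid")
  }
  if (any(age_years > 130, na.rm = TRUE)) {
    stop_input("age above 130 years is invalid")
  }
  out <- rep("unspecified", length(age_years))
  ok <- !is.na(age_years)
  out[ok & age_years < 18] <- "<18"
  out[ok & age_years >= 18 & age_years < 45] <- "18-44"
  out[ok & age_years >= 45 & age_years < 65] <- "45-64"
  out[ok & age_years >= 65] <- ">=65"
  out
}

#' Write a corpus to FAERS-style delimited tables
#'
#' Emits DEMO, DRUG, REAC, THER and OUTC tables (`$`-delimited ASCII) into
#' `dir`. Output is deterministic: rows are ordered by case id, version and
#' sequence number, so write -> read -> write is byte-stable.
#'
#' @param corpus report tibble as returned by [generate_corpus()] or
#'   [read_report_tables()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- dplyr::arrange(corpus, .data$case_id, .data$version_id)
  pid <- paste0(corpus$case_id, "-", corpus$version_id)

  demo <- data.frame(
    primaryid = pid,
    caseid = corpus$case_id,
    caseversion = corpus$version_id,
    fda_dt = format_faers_date(corpus$receipt_date),
    event_dt = format_faers_date(corpus$event_date),
    sex = SEX_CODES[corpus$sex],
    age = ifelse(is.na(corpus$age_years), "",
                 sprintf("%.2f", corpus$age_years)),
    age_cod = ifelse(is.na(corpus$age_years), "", "YR"),
    occp_cod = REPORTER_CODES[corpus$reporter],
    occr_country = corpus$country,
    serious = ifelse(corpus$serious, "Y", "N"),
    source = corpus$source,
    stringsAsFactors = FALSE)

  nd <- vapply(corpus$drugs, nrow, 0L)
  drug <- data.frame(
    primaryid = rep(pid, nd),
    drug_seq = unlist(lapply(nd, seq_len)),
    drugname = unlist(lapply(corpus$drugs, `[[`, "drug_name")),
    role_cod = ROLE_CODES[unlist(lapply(corpus$drugs, `[[`, "role"))],
    stringsAsFactors = FALSE)

  ther <- data.frame(
    primaryid = rep(pid, nd),
    dsg_drug_seq = drug$drug_seq,
    start_dt = format_faers_date(
      as.Date(unlist(lapply(corpus$drugs, function(d)
        as.character(d$start_date))))),
    stringsAsFactors = FALSE)

  nr <- lengths(corpus$reactions)
  reac <- data.frame(primaryid = rep(pid, nr),
                     pt = unlist(corpus$reactions),
                     stringsAsFactors = FALSE)

  no <- lengths(corpus$outcomes)
  outc <- data.frame(primaryid = rep(pid, no),
                     outc_cod = OUTCOME_CODES[unlist(corpus$outcomes)],
                     stringsAsFactors = FALSE)

  paths <- c(demo = file.path(dir, "DEMO.txt"), drug = file.path(dir, "DRUG.txt"),
             reac = file.path(dir, "REAC.txt"), ther = file.path(dir, "THER.txt"),
             outc = file.path(dir, "OUTC.txt"))
  for (nm in names(paths)) {
    write.table(get(nm), paths[[nm]], sep = "$", quote = FALSE,
                row.names = FALSE, na = "", fileEncoding = "UTF-8")
  }
  invisible(paths)
}

read_delim_table <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("missing mandatory table: %s", path))
  utils::read.table(path, sep = "$", header = TRUE, colClasses = "character",
                    quote = "", comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

parse_dates_warn <- function(x, what) {
  d <- parse_faers_date(x)
  bad <- sum(!is.na(x) & trimws(x) != "" & is.na(d))
  if (bad > 0) {
    rlang::warn(sprintf("%d unparseable or partial %s value(s) set to missing",
                        bad, what))
  }
  d
}

#' Read FAERS-style report tables into a corpus
#'
#' Joins the DEMO, DRUG, REAC and optional THER / OUTC tables on
#' (case id, version) keys into one record per case version. Unparseable or
#' partial dates become missing with a warning; a duplicated
#' (case id, version) key in DEMO is a data-integrity error.
#'
#' @param paths named list/vector of file paths with elements `demo`, `drug`,
#'   `reac` and optionally `ther`, `outc`. A directory written by
#'   [write_corpus()] may be given instead.
#' @return report tibble (same shape as [generate_corpus()] output).
#' @export
read_report_tables <- function(paths) {
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths)) {
    paths <- list(demo = file.path(paths, "DEMO.txt"),
                  drug = file.path(paths, "DRUG.txt"),
                  reac = file.path(paths, "REAC.txt"),
                  ther = file.path(paths, "THER.txt"),
                  outc = file.path(paths, "OUTC.txt"))
  }
  for (req in c("demo", "drug", "reac")) {
    if (is.null(paths[[req]])) stop_input(sprintf("missing mandatory table '%s'", req))
  }
  demo <- read_delim_table(paths[["demo"]])
  drug <- read_delim_table(paths[["drug"]])
  reac <- read_delim_table(paths[["reac"]])
  ther <- if (!is.null(paths[["ther"]]) && file.exists(paths[["ther"]]))
    read_delim_table(paths[["ther"]]) else NULL
  outc <- if (!is.null(paths[["outc"]]) && file.exists(paths[["outc"]]))
    read_delim_table(paths[["outc"]]) else NULL

  if (anyDuplicated(demo$primaryid)) {
    rlang::abort("duplicated (case, version) key in DEMO table",
                 class = "pvsignal_integrity_error")
  }

  receipt <- parse_dates_warn(demo$fda_dt, "receipt date")
  event <- parse_dates_warn(demo$event_dt, "event date")
  sex <- names(SEX_CODES)[match(demo$sex, SEX_CODES)]
  sex[is.na(sex) | demo$sex == ""] <- "unspecified"
  age <- suppressWarnings(as.numeric(demo$age))
  rep_codes <- REPORTER_CODES[REPORTER_CODES != ""]
  reporter <- names(rep_codes)[match(demo$occp_cod, rep_codes)]
  reporter[is.na(reporter)] <- "unspecified"

  if (!is.null(ther)) {
    drug$start_dt <- ther$start_dt[match(
      paste(drug$primaryid, drug$drug_seq),
      paste(ther$primaryid, ther$dsg_drug_seq))]
  } else {
    drug$start_dt <- NA_character_
  }
  drug$start_date <- parse_dates_warn(drug$start_dt, "therapy start date")
  drug$role <- names(ROLE_CODES)[match(drug$role_cod, ROLE_CODES)]
  if (anyNA(drug$role)) stop_input("unknown drug role code in DRUG table")
  drug <- drug[order(drug$primaryid, as.integer(drug$drug_seq)), ]

  drug_split <- split(seq_len(nrow(drug)), factor(drug$primaryid, demo$primaryid))
  reac_split <- split(reac$pt, factor(reac$primaryid, demo$primaryid))
  outc_split <- if (!is.null(outc) && nrow(outc)) {
    split(names(OUTCOME_CODES)[match(outc$outc_cod, OUTCOME_CODES)],
          factor(outc$primaryid, demo$primaryid))
  } else {
    rep(list(character(0)), nrow(demo))
  }

  dn <- drug$drugname; dr <- drug$role; dsd <- drug$start_date
  drugs_col <- lapply(drug_split, function(i) {
    quick_df(list(drug_name = dn[i], role = dr[i], start_date = dsd[i]))
  })

  corpus <- tibble::tibble(
    case_id = demo$caseid,
    version_id = as.integer(demo$caseversion),
    receipt_date = receipt,
    sex = sex,
    age_years = age,
    age_group = derive_age_group(age),
    reporter = reporter,
    country = demo$occr_country,
    serious = demo$serious == "Y",
    outcomes = unname(outc_split),
    reactions = unname(reac_split),
    drugs = unname(drugs_col),
    event_date = event,
    source = if ("source" %in% names(demo)) demo$source else "FAERS-like")
  dplyr::arrange(corpus, .data$case_id, .data$version_id)
}

#' Deduplicate report versions to one record per case
#'
#' Retains, for each `case_id`, the version with the greatest
#' (receipt date, version id) in lexicographic order — the standard FAERS
#' convention of keeping the latest report of a case. The result is sorted
#' by case id and the operation is idempotent.
#'
#' @param records report tibble.
#' @return deduplicated report tibble, one row per case.
#' @export
deduplicate <- function(records) {
  key <- as.numeric(records$receipt_date)
  key[is.na(key)] <- -Inf  # a version without a receipt date never wins
  o <- order(records$case_id, key, records$version_id)
  keep <- !duplicated(records$case_id[o], fromLast = TRUE)
  records[o[keep], ]
}

#' Select the per-drug analysis sets
#'
#' For each study and control drug, keeps the deduplicated records in which
#' that drug is a primary suspect *and* at least one reaction lies in the
#' target PT set. A record with two study drugs as primary suspects appears
#' under both (the multiplicity is reported in the `multiplicity` field).
#'
#' @param records deduplicated report tibble.
#' @param config an [analysis_config()].
#' @return list with `sets` (named list of per-drug record tibbles, study
#'   drugs then controls), `corpus` (the full deduplicated denominator
#'   population after any date-window filter) and `multiplicity` (number of
#'   records selected under more than one drug).
#' @export
select_analysis_set <- function(records, config) {
  stopifnot(inherits(config, "analysis_config"))
  if (!length(config$target_pt_set)) {
    stop_config("'target_pt_set' must be non-empty", "target_pt_set")
  }
  if (!is.null(config$date_window)) {
    records <- dplyr::filter(records,
                             .data$receipt_date >= config$date_window[1],
                             .data$receipt_date <= config$date_window[2])
  }
  ps <- primary_suspects(records, config$synonyms)
  hit_target <- vapply(records$reactions,
                       function(r) any(r %in% config$target_pt_set), TRUE)
  drugs <- c(config$study_drugs, config$positive_control,
             config$negative_control)
  sel <- lapply(drugs, function(d) {
    has_d <- vapply(ps, function(p) d %in% p, TRUE)
    which(has_d & hit_target)
  })
  names(sel) <- drugs
  study_idx <- unlist(sel[config$study_drugs])
  multiplicity <- sum(table(study_idx) > 1)
  if (multiplicity > 0) {
    rlang::inform(sprintf(
      "%d record(s) selected under more than one study drug", multiplicity))
  }
  list(sets = lapply(sel, function(i) records[i, ]),
       corpus = records,
       multiplicity = multiplicity)
}
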