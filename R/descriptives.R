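# Descriptive characteristic tables (case counting) and PT-share summaries
# (pair counting). All percentages are 100 * count / denominator rounded
# half-up to 2 decimals; machine-readable outputs keep the raw counts so no
# precision is lost to presentation rounding.

default_reporting_bands <- function() {
  tibble::tibble(band = c("2004-2008", "2009-2013", "2014-2018", "2019-2024"),
                 from = c(2004, 2009, 2014, 2019),
                 to = c(2008, 2013, 2018, 2024))
}

count_rows <- function(grouping, categories, counts, denom, multi = FALSE) {
  counts <- unname(counts)
  tibble::tibble(characteristic = grouping, category = unname(categories),
                 count = as.integer(counts), denominator = as.integer(denom),
                 percentage = round_half_up(100 * counts / denom, 2),
                 multi_valued = multi)
}

summarize_one_group <- function(cases, countries, bands) {
  n <- nrow(cases)
  sex <- table(factor(cases$sex, SEX_LEVELS))
  agegrp <- table(factor(cases$age_group, AGE_GROUP_LEVELS))
  reporter <- table(factor(cases$reporter, REPORTER_LEVELS))
  ctry <- table(factor(ifelse(cases$country %in% countries,
                              cases$country, "Other"),
                       c(countries, "Other")))
  serious <- c("serious" = sum(cases$serious),
               "non-serious" = sum(!cases$serious))
  outc <- vapply(OUTCOME_LEVELS, function(o)
    sum(vapply(cases$outcomes, function(x) o %in% x, TRUE)), 0)
  yr <- as.integer(format(cases$receipt_date, "%Y"))
  yr_band <- vapply(seq_len(nrow(bands)), function(i)
    sum(yr >= bands$from[i] & yr <= bands$to[i], na.rm = TRUE), 0)
  dplyr::bind_rows(
    count_rows("sex", names(sex), as.vector(sex), n),
    count_rows("age_group", names(agegrp), as.vector(agegrp), n),
    count_rows("reporter", names(reporter), as.vector(reporter), n),
    count_rows("country", names(ctry), as.vector(ctry), n),
    count_rows("seriousness", names(serious), unname(serious), n),
    count_rows("outcome", OUTCOME_LEVELS, outc, n, multi = TRUE),
    count_rows("reporting_year", bands$band, yr_band, n))
}

#' Descriptive characteristic summaries per drug and overall
#'
#' Tabulates sex, age band, reporter type, country (top-k plus "Other"),
#' seriousness, outcomes, and reporting-year bands — per study drug and for
#' the pooled set of distinct cases — with case counting throughout. The
#' outcome grouping is multi-valued (a case can carry several regulatory
#' outcomes) so its percentages may sum past 100; every other grouping sums
#' to 100 within rounding.
#'
#' @param sets named list of per-drug case tibbles (e.g.
#'   `select_analysis_set()$sets` restricted to study drugs).
#' @param top_countries number of named countries before pooling into
#'   "Other" (ranked on the pooled case set).
#' @param reporting_bands tibble with columns `band`, `from`, `to` defining
#'   receipt-year bands.
#' @return tibble with columns `drug` ("total" plus each set name),
#'   `characteristic`, `category`, `count`, `denominator`, `percentage`,
#'   `multi_valued`.
#' @export
summarize_characteristics <- function(sets, top_countries = 5,
                                      reporting_bands = default_reporting_bands()) {
  total <- dplyr::distinct(dplyr::bind_rows(sets), .data$case_id,
                           .keep_all = TRUE)
  ctab <- sort(table(total$country), decreasing = TRUE)
  countries <- utils::head(setdiff(names(ctab), "Other"), top_countries)

  out <- dplyr::bind_rows(
    dplyr::mutate(summarize_one_group(total, countries, reporting_bands),
                  drug = "total", .before = 1),
    dplyr::bind_rows(lapply(names(sets), function(d) {
      dplyr::mutate(summarize_one_group(sets[[d]], countries, reporting_bands),
                    drug = d, .before = 1)
    })))
  # drug mix within the pooled case set
  drug_counts <- vapply(sets, nrow, 0L)
  dplyr::bind_rows(
    dplyr::mutate(count_rows("drug", names(sets), drug_counts, nrow(total)),
                  drug = "total", .before = 1),
    out)
}

#' Per-PT counts and shares of the target-event corpus
#'
#' Counts drug-event pairs per PT and expresses each as a percentage of the
#' total target-event pair count (rounded half-up to 2 decimals). Accepts
#' either a named count vector (for worked examples over published counts)
#' or a report tibble, in which case each (case, primary-suspect drug)
#' appearance of a PT is one pair.
#'
#' @param x named numeric vector of per-PT counts, or a report tibble.
#' @param pts PT labels to tabulate when `x` is a tibble.
#' @param total denominator; defaults to the sum of the tabulated counts.
#' @param synonyms optional drug synonym map (tibble input only).
#' @return tibble with columns `pt`, `n`, `share` (percent).
#' @export
pt_share <- function(x, pts = NULL, total = NULL, synonyms = NULL) {
  if (is.data.frame(x)) {
    if (is.null(pts)) stop_input("'pts' is required for corpus input")
    n_ps <- lengths(primary_suspects(x, synonyms))
    counts <- vapply(pts, function(p)
      sum(n_ps * vapply(x$reactions, function(r) p %in% r, TRUE)), 0)
    names(counts) <- pts
  } else {
    if (is.null(names(x))) stop_input("count vector must be named by PT")
    counts <- x
  }
  total <- total %||% sum(counts)
  tibble::tibble(pt = names(counts), n = as.numeric(counts),
                 share = round_half_up(100 * as.numeric(counts) / total, 2))
}
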