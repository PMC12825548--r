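# Demographic stratification: the four-algorithm screen recomputed inside
# sex and age-band strata. The comparison denominator within a stratum is
# that stratum's own sub-corpus, so each stratum is a self-contained
# disproportionality analysis; records with an unspecified value on the
# dimension form a separate pool that is reported but never stratified.

#' Partition a corpus by a demographic dimension
#'
#' @param corpus deduplicated report tibble with derived age groups.
#' @param dimension `"sex"` or `"age_group"`.
#' @return list with `strata` (named list of sub-corpora over the specified
#'   levels), `unspecified` (the excluded pool) and `dimension`.
#' @export
stratify_corpus <- function(corpus, dimension = c("sex", "age_group")) {
  if (!is.character(dimension) || !dimension[1] %in% c("sex", "age_group")) {
    stop_config("unknown stratification dimension", "dimension")
  }
  dimension <- dimension[1]
  levels <- if (dimension == "sex") c("female", "male") else
    setdiff(AGE_GROUP_LEVELS, "unspecified")
  vals <- corpus[[dimension]]
  strata <- lapply(levels, function(l) corpus[vals == l, ])
  names(strata) <- levels
  list(strata = strata,
       unspecified = corpus[vals == "unspecified", ],
       dimension = dimension)
}

#' Four-algorithm results per demographic stratum
#'
#' Recomputes the full screen for one drug against the target event set
#' inside each stratum (the stratum sub-corpus is the denominator). The
#' stratum-level expected information component is exported as `eic` with
#' its 95% interval (`eic_low` = IC - 2 sd, `eic_high` = IC + 2 sd). Strata
#' with a < 3 are retained with all flags FALSE and `small_count = TRUE`;
#' when a = 0 the ROR/PRR columns carry NA as an undefined-result marker
#' while the BCPNN columns stay defined.
#'
#' @param corpus deduplicated report tibble.
#' @param drug drug label.
#' @param event_pts target PT set.
#' @param dimension `"sex"` or `"age_group"`.
#' @param counting_unit `"case"` or `"pair"`.
#' @param synonyms optional drug synonym map.
#' @return tibble keyed by (`drug`, `dimension`, `stratum`) with all
#'   statistics, EIC columns, flags and `small_count`; the unspecified pool
#'   appears as stratum `"unspecified"` with its size only.
#' @export
stratum_signals <- function(corpus, drug, event_pts,
                            dimension = c("sex", "age_group"),
                            counting_unit = "case", synonyms = NULL) {
  parts <- stratify_corpus(corpus, dimension)
  rows <- lapply(names(parts$strata), function(lvl) {
    sub <- parts$strata[[lvl]]
    if (!nrow(sub)) {
      return(tibble::tibble(drug = drug, dimension = parts$dimension,
                            stratum = lvl, stratum_size = 0L,
                            small_count = TRUE))
    }
    tab <- build_table(sub, drug, event_pts, counting_unit, synonyms)
    ic <- bcpnn_ic(tab)
    mg <- tryCatch({
      pooled <- pool_target_reactions(sub, event_pts)
      g <- mgps_ebgm(drug_event_grid(pooled, synonyms))
      j <- which(g$drug == normalize_drug(drug, synonyms) &
                   g$pt == "[target event]")
      if (length(j) == 1) list(ebgm = g$ebgm[j], ebgm05 = g$ebgm05[j])
      else list(ebgm = NA_real_, ebgm05 = NA_real_)
    }, error = function(e) list(ebgm = NA_real_, ebgm05 = NA_real_))
    res <- evaluate_signal(
      tab,
      ror_res = if (tab$a > 0) ror(tab) else NULL,
      prr_res = if (tab$a > 0) prr(tab) else NULL,
      ic_res = ic, ebgm = mg$ebgm, ebgm05 = mg$ebgm05)
    if (tab$a < 3) {  # small-count strata never flag
      res$ror_flag <- res$prr_flag <- res$bcpnn_flag <- res$mgps_flag <- FALSE
      res$joint_signal <- FALSE
    }
    meta <- tibble::tibble(drug = drug, dimension = parts$dimension,
                           stratum = lvl, stratum_size = nrow(sub),
                           eic = ic$ic, eic_low = ic$ic025,
                           eic_high = ic$ic975, small_count = tab$a < 3)
    dplyr::bind_cols(meta, res)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_rows(out, tibble::tibble(
    drug = drug, dimension = parts$dimension, stratum = "unspecified",
    stratum_size = nrow(parts$unspecified), small_count = TRUE))
  out
}
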