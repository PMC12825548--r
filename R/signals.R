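# Drug-level signal screening (all four algorithms + joint criterion) and
# PT-level count / IC025 matrices.

# Pool the target PT set into one pseudo-event so the whole event set
# occupies a single cell of the MGPS grid; background PTs keep their own
# columns. Records never contribute the pooled label twice.
pool_target_reactions <- function(corpus, event_pts, label = "[target event]") {
  corpus$reactions <- lapply(corpus$reactions, function(r) {
    hit <- r %in% event_pts
    if (any(hit)) unique(c(label, r[!hit])) else r
  })
  corpus
}

#' Screen study and control drugs with all four algorithms
#'
#' For every study drug plus the positive and negative control, builds the
#' 2x2 table against the target event set, computes ROR, PRR and the BCPNN
#' information component, obtains EBGM / EBGM05 from an MGPS fit over the
#' full drug-by-event grid (target PTs pooled into one event column), and
#' applies the per-algorithm thresholds and the joint signal criterion.
#'
#' @param selection result of [select_analysis_set()].
#' @param config the [analysis_config()] used for the selection.
#' @param counting_unit overrides `config$counting_unit` if given.
#' @return tibble with one row per drug: counts, all statistics, flags, IC
#'   category and `joint_signal`. The fitted MGPS prior is attached as
#'   attribute `"mgps_prior"`.
#' @export
signal_table <- function(selection, config, counting_unit = NULL) {
  unit <- counting_unit %||% config$counting_unit
  corpus <- selection$corpus
  pooled <- pool_target_reactions(corpus, config$target_pt_set)
  grid <- mgps_ebgm(drug_event_grid(pooled, config$synonyms))
  prior <- attr(grid, "prior")
  tgt <- grid[grid$pt == "[target event]", ]

  drugs <- names(selection$sets)
  roles <- c(rep("study", length(config$study_drugs)),
             "positive control", "negative control")
  ps <- primary_suspects(corpus, config$synonyms)
  rows <- lapply(seq_along(drugs), function(i) {
    d <- normalize_drug(drugs[i], config$synonyms)
    tab <- build_table(corpus, d, config$target_pt_set, unit, config$synonyms,
                       ps = ps)
    j <- match(d, tgt$drug)
    res <- evaluate_signal(
      tab,
      ror_res = if (tab$a > 0) ror(tab) else NULL,
      prr_res = if (tab$a > 0) prr(tab) else NULL,
      ic_res = bcpnn_ic(tab),
      ebgm = if (is.na(j)) NA_real_ else tgt$ebgm[j],
      ebgm05 = if (is.na(j)) NA_real_ else tgt$ebgm05[j])
    dplyr::mutate(res, drug = drugs[i], role = roles[i], unit = unit,
                  .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mgps_prior") <- prior
  out
}

#' Per-PT signal matrix (counts and IC025)
#'
#' Tallies, for each (drug, PT) pair under pair counting, the number of
#' primary-suspect reports and the BCPNN information component with its
#' lower bound — the long-format analogue of a PT-level count heatmap and
#' its IC025 companion.
#'
#' @param corpus deduplicated report tibble (denominator population).
#' @param drugs character vector of drug labels.
#' @param pts character vector of PT labels.
#' @param synonyms optional drug synonym map.
#' @return tibble with columns `drug`, `pt`, `n`, `ic`, `ic025`.
#' @export
pt_level_matrix <- function(corpus, drugs, pts, synonyms = NULL) {
  ps <- primary_suspects(corpus, synonyms)
  rows <- lapply(drugs, function(d) {
    dplyr::bind_rows(lapply(pts, function(p) {
      tab <- build_table(corpus, d, p, "pair", synonyms, ps = ps)
      bc <- bcpnn_ic(tab)
      tibble::tibble(drug = d, pt = p, n = tab$a, ic = bc$ic, ic025 = bc$ic025)
    }))
  })
  dplyr::bind_rows(rows)
}
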