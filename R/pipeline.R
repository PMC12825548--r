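# End-to-end orchestration: simulate -> write -> ingest -> deduplicate ->
# select -> four-algorithm screen -> PT matrices -> stratified analysis ->
# time-to-onset -> descriptives, with a machine-readable manifest. Given the
# same configuration (including seed) a re-run writes byte-identical files.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage,
                         conditionMessage(e)),
                 class = "pvsignal_stage_error", parent = e)
  })
}

write_output_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "", eol = "\n",
                   quote = TRUE, fileEncoding = "UTF-8")
  path
}

#' Run the full synthetic-corpus analysis pipeline
#'
#' Generates a corpus under `config`, round-trips it through the on-disk
#' report-table format, deduplicates, selects the per-drug analysis sets,
#' and writes: the drug-level signal table, PT-level count/IC025 matrix,
#' PT shares, sex- and age-stratified results, Weibull time-to-onset fits
#' with the Kruskal-Wallis comparison and cumulative curves, descriptive
#' characteristic tables, the generator's expected contingency tables, and
#' a manifest with row counts and content hashes for every output.
#'
#' @param out_dir output directory (created; existing files overwritten).
#' @param config a [synthetic_config()].
#' @param analysis an [analysis_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return invisibly, a list with all in-memory results plus the manifest.
#' @export
run_pipeline <- function(out_dir, config = synthetic_config(),
                         analysis = analysis_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  config <- validate_synthetic_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  corpus_dir <- file.path(out_dir, "corpus")
  raw <- run_stage("simulate", generate_corpus(config))
  run_stage("write", write_corpus(raw, corpus_dir))
  corpus <- run_stage("ingest", read_report_tables(corpus_dir))
  dedup <- run_stage("deduplicate", deduplicate(corpus))
  selection <- run_stage("select", select_analysis_set(dedup, analysis))

  signals <- run_stage("signals", signal_table(selection, analysis))
  ptm <- run_stage("pt_level", pt_level_matrix(
    dedup, analysis$study_drugs, analysis$target_pt_set, analysis$synonyms))
  shares <- run_stage("pt_share", pt_share(
    dplyr::bind_rows(selection$sets[analysis$study_drugs]),
    pts = analysis$target_pt_set, synonyms = analysis$synonyms))

  strat <- run_stage("stratify", dplyr::bind_rows(lapply(
    c("sex", "age_group"), function(dim) {
      dplyr::bind_rows(lapply(analysis$study_drugs, function(d) {
        stratum_signals(dedup, d, analysis$target_pt_set, dim,
                        analysis$counting_unit, analysis$synonyms)
      }))
    })))

  tto <- run_stage("tto", {
    samples <- lapply(analysis$study_drugs, function(d)
      compute_tto(selection$sets[[d]], d, synonyms = analysis$synonyms))
    names(samples) <- analysis$study_drugs
    fits <- lapply(samples, function(s) {
      tryCatch(fit_weibull(s), error = function(e) NULL)
    })
    fit_rows <- dplyr::bind_rows(lapply(analysis$study_drugs, function(d) {
      f <- fits[[d]]; s <- samples[[d]]
      tibble::tibble(
        drug = d, n = s$n, n_excluded = s$n_excluded,
        median_days = if (s$n) median(s$onsets_days) else NA_real_,
        q25 = if (s$n) quantile(s$onsets_days, 0.25, names = FALSE) else NA_real_,
        q75 = if (s$n) quantile(s$onsets_days, 0.75, names = FALSE) else NA_real_,
        alpha = f$alpha %||% NA_real_, alpha_low = f$alpha_low %||% NA_real_,
        alpha_high = f$alpha_high %||% NA_real_,
        beta = f$beta %||% NA_real_, beta_low = f$beta_low %||% NA_real_,
        beta_high = f$beta_high %||% NA_real_,
        failure_type = f$failure_type %||% NA_character_)
    }))
    kw <- if (sum(vapply(samples, function(s) s$n, 0L) > 0) >= 2) {
      compare_medians(samples)
    } else {
      list(H = NA_real_, df = NA_real_, p_value = NA_real_)
    }
    list(samples = samples, fits = fit_rows, kw = kw,
         curves = cumulative_curves(samples))
  })

  descr <- run_stage("descriptives",
                     summarize_characteristics(selection$sets[analysis$study_drugs]))
  gt <- run_stage("ground_truth", ground_truth_tables(config))

  files <- c(
    signals = write_output_csv(signals, file.path(out_dir, "signals.csv")),
    pt_level = write_output_csv(ptm, file.path(out_dir, "pt_level.csv")),
    pt_share = write_output_csv(shares, file.path(out_dir, "pt_share.csv")),
    stratified = write_output_csv(strat, file.path(out_dir, "stratified.csv")),
    tto_fits = write_output_csv(tto$fits, file.path(out_dir, "tto_fits.csv")),
    tto_curves = write_output_csv(tto$curves, file.path(out_dir, "tto_curves.csv")),
    descriptives = write_output_csv(descr, file.path(out_dir, "descriptives.csv")),
    ground_truth = write_output_csv(gt, file.path(out_dir, "ground_truth.csv")))

  cfg_path <- file.path(out_dir, "config.json")
  writeLines(jsonlite::serializeJSON(config, digits = NA), cfg_path)

  manifest <- list(
    package = "pvsignal",
    version = as.character(utils::packageVersion("pvsignal")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    counts = list(
      reports_raw = nrow(raw),
      reports_ingested = nrow(corpus),
      cases_deduplicated = nrow(dedup),
      analysis_sets = lapply(selection$sets, nrow),
      kruskal_wallis = tto$kw),
    files = lapply(as.list(files), function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(config = config, corpus = dedup, selection = selection,
                 signals = signals, pt_level = ptm, pt_share = shares,
                 stratified = strat, tto = tto, descriptives = descr,
                 ground_truth = gt, manifest = manifest, files = files))
}
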