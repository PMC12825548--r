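# Four-grid (2x2) contingency tables and the frequentist / Bayesian
# disproportionality statistics computed from them.
#
#             target event(s)   other events
#  target drug        a               b
#  other drugs        c               d
#
# Counting units: under "case" counting each deduplicated case is one unit
# classified by its primary-suspect drugs and reaction set; under "pair"
# counting each (case, primary-suspect drug, reaction PT) triple is one
# unit, matching PT-level tallies.

#' Construct a 2x2 contingency table
#'
#' @param a,b,c,d non-negative cell counts: target drug with target event,
#'   target drug with other events, other drugs with target event, other
#'   drugs with other events.
#' @return object of class `contingency_table` with fields `a`, `b`, `c`,
#'   `d`, `n`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop_input("contingency cells must be finite and non-negative")
  }
  if (sum(cells) < 1) stop_input("contingency table must hold at least one unit")
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> a=%g b=%g c=%g d=%g (n=%g)\n",
              x$a, x$b, x$c, x$d, x$n))
  invisible(x)
}

#' Build the 2x2 table for one drug against an event set
#'
#' @param corpus deduplicated report tibble (the denominator population).
#' @param drug target drug label (normalized against `synonyms`).
#' @param event_pts character set of PT labels forming the target event.
#' @param counting_unit `"case"` or `"pair"` (see module header).
#' @param synonyms optional drug synonym map as in [analysis_config()].
#' @param ps optional precomputed per-record primary-suspect list (an
#'   internal fast path for callers tabulating many event sets on one
#'   corpus).
#' @return a [contingency_table()].
#' @export
build_table <- function(corpus, drug, event_pts,
                        counting_unit = c("case", "pair"), synonyms = NULL,
                        ps = NULL) {
  counting_unit <- match.arg(counting_unit)
  if (!nrow(corpus)) stop_input("empty corpus")
  drug <- normalize_drug(drug, synonyms)
  ps <- ps %||% primary_suspects(corpus, synonyms)
  has_d <- vapply(ps, function(p) drug %in% p, TRUE)
  if (counting_unit == "case") {
    has_e <- vapply(corpus$reactions, function(r) any(r %in% event_pts), TRUE)
    a <- sum(has_d & has_e); b <- sum(has_d & !has_e)
    c <- sum(!has_d & has_e); d <- sum(!has_d & !has_e)
  } else {
    n_ps <- lengths(ps)
    k_in <- vapply(corpus$reactions, function(r) sum(r %in% event_pts), 0L)
    k_all <- lengths(corpus$reactions)
    a <- sum(has_d * k_in)
    b <- sum(has_d * (k_all - k_in))
    c <- sum((n_ps - has_d) * k_in)
    d <- sum((n_ps - has_d) * (k_all - k_in))
  }
  contingency_table(a, b, c, d)
}

# Haldane-Anscombe policy: add 0.5 to every cell, but only when some cell is
# zero (otherwise estimates are left untouched). BCPNN and MGPS never use it;
# their priors smooth zeros natively.
correct_zero_cells <- function(tab) {
  if (min(tab$a, tab$b, tab$c, tab$d) > 0) return(c(tab$a, tab$b, tab$c, tab$d))
  c(tab$a, tab$b, tab$c, tab$d) + 0.5
}

#' Reporting odds ratio with Wald 95% CI
#'
#' ROR = (a d)/(b c); the interval is
#' exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)). When any cell is zero,
#' 0.5 is added to all four cells first (Haldane-Anscombe continuity
#' correction).
#'
#' @param table a [contingency_table()].
#' @return list with `ror`, `ror_low`, `ror_high`, `corrected`.
#' @export
ror <- function(table) {
  z <- correct_zero_cells(table)
  if (z[2] * z[3] == 0) {
    rlang::abort("ROR undefined: b*c = 0 after continuity correction",
                 class = "pvsignal_undefined_error")
  }
  est <- (z[1] * z[4]) / (z[2] * z[3])
  se <- sqrt(sum(1 / z))
  list(ror = est,
       ror_low = exp(log(est) - 1.96 * se),
       ror_high = exp(log(est) + 1.96 * se),
       corrected = min(table$a, table$b, table$c, table$d) == 0)
}

#' Proportional reporting ratio with Wald 95% CI
#'
#' PRR = \[a/(a+b)\] / \[c/(c+d)\]; the interval is
#' exp(ln PRR +/- 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))). The zero-cell
#' policy matches [ror()].
#'
#' @inheritParams ror
#' @return list with `prr`, `prr_low`, `prr_high`, `corrected`.
#' @export
prr <- function(table) {
  z <- correct_zero_cells(table)
  if (z[1] + z[2] == 0 || z[3] + z[4] == 0 || z[3] == 0) {
    rlang::abort("PRR undefined after continuity correction",
                 class = "pvsignal_undefined_error")
  }
  est <- (z[1] / (z[1] + z[2])) / (z[3] / (z[3] + z[4]))
  se <- sqrt(1 / z[1] - 1 / (z[1] + z[2]) + 1 / z[3] - 1 / (z[3] + z[4]))
  list(prr = est,
       prr_low = exp(log(est) - 1.96 * se),
       prr_high = exp(log(est) + 1.96 * se),
       corrected = min(table$a, table$b, table$c, table$d) == 0)
}

#' BCPNN information component (closed form)
#'
#' Posterior expectation and variance of the information component
#' IC = log2 P(drug, event) / (P(drug) P(event)) under the standard BCPNN
#' Beta/Dirichlet priors (alpha1 = beta1 = 1, alpha = beta = 2, gamma11 = 1,
#' with gamma tuned so the prior IC expectation is 0):
#'
#'   gamma  = (N + alpha)(N + beta) / ((a+b+alpha1)(a+c+beta1))
#'   E(IC)  = log2 \[ (a + 1)(N + alpha)(N + beta) /
#'                    ((N + gamma)(a+b+alpha1)(a+c+beta1)) \]
#'   V(IC)  = (ln 2)^-2 \[ (N - a + gamma - 1)/((a+1)(1+N+gamma)) +
#'                         (N - a - b + 1)/((a+b+1)(1+N+2)) +
#'                         (N - a - c + 1)/((a+c+1)(1+N+2)) \]
#'
#' IC025 = E(IC) - 2 sqrt(V(IC)), the conventional lower bound used as the
#' signal threshold; IC975 is the matching upper bound. Defined (finite) for
#' every non-negative table, including a = 0.
#'
#' @inheritParams ror
#' @return list with `ic`, `ic025`, `ic975`, `ic_var`.
#' @export
bcpnn_ic <- function(table) {
  a <- table$a; b <- table$b; c <- table$c; n <- table$n
  alpha1 <- 1; beta1 <- 1; alpha <- 2; beta <- 2; gamma11 <- 1
  gamma <- gamma11 * (n + alpha) * (n + beta) /
    ((a + b + alpha1) * (a + c + beta1))
  ic <- log2((a + gamma11) * (n + alpha) * (n + beta) /
               ((n + gamma) * (a + b + alpha1) * (a + c + beta1)))
  v <- ((n - a + gamma - gamma11) / ((a + gamma11) * (1 + n + gamma)) +
          (n - a - b + alpha - alpha1) / ((a + b + alpha1) * (1 + n + alpha)) +
          (n - a - c + beta - beta1) / ((a + c + beta1) * (1 + n + beta))) /
    log(2)^2
  list(ic = ic, ic025 = ic - 2 * sqrt(v), ic975 = ic + 2 * sqrt(v), ic_var = v)
}

ic_category <- function(ic025) {
  if (ic025 <= 0) "none"
  else if (ic025 <= 1.5) "weak"
  else if (ic025 <= 3) "medium"
  else "strong"
}

#' Combine the four algorithms into a signal decision
#'
#' Applies the per-algorithm thresholds — ROR: a >= 3 and CI lower bound
#' > 1; PRR: a >= 3 and CI lower bound > 1; BCPNN: IC025 > 0; MGPS:
#' EBGM05 > 2 with a > 0 — and the joint criterion (all four
#' simultaneously). The IC strength category is "weak" for IC025 in
#' (0, 1.5\], "medium" in (1.5, 3\], "strong" above 3.
#'
#' @param table a [contingency_table()].
#' @param ror_res,prr_res,ic_res results of [ror()], [prr()], [bcpnn_ic()]
#'   for `table` (any may be NULL, flagging that algorithm FALSE).
#' @param ebgm,ebgm05 MGPS point estimate and lower percentile for this
#'   cell (NA flags MGPS FALSE).
#' @return one-row tibble with all statistics, per-algorithm flags, the IC
#'   category and `joint_signal`.
#' @export
evaluate_signal <- function(table, ror_res, prr_res, ic_res,
                            ebgm = NA_real_, ebgm05 = NA_real_) {
  a <- table$a
  ror_flag <- !is.null(ror_res) && a >= 3 && ror_res$ror_low > 1
  prr_flag <- !is.null(prr_res) && a >= 3 && prr_res$prr_low > 1
  bcpnn_flag <- !is.null(ic_res) && ic_res$ic025 > 0
  mgps_flag <- is.finite(ebgm05) && ebgm05 > 2 && a > 0
  tibble::tibble(
    a = a, b = table$b, c = table$c, d = table$d, n = table$n,
    ror = if (is.null(ror_res)) NA_real_ else ror_res$ror,
    ror_low = if (is.null(ror_res)) NA_real_ else ror_res$ror_low,
    ror_high = if (is.null(ror_res)) NA_real_ else ror_res$ror_high,
    prr = if (is.null(prr_res)) NA_real_ else prr_res$prr,
    prr_low = if (is.null(prr_res)) NA_real_ else prr_res$prr_low,
    prr_high = if (is.null(prr_res)) NA_real_ else prr_res$prr_high,
    ic = if (is.null(ic_res)) NA_real_ else ic_res$ic,
    ic025 = if (is.null(ic_res)) NA_real_ else ic_res$ic025,
    ic975 = if (is.null(ic_res)) NA_real_ else ic_res$ic975,
    ebgm = ebgm, ebgm05 = ebgm05,
    ror_flag = ror_flag, prr_flag = prr_flag,
    bcpnn_flag = bcpnn_flag, mgps_flag = mgps_flag,
    ic_category = if (is.null(ic_res)) "none" else ic_category(ic_res$ic025),
    joint_signal = ror_flag && prr_flag && bcpnn_flag && mgps_flag)
}
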