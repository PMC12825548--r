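---
title: "Methods: disproportionality screening, stratification and time-to-onset modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening, stratification and time-to-onset modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## Scope and data model

`pvsignal` implements a complete pharmacovigilance screening pipeline for
spontaneous reporting systems (SRS) such as FAERS: ingestion of quarterly-style
report tables, case deduplication, selection of primary-suspect exposures
against a flat MedDRA-preferred-term (PT) event list, four-algorithm
disproportionality analysis with a joint signal criterion, demographic
stratification, Weibull time-to-onset (TTO) modelling, and descriptive
reporting. The packaged defaults describe an antiplatelet / CNS-hematoma
surveillance design — four study drugs (aspirin, clopidogrel, ticagrelor,
prasugrel), warfarin as positive control, rosuvastatin as negative control, and
a target event set of subdural, cerebral, extradural and spinal epidural
hematoma PTs in both English spellings — but every element is configurable.

A report record carries a case identifier and version, receipt date, drug
exposures with role codes (primary suspect, secondary suspect, concomitant,
interacting) and therapy start dates, a non-empty set of reaction PTs, an
optional event date, demographics, seriousness and regulatory outcome
categories. Deduplication retains, per case, the version with the greatest
(receipt date, version id) — the usual "latest version wins" convention for
FAERS case series; no cross-case probabilistic duplicate matching is
attempted, because it is not auditable without access to the identifier fields
that public extracts lack.

Two counting units coexist deliberately. Descriptive tables use **case**
counting (one deduplicated case, one unit). PT-level matrices use **pair**
counting (one primary-suspect drug-event pair, one unit), which is why a
report total can exceed the patient total in the same analysis.

## The four-grid table and the frequentist statistics

For a drug $D$ and an event set $\mathcal{E}$, every counting unit falls in
exactly one cell of

|              | event in $\mathcal{E}$ | other events |
|--------------|-----------------------:|-------------:|
| drug $D$     | $a$                    | $b$          |
| other drugs  | $c$                    | $d$          |

The reporting odds ratio and proportional reporting ratio are

$$\mathrm{ROR} = \frac{ad}{bc}, \qquad
  \mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)},$$

with Wald 95% intervals on the log scale,
$\exp\!\left(\ln\mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d}\right)$ and
$\exp\!\left(\ln\mathrm{PRR} \pm 1.96\sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}\right)$.
When any cell is zero the Haldane–Anscombe correction adds 0.5 to **all four**
cells, and only then; the Bayesian methods below never use it, their priors
smooth zeros natively. When $a = 0$ in a stratum the ROR/PRR columns are
reported as `NA` (an undefined-result marker) rather than a corrected
pseudo-estimate, since a stratum with no observed events should not display a
point estimate.

## BCPNN information component

The information component is the shrunk $\log_2$ observed-to-expected measure
of the Bayesian confidence propagation neural network. We use the classic
closed-form formulation with hyperparameters $\alpha_1=\beta_1=1$,
$\alpha=\beta=2$, $\gamma_{11}=1$ and $\gamma$ tuned so the prior expectation
of IC is zero:

$$\gamma = \frac{(N+\alpha)(N+\beta)}{(a+b+\alpha_1)(a+c+\beta_1)},\qquad
E(IC) = \log_2 \frac{(a+\gamma_{11})(N+\alpha)(N+\beta)}
                    {(N+\gamma)(a+b+\alpha_1)(a+c+\beta_1)}$$

with the matching closed-form variance (spelled out in `bcpnn_ic()`), and
$IC_{025} = E(IC) - 2\sqrt{V(IC)}$, the conventional "two standard
deviations" lower bound. The closed form is finite for every non-negative
table, including $a=0$, and is monotone increasing in $a$ at fixed
$b, c, d$ — both properties are tested. Signal strength is banded on
$IC_{025}$: (0, 1.5] weak, (1.5, 3] medium, $>3$ strong. A Monte-Carlo
credible-interval variant was considered and rejected: the closed form is
deterministic, testable to $10^{-10}$ against an independent script, and is
the formulation the $IC_{025}>0$ threshold was calibrated on.

## MGPS empirical Bayes

The multi-item gamma Poisson shrinker models cell counts $n_{ij}$ over the
**full** primary-suspect-drug × PT grid (zero cells included) as
$\mathrm{Poisson}(\lambda_{ij} E_{ij})$ with
$E_{ij} = (\text{row total} \times \text{column total})/N$ and a
two-component gamma mixture prior on $\lambda$. The five hyperparameters are
fitted by maximizing the marginal negative-binomial mixture likelihood over
all cells; the prior is fitted on the whole corpus grid, never only on the
study drugs, because shrinkage strength depends on the grid. For the
drug-level screen the target PT set is pooled into a single pseudo-event
column so the whole event set occupies one cell; PT-level analyses use the
unpooled grid.

Per cell, the posterior is again a two-component gamma mixture;
$\mathrm{EBGM} = \exp E[\ln\lambda \mid n]$ is the empirical-Bayes geometric
mean and `ebgm05` its 5th posterior percentile. The threshold
"$\mathrm{EBGM05} > 2$ with $a>0$" historically refers to the 5th percentile
(EB05), so that is the default; a 2.5th percentile is available via the
`percentile` argument for a symmetric 95% reading.

Two numerical points deserve emphasis.

* **Multimodality.** The mixture likelihood is multimodal: a grid dominated
  by exact-independence cells admits a spurious mode in which both components
  collapse to a spike at $\lambda=1$ and genuine excess cells are swallowed.
  `fit_mgps_prior()` therefore multi-starts — the conventional start
  (0.2, 0.1, 2, 4, 1/3) and a data-informed start with a tight null component
  plus a component centred on the largest observed $n/E$ — explores with
  Nelder-Mead, polishes with BFGS, and keeps the best converged mode.
* **Shrinkage is toward the prior, not toward 1.** The often-quoted sandwich
  $1 < \mathrm{EBGM} < n/E$ is not a theorem. Cells whose raw ratio lies
  below a fitted prior component mean are pulled *up* toward it, and
  near-null cells can cross below 1 because the geometric mean of a
  null-centred posterior is below its arithmetic mean (Jensen). The sandwich
  provably applies to cells with $n \ge 3$ reporting above every prior
  component mean, and that is the regime in which the test suite asserts it.
  Relatedly, on a grid in which exactly one cell deviates from independence
  and carries only a handful of events, the all-null prior can be the true
  maximum-likelihood fit, so MGPS legitimately shrinks an isolated weak
  signal to 1 — a power property of empirical Bayes worth remembering when
  interpreting single-association corpora.

## The joint criterion

A drug-event pair is flagged only when all four algorithms agree:
$a\ge 3$ with ROR CI lower bound $>1$; $a \ge 3$ with PRR CI lower bound
$>1$; $IC_{025} > 0$; $\mathrm{EBGM05} > 2$ with $a > 0$. The conjunction is
deliberately conservative; its null calibration (joint firing $\le 5\%$ — in
practice $\approx 0$ — on null corpora) is part of the acceptance suite.

## Stratified analysis

Stratification recomputes the full screen inside sex and age-band strata,
using the **stratum's own sub-corpus as the denominator** — each stratum is a
self-contained disproportionality analysis, not a reweighting of the pooled
table. Records with an unspecified value on the dimension form a separate
reported pool. The stratum-level expected information component ("EIC") is
the BCPNN posterior IC expectation with its $\pm 2\sqrt{V}$ interval; no
separate estimator is invented. Strata with $a<3$ are reported (never
dropped) with all flags `FALSE` and a small-count marker, so downstream
tables stay complete. No formal interaction testing is performed.

## Time-to-onset and the Weibull shape test

Onset is the whole-day interval from the primary-suspect therapy start date
to the event date. Records missing either date, or with a negative interval,
are excluded with tallied reasons; partial dates (year or year-month
precision) are treated as missing. Zero-day onsets are **recoded to 0.5
days** by default: same-day events are clinically real and the Weibull
support requires $t>0$; `zero_day = "exclude"` is available.

`fit_weibull()` maximizes the Weibull likelihood in $(\log\alpha,
\log\beta)$ (scale in days, shape dimensionless) and builds 95% intervals
from the observed information on the log scale, back-transformed — bounds are
therefore always positive. A parametric-bootstrap interval was considered
and not adopted: the asymptotic intervals show 90–99% empirical coverage at
the sample sizes involved (tested), at a fraction of the cost. The reported
median and IQR are empirical quantiles of the raw onset days, not
model-based quantities: published onset medians such as 442.5 days are
half-integers of day counts, which only empirical quantiles produce. Hazard
shape is classified from $\beta$ and its CI: early failure
($\beta<1$, CI upper $<1$), wear-out failure ($\beta>1$, CI lower $>1$),
random failure (CI includes 1); an inconsistent bound configuration falls
back to random with a warning. Fits refuse fewer than 10 onsets and
degenerate (all-equal) samples rather than returning noise. Onset medians
across drugs are compared with the tie-corrected Kruskal–Wallis test
(`stats::kruskal.test`), significant at 0.05; no censoring or competing-risk
model is attempted because an SRS only contains reported events.

## The synthetic reporting system

Because no SRS extract ships with the package, every downstream stage is
validated against a generator whose ground truth is analytic. Each report
draws one primary-suspect drug from a categorical marginal, demographics from
configurable mixtures, then each PT **independently** with probability
$\min(1,\; q_{pt} \cdot \lambda_{drug,pt} \cdot m_{sex} \cdot m_{age})$. No
renormalization is applied — this is what keeps every 2×2 cell expectation
computable in closed form (`ground_truth_tables()`), at the cost of a slight
upward drift of realized PT marginals when $\lambda$ is large, which is
documented rather than corrected. Three consequences of this design:

* event baseline probabilities are independent Bernoulli marginals and are
  *not* constrained to sum to one (the drug marginal, being categorical, is);
* a report that draws no PT receives one **background** PT from the
  renormalized background marginal, satisfying "reactions are non-empty"
  without touching target-set cell membership, so the closed-form tables stay
  exact;
* stratum multipliers apply only to the (drug, PT) pairs listed in
  `signal_multipliers`. Scaling *all* of a drug's PTs by the stratum effect
  would cancel out of the within-stratum odds ratio and make configured
  demographic effects undetectable — the multiplier is an association
  modifier, not a reporting-volume modifier.

Onset times are drawn per drug from configured Weibull laws, rounded half-up
to whole days, zero-day draws kept. Duplicated cases are re-emitted as a
second version with receipt date +1 day and a perturbed reporter field.
Missingness is applied per field, independently, after generation (MCAR) —
no informative missingness mechanism is modelled. The generator does not
model reporting-bias dynamics (media attention, regulatory warnings), so
passing tests demonstrate algorithmic correctness on a stylized SRS, not
robustness to the reporting artifacts of real databases.

Default parameters mirror the study conditions the package is patterned on:
drug-level signal multipliers on the reporting-odds-ratio scale observed for
the six drugs (22, 27, 8, 17; 38 for the positive control, 0.4 for the
negative), a female multiplier of 1.6 and an elderly multiplier of 1.2 on the
study drugs' signal pairs, demographic mixtures matching the published case
characteristics, and per-drug Weibull onset models with early-failure shapes
(e.g. scale 930 days, shape 0.62 for aspirin). Where the source material
gives no value (background drug and event marginals, duplication rate 5%,
date-missingness rates chosen so roughly a quarter of target cases carry both
dates), values were fixed once at what a practitioner would call a realistic
SRS and are not tuned.

## Problem sizes used in validation

The simulation-based checks run at corpus size $N = 20{,}000$ — large enough
that the designated association's expected count sits near 27 and normal
asymptotics apply, small enough to keep a 300-corpus suite comfortable: null
calibration over 200 seeds, detection and Wald-coverage of an injected
$\lambda = 8$ association over 100 seeds, Weibull recovery
($n = 500$, shape 0.6 and 1.0) over 200 seeds, and a 400-cell MGPS grid
simulated from a stated two-gamma prior (tight null component
$\Gamma(20,20)$, elevated component $\Gamma(2,0.4)$, 10% weight) checked
cell-by-cell against numerical integration of the prior density times the
Poisson likelihood.

## Known limitations

* Drug-name normalization is case-insensitive exact matching through a
  configurable synonym list; no fuzzy matching, by design, for determinism
  and auditability.
* The MedDRA hierarchy is not traversed; the event set is a flat PT list.
* The deduplication rule is the single implemented policy; field-combination
  duplicate detection across case identifiers is out of scope.
* Published headline estimates from full-scale databases (e.g. a clopidogrel
  ROR of 26.79) are not reproducible from a desk-scale corpus, because their
  denominators are the tens of millions of background reports; the package
  validates arithmetic identities on published count tables and operating
  characteristics on synthetic corpora instead.
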