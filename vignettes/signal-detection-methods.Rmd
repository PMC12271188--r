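---
title: "Disproportionality signal detection and onset modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection and onset modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
library(dplyr)
```

# The problem

Spontaneous adverse-event databases such as FAERS collect individual
case safety reports (ICSRs): one report names the drugs a patient took
(each with a role code -- primary suspect, secondary suspect,
concomitant, interacting), the adverse reactions coded as MedDRA
preferred terms (PTs), demographics, outcomes, and therapy dates.
Because there is no denominator of exposed patients, drug--event
associations are screened by *disproportionality*: for a drug $D$ and
event $E$, the 2x2 table

|            | event $E$ | other events |
|------------|-----------|--------------|
| drug $D$   | $a$       | $b$          |
| other drugs| $c$       | $d$          |

compares how often $E$ is reported with $D$ against the background of
all other reports. `faersignal` implements the standard screening
workflow end to end -- deduplication, primary-suspect restriction,
PT/SMQ mapping, four disproportionality statistics with signal criteria
and Bonferroni correction, demographic subgroups, and Weibull
time-to-onset modelling -- together with a synthetic ICSR generator so
the whole pipeline is testable without a database download.

# Deduplication

FAERS cases are versioned and sometimes resubmitted, so raw tables
overcount. Two rules are applied in order:

1. **Latest version.** Among reports sharing a `case_id`, only the one
   with the greatest `primary_id` is kept.
2. **Six-field redundancy.** Among the survivors, reports identical on
   *(event date, age, sex, reaction-PT set, drug-name set, country)*
   are collapsed to the record with the latest receipt date (ties to
   the greatest `primary_id`).

Two choices here are genuinely open and are resolved as follows. The
"drug group administered" component of the key is read as the *set of
normalized drug names* on the report; drug names are normalized by
uppercasing and whitespace-squishing only (no ingredient/brand
mapping), so matching is exact and deterministic. Missing key fields
enter the key as an explicit sentinel, so two reports missing the same
field can still be judged duplicates -- the intent is to collapse
resubmissions, which typically share their missingness pattern. A
consequence worth knowing: in data where event dates are frequently
missing, genuinely distinct but clinically indistinguishable reports
(same sex, same single common PT, same drug, both dates missing) are
also collapsed. That is the rule working as specified, not an error;
the run log reports both stages' removal counts so the effect is
visible.

Partial dates (`YYYYMM`, `YYYY`) are completed to the first of the
month/year and flagged; FAERS age-unit codes (`DEC`, `YR`, `MON`,
`WK`, `DY`, `HR`) are converted to years, with unknown codes treated
as missing.

# The four statistics

All four operate on the same table; $N = a+b+c+d$ and the expected
count is $E = (a+b)(a+c)/N$ (the row-by-column convention, with no
stratification).

**ROR** (reporting odds ratio): $ad/bc$, with the Wald interval
$\exp(\ln \mathrm{ROR} \pm z\sqrt{1/a+1/b+1/c+1/d})$. Signal when the
lower 95% bound exceeds 1 and $a \ge 3$.

**PRR** (proportional reporting ratio):
$\frac{a/(a+b)}{c/(c+d)}$ with
$SE = \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}$ on the log scale, plus the
Pearson $\chi^2$ of the table (uncorrected by default -- the
conventional criterion $\chi^2 \ge 4$ is stated for the uncorrected
statistic; Yates' correction is available by flag). Signal when
$\mathrm{PRR} \ge 2$, $\chi^2 \ge 4$ and $a \ge 3$.

**IC** (information component):
$\log_2 \frac{a + 0.5}{E + 0.5}$, with the closed-form credibility
bounds $IC_{025} = IC - 3.3(a+0.5)^{-1/2} - 2.0(a+0.5)^{-3/2}$ and
$IC_{975} = IC + 2.4(a+0.5)^{-1/2} + 0.5(a+0.5)^{-3/2}$. Defined at
$a = 0$; signal when $IC_{025} > 0$.

**EBGM** (empirical Bayes geometric mean). Counts are modelled as
$a_i \sim \mathrm{Poisson}(\lambda_i E_i)$ with
$\lambda_i \sim w\,\Gamma(\alpha_1,\beta_1) +
(1-w)\,\Gamma(\alpha_2,\beta_2)$ (shape/rate). The marginal is a
two-component negative-binomial mixture whose likelihood is maximized
over all observed drug--event pairs by BFGS on log parameters (logit
for $w$) from five fixed starting points, convergence tolerance
`reltol = 1e-10`; the fit is deterministic given data. Each pair's
posterior is again a two-component gamma mixture;
$\mathrm{EBGM} = \exp(\mathbb{E}[\ln \lambda \mid a])$ is evaluated in
closed form via the digamma function, and EBGM05/EBGM95 are found by
bisection on the posterior mixture CDF (tolerance `1e-8`, bracket
grown from the posterior mean plus 10 SDs). Signal when
$\mathrm{EBGM05} > 2$.

Each formula is implemented in its standard literature form (Wald
log-scale CIs, the closed-form IC credibility approximation, the
two-component gamma--Poisson shrinker), stated explicitly in the code
so any deviation from a reader's preferred variant can be audited line
by line.

**Zero cells.** ROR/PRR with a zero cell are returned as `NA` with a
machine-readable reason; the Haldane--Anscombe $+0.5$ correction is
applied only when explicitly requested. Silent continuity corrections
change estimates for exactly the sparse pairs where screening
decisions are most fragile.

**P-values and multiplicity.** The 2x2 p-value is the Pearson
$\chi^2$ test (1 df, no continuity correction) when every expected
cell is at least 5, and the two-sided Fisher exact test otherwise. The
Bonferroni correction multiplies by $m$, capped at 1; $m$ defaults to
the number of drug--event pairs tested in the run and is
configurable, since no single convention fits every screening design.

**Consensus.** A pair is flagged when *at least one* method's
criterion is met (with $a = 0$ never flagged); all per-method flags
are reported so stricter consensus rules can be applied downstream.

# SMQ aggregation

The bundled osteoporosis query holds ten PTs (bone density decreased,
bone formation decreased, bone loss, bone marrow oedema syndrome,
osteopenia, osteoporosis, osteoporosis postmenopausal, osteoporotic
fracture, resorption bone increased, senile osteoporosis). Two
counting conventions exist for the SMQ-level $a$:

* **PT-row sum** (default): the sum of member-PT counts, so a report
  carrying $k$ member PTs contributes $k$. This is the convention
  whose totals match published per-PT count columns exactly, which is
  why it is the default here.
* **Unique report** (`method = "unique_report"`): each report counted
  once -- MedDRA-standard case counting, available behind a flag.

# Subgroups

Signal subgroups split by sex (male/female; unknown retained only in
the overall row) and by age at 60 years (younger `< 60`, older
`>= 60`, the cutoff on the older side; age-missing reports drop out of
the strata). Descriptive tables use finer bands (<18, 18--64.9,
65--85, >85), since both groupings are in common use for different
purposes. Subgroup 2x2 tables are *stratum-internal*: numerator and
background are both restricted to the stratum. The alternative --
stratum numerator against the whole-database background -- answers a
different question (how the stratum's reporting compares with everyone)
and inflates subgroup estimates when the stratum itself reports the
event more; the stratum-internal choice is recorded in the output
metadata.

# Time to onset

Onset is the whole-day difference between the event date and the
*earliest* therapy start of the primary-suspect drug. Durations that
are missing either date or are $\le 0$ are excluded and counted
(Weibull support is positive; a zero duration is indistinguishable
from a date-entry artifact). The Weibull fit maximizes the
log-likelihood in $(\log\beta, \log\alpha)$ by BFGS
(`reltol = 1e-12`); 95% CIs are Wald intervals from the observed
information on the log scale. Degenerate samples (all equal, $n < 3$)
are errors, not guesses. The failure curve is classified from the
shape CI: entirely below 1 -> early failure (decreasing hazard);
containing 1 -> random failure; entirely above 1 -> wear-out failure
(risk grows with treatment duration).

Two onset distributions are compared with the two-sided Mann--Whitney
U test -- chosen because onset distributions are strongly skewed; this
is an interpretation, not a convention inherited from any single
study -- exact by full enumeration when both samples have at most 8
values (midranks for ties), the tie-corrected normal approximation
otherwise. A log-rank option exists for users who prefer the survival
framing; spontaneous reports carry no censoring information, so
neither test uses it. Year-bucket summaries use half-open intervals
[0, 30), [30, 90), [90, 180), [180, 365), [365, Inf) days.

# The synthetic generator

`faers_sim_config()` describes a reporting universe with known ground
truth; `simulate_faers()` draws from it reproducibly and
`write_faers_quarter()` emits the `'$'`-delimited quarterly dialect the
reader consumes. Per report: a primary-suspect drug by market share;
each PT independently with probability `rate * rho(drug, pt)` (capped
at 0.99); a report that draws no event receives the filler PT
`"drug ineffective"` so reaction sets are never empty while the study
PTs keep their configured rates exactly; demographics and missingness
per config; therapy start uniform over 2004--2024; onset a Weibull
draw rounded up to whole days; receipt shortly after the event.
Duplicates are then injected: *version* duplicates (same case, higher
`primary_id`, receipt +30 d, one updated field) and *redundancy*
duplicates (new case, identical six-field key, receipt +60 d), all
recorded in a manifest.

The default scenario is calibrated to the shape of a two-drug
antiviral safety study: a rarely reported first-generation drug (0.5%
of reports) against a ~16x more reported successor (8%), four
background drugs, the ten osteoporosis PTs at low background rates
plus fifty background PTs, planted rate ratios from ~11 to ~180, and
onset parameters Weibull(1.07, 1332) and Weibull(1.29, 2288) days.
Event draws are independent across PTs given the drug (no
event-correlation model), calendar structure is minimal, and reporter
occupation has no effect on reporting -- so passing tests demonstrate
that the *estimators and plumbing* are correct under known truth, not
that real reporting behaviour (event clustering, secular trends,
notoriety effects) is captured.

One consequence of a shared background deserves note: when a second
drug with very large planted rate ratios occupies a visible share of
the universe, it inflates the background rate of the shared PTs, so
the measured ROR of the first drug sits below its planted rho. This is
the same contamination that affects real disproportionality screens
and is left visible on purpose; parameter-recovery checks therefore
use a dedicated single-signal configuration.

# Problem sizes used by the test suite

The bundled checks run at sizes chosen to make their Monte-Carlo error
small relative to the property being asserted: null calibration and
rate-ratio recovery at 200,000 reports (coverage of a 95% interval
estimated to about +-0.5%, recovery over 100 seeded runs), Weibull CI
coverage over 500 fits of 254 durations (the scale of a small SMQ
cohort), duplicate-removal accounting at 10,000 reports, and oracle
comparisons (closed forms, quadrature, exhaustive enumeration) at
whatever size makes the oracle exact.

# Worked example

```{r example, eval = FALSE}
cfg <- faers_sim_config(n_reports = 50000, seed = 7)
dir <- tempfile(); out <- tempfile()
simulate_faers_files(cfg, dir)

study <- study_config(c("ADEFOVIR", "TENOFOVIR"))
run_faers_analysis(dir, study, out)

readr::read_tsv(file.path(out, "adefovir_smq_signals.tsv"), skip = 1)
```

The SMQ table carries the overall row plus the four subgroup rows
(male, female, younger, older), each with N, the four statistics with
their intervals, p-values, per-method flags and the consensus flag.

# Known limitations

* No MedDRA hierarchy: PT matching is exact on lowercased strings, and
  SMQ scope (narrow/broad) is not modelled.
* Expected counts are unstratified (`E = (a+b)(a+c)/N`); no covariate
  stratification of the shrinker.
* No multi-drug interaction terms; one 2x2 per (drug, PT).
* The pre-2012 LAERS schema is not read.
* Spontaneous-report biases (under/over-reporting, notoriety) are out
  of scope of any disproportionality method; flags are screening
  signals, not causal claims.
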