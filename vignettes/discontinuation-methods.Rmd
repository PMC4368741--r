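---
title: "Methods: prescribing episodes, pregnancy cohorts and discontinuation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prescribing episodes, pregnancy cohorts and discontinuation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preglith)
```

This vignette is the package's own account of what it computes and why the
design is the way it is. The application throughout is lithium prescribing
around pregnancy in UK-style primary-care records, but every rule is
parameterised and drug-agnostic.

## The inferential problem

A prescribing database records *issues* — dates on which a repeat
prescription was written — not ingestion and not explicit stop orders.
Discontinuation must therefore be inferred from silence: a prescription is
treated as the **last of an episode** when more than 91 prescription-free
days follow it. Most repeat prescriptions cover one or two months, so 91
days (three months) tolerates an early or late refill without mistaking
ordinary refill slack for stopping. The same constant drives three distinct
rules, deliberately kept identical so that a single notion of "being on
treatment" runs through the pipeline:

1. episode construction (`build_episodes()`): split where a gap exceeds 91
   days, a gap of exactly 91 days does **not** split;
2. the continuity predicate (`is_continuous_at()`): an issue in days
   [−183, −92] before the anchor plus a later issue in [−91, −1] at most 91
   days after its immediate predecessor — i.e. the woman was settled on
   the drug, not merely issued once;
3. "receiving prescriptions at date t" (postpartum status): at least one
   issue within the 91 days up to and including t.

All windows are closed intervals of whole days; "6 months" is 183 days,
"3 months" 91, "1 year" 365, "2 years" 730, "6 weeks" 42. Dates are `Date`
objects (integer days), so no rule ever depends on time-of-day or on
month arithmetic.

## Pregnancy cohort and follow-up

Pregnancy start is gestational day 0 (first day of the last menstrual
period). When gestational length is unrecorded the duration is set to 280
days, the conventional term length; recorded durations must lie in
[100, 320] days. Miscarriages and terminations are excluded from the
prevalence and discontinuation cohorts — their start dates are too poorly
determined — but still count as pregnancies when non-pregnant comparator
periods are carved out. Eligibility additionally demands one registration
period covering the pregnancy and the 183 days before it: a practice
transfer inside that span would hide prescriptions and mimic
discontinuation.

Follow-up for the discontinuation cohort starts at day −91 (the woman is
guaranteed an issue in [−91, −1] by the continuity predicate) and is
censored at gestational day 220 or at an earlier delivery. The reason for
220 — two months before term — is subtle: a genuinely continuing woman
whose final pre-delivery issue happens to fall shortly before delivery
would otherwise be classified as an observed "last prescription" merely
because the pregnancy ended. Stopping observation two months early leaves
room for the next refill to prove continuation. The product-limit
estimator is standard; at tied times events are ranked before censorings
(the usual convention — both leave the risk set after the time point).

**Continuation at six weeks** is keyed on the last-prescription date:
`last_rx_date >= start + 43`. The first six weeks are taken as gestational
days 0–42 (6 × 7 = 42 completed days), so day 43 is the first "beyond"
day. The boundary could defensibly be drawn one day earlier; day ≥ 43 was
chosen once and is exercised explicitly by the boundary tests. Under the
cohort's eligibility this classification coincides with "any issue after
day 42", because an issue after a > 91-day silence would open a new
episode, not extend the old one.

Prevalence is tabulated by 3-year calendar periods keyed on the **year of
pregnancy start** (start anchors every other window in the analysis; the
alternative — delivery year — would split pregnancies across period
boundaries inconsistently with the exposure windows). Percentages are
100·n/total, rounded half-up to 3 decimals, matching the precision at
which prevalences of order 0.01% are meaningfully reported.

## Comparator construction

Pregnancy is not the only reason to stop lithium, so the pregnant curve
needs a non-pregnant reference. For every woman not in the case cohort the
package derives her **non-pregnant periods**: inside the study window and
a registration period, aged 14–50 (age is calendar-year arithmetic,
`year − birth_year`, the only age available when records carry birth year
alone), at least 365 days after the end of any previous pregnancy and at
least 730 days before the start of any subsequent one — around a pregnancy
[S, D] the excluded zone is [S − 730, D + 364]. One **index date** is drawn
uniformly over the union of those days to stand in for a pregnancy start;
the woman becomes a candidate only if she satisfies the same continuity
predicate at that date that cases satisfy at pregnancy start. A failed
draw discards the woman rather than redrawing: redrawing until the
predicate passes would over-select dates inside long prescribing histories
and bias the comparator toward persistent users. Two comparators per case
are then sampled without replacement within the case's 5-year age band
(bands 15–19 … 45–49; 14 folds into the lowest, 50 into the highest —
band anchors are a convention the data cannot pin down). A stratum with
too few candidates raises an explicit shortfall error naming the band
rather than silently relaxing the match. Comparator follow-up mirrors
cases exactly: from index − 91, censored at index + 220.

## Confidence intervals

The characteristics table reports each cell k out of group size n with a
95% interval computed on the log-odds scale:

$$L = \ln\frac{p}{1-p}, \qquad
  se = \frac{\sqrt{p(1-p)/(n-1)}}{p(1-p)}, \qquad
  \mathrm{logit}^{-1}\!\left(L \pm t_{0.975,\,df}\; se\right)$$

with p = k/n and df = total cohort size − 1 (51 when the cohort has 52
women), the natural choice when many subgroup proportions share one
table. This is the logit-transform interval a Stata-style `proportion`
analysis produces; the package treats it as a first-class operation
(`proportion_ci()`) and its test suite verifies it against every defined
published-style cell at the printed precision. The interval is undefined
when k = 0 or k = n (the log-odds diverge) and such cells are rendered
"-"; `n < 2` is a contract error. Percentages print to 1 decimal, prose
percentages to whole percent, rounding half-up in both cases.

Prior continuous time on the drug is measured from the start of the
episode in progress at day −91 up to day −91, and categorised as
< 183 days, 183–365 days, > 365 days ("< 6", "6–12", "> 12 months") —
the categories are published convention, the day boundaries are this
package's choice. Parity uses the recorded value when present, otherwise
the larger of prior delivery-outcome pregnancies and older children in
the household (household members born after the mother but before the
index pregnancy).

## The synthetic generator

`simulate_ehr()` exists so that every downstream stage is testable without
proprietary data; its defaults (`default_study_scenario()`) define the
package's study conditions. Per woman: birth year uniform 1952–1980;
registration from up to two years before the window (8% join late, to
exercise registration-gap exclusions) to past its end; lithium issues
every 28 ± 7 days; a per-refill baseline stop hazard of 0.025 (absorbing
within a course, with a 70% chance of a new course after a 120–720-day
break — lithium users commonly cycle on and off treatment); pregnancies
for 8% of women at maternal ages 25–39, with 10% miscarriages and 5%
terminations; a Bernoulli stop decision of probability 0.625 at
gestational day 28 (around week 4, when a pregnancy is typically
recognised) for women still being prescribed then; a 10% chance of
restarting during pregnancy after a clear break, otherwise a 40% chance
of restarting 30–150 days after the end of pregnancy; co-prescribed
antidepressant/antipsychotic/anticonvulsant courses for 35/35/17% of
women; and a 2% chance of leaving the practice within 183 days of
delivery.

Two defaults are calibrated rather than assumed, by simulating ~1,600
cohort women and reading the result off the package's own estimators: the
recognition-stop probability 0.625 places the *continuing* fraction at six
weeks in 0.30–0.36 (roughly one third, the qualitative pattern the
analysis is designed to detect), and the baseline hazard 0.025 keeps
non-pregnant persistence 42 days after the index date above 0.80. The
`pregnancy_prob` knob (default 0.08) is a generator extension: some
control over the pregnant-to-non-pregnant balance is needed for the 2:1
age-band match to be feasible, and 8% over an 18-year window is a
realistic order for this subpopulation.

The generator's stopping model makes one identity available to the test
suite: because the recognition decision is independent of everything that
precedes it, the stopped-before-six-weeks fraction satisfies
f(p) = q + p(1 − q), where q = f(0) is the baseline component. The
parameter-recovery test runs the generator twice (at the default p and at
p = 0, ~2,000 women each, cohorts of several hundred), recovers
p̂ = (f − q̂)/(1 − q̂), and requires agreement within 3 Monte-Carlo
standard errors; it also checks that 1 − S(133) from the Kaplan–Meier
curve equals the stopped fraction exactly, since the scenario admits no
censoring before follow-up day 133.

What the generator does **not** emulate: dose and titration, serum-level
monitoring, gestational-age mis-dating, practice-level clustering,
secular prescribing trends, or prescriptions issued by specialist
services outside primary care. Green tests therefore demonstrate that the
pipeline's logic is faithful to its stated rules on data with the assumed
structure — not that the rules are robust to recording artefacts real
databases contain.

## Numerical and degenerate-input choices

* Same-day duplicate issues collapse to one before any rule is applied.
* Unsorted issue vectors are a contract error, not silently sorted, in
  the exposure primitives; table-level drivers sort per patient.
* `km_estimate()` emits an explicit time-0 row with survival 1; a curve
  of all-censored observations is identically 1.
* Empty inputs flow through: zero women yield four empty tables, an empty
  cohort yields no curves and no characteristics, and `run_study()` still
  returns a complete object with zero counts.
* The multiple-eligible-pregnancy tie (one woman, several qualifying
  pregnancies) is resolved by a seeded uniform choice; the three RNG
  streams (pregnancy choice, index dates, control sampling) are seeded
  independently so changing one stage's seed cannot perturb another.
* Loaders force unknown pregnancy durations to 280 days and recompute the
  end date, then validate every declared invariant exhaustively,
  reporting offending rows.

## Problem sizes

The package's own experiments are sized to run comfortably on a single
CPU: oracle-equivalence sweeps use 1,000 random instances of ≤ 12–15
dates/subjects against brute-force reimplementations; the
parameter-recovery experiment uses two 2,000-woman generator runs; the
pipeline tests use 150–400-woman runs. A full default `run_study()` takes
a few seconds.

## Known limitations

Calendar-year age, a single authoritative pregnancy start date (no
adjudication between LMP and gestational-age dating), no dose or supply
modelling, no between-group hypothesis testing (cohorts this small would
make such tests uninformative — the interval widths carry that message),
and a comparator match on age band only.
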