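# preglith

Drug-utilisation analysis of medication **discontinuation around pregnancy**
from longitudinal primary-care prescribing records, with lithium as the
worked application.

Women prescribed a maintenance drug such as lithium face a difficult
decision when they conceive: continuing carries a possible fetal risk,
stopping carries a risk of maternal relapse. Prescribing databases record
every issued prescription, so the question *"do women stop when they become
pregnant?"* can be answered from issue dates alone — if the episodes of
prescribing, the pregnancy windows and a fair non-pregnant comparison group
are constructed carefully. This package implements that construction as a
tested, reusable pipeline for epidemiologists working with primary-care
EHR-style tables (patients, registrations, prescriptions, pregnancies).

## The method

All rules are day-granular, on closed intervals, with pregnancy start
(first day of the last menstrual period) as day 0:

* **Prescribing episodes** — consecutive issues belong to one episode while
  inter-issue gaps are ≤ 91 days; an issue followed by > 91
  prescription-free days is the *last prescription* of its episode.
* **Continuous prescribing at an anchor date** (cohort entry, applied
  identically at pregnancy start and at comparator index dates): at least
  one issue in days [−183, −92] and a further issue in [−91, −1] no more
  than 91 days after its predecessor.
* **Follow-up** — starts at day −91; censored at gestational day 220 (two
  months before a term delivery, so the record's end cannot masquerade as
  discontinuation) or at an earlier actual delivery. Time to last
  prescription is summarised by the Kaplan–Meier product-limit estimator
  S(t) = ∏_{t_i ≤ t} (1 − d_i/n_i), events ranked before tied censorings.
* **Continuation at six weeks** — last prescription on/after gestational
  day 43 (the first six weeks are days 0–42).
* **Comparators** — non-pregnant periods (≥ 1 year after any previous
  pregnancy, ≥ 2 years before any subsequent one, inside a registration
  period, ages 14–50); one uniform random index date per woman; 2
  comparators per case sampled without replacement within 5-year age bands.
* **Proportions** — each characteristics-table cell k/n carries a 95%
  interval computed on the log-odds scale,
  L = ln(p/(1−p)), se = √(p(1−p)/(n−1)) / (p(1−p)),
  bounds = logit⁻¹(L ± t₀.₉₇₅,df · se), df = total cohort size − 1;
  undefined (rendered “-”) when k = 0 or k = n.

A seeded synthetic-EHR generator (`simulate_ehr()`) emulates the
lithium-prescribed subpopulation — repeat issues every 21–35 days, a step
increase in stopping at pregnancy recognition (~gestational week 4),
postpartum restarts, co-prescribed psychotropics, miscarriages and
terminations — so the entire pipeline is testable without any proprietary
data. See the methods vignette (`vignettes/discontinuation-methods.Rmd`)
for every parameter and the reasoning behind it.

## Worked example

```r
library(preglith)
res <- run_study(default_study_scenario())
print(res)
```

```
Discontinuation study run
  women_loaded           1787
  pregnancies            44
  pregnancies_eligible   37
  cohort_size            19
  continued_beyond_6w    7
  comparators_sampled    38
  continued beyond 6 weeks: 7/19 (37%)
```

Of 44 synthetic pregnancies, 37 survive the eligibility rules (delivery
outcome, start inside 1995–2012, one registration period covering the
pregnancy plus 183 days before). 19 women were continuously prescribed
lithium at pregnancy start; 7 of them (37%) continued beyond six weeks,
and each was matched to two non-pregnant continuously-prescribed
comparators. The two product-limit curves separate sharply:

```r
km <- res$km_curves
km_survival_at(km[km$group == "pregnant", ], 133)    # 0.368
km_survival_at(km[km$group == "comparator", ], 133)  # 0.842
```

At follow-up day 133 — six gestational weeks — 37% of pregnant women but
84% of non-pregnant comparators are still within a prescribing episode:
pregnancy, not background discontinuation, drives the drop. Cell-level
output carries the logit-t intervals:

```r
ch <- res$characteristics
ch[ch$variable == "comedication" & ch$group == "continued", ]
#             level k n  pct lower upper
#    antidepressant 3 7 42.9  11.7  80.9
#     antipsychotic 4 7 57.1  19.1  88.3
#    anticonvulsant 1 7 14.3   1.4  65.9
```

`run_study(..., out_dir = "results")` writes every table
(`prevalence.csv`, `cohort.csv`, `comparators.csv`, `km_curves.csv`,
`characteristics.csv`, `restarts.csv`) plus a `run_metadata.txt` log of
seeds and stage counts; column contracts are in `inst/extdata/schema.md`.
A thin command-line front end lives at `inst/cli/preglith.R`
(`simulate` and `run` subcommands).

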