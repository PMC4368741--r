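# Table schemas

All tables are comma-separated text with a header row; dates are ISO-8601
(`YYYY-MM-DD`); missing values are empty fields. Day arithmetic is integer
and all windows are closed intervals.

## Input tables

### patients.csv
| column | type | notes |
|---|---|---|
| patient_id | text | unique |
| birth_year | integer | 1945-2005 |
| household_id | text | optional; links household members |
| recorded_parity | integer | optional; parity from the medical record |

### registrations.csv
| column | type | notes |
|---|---|---|
| patient_id | text | |
| reg_start | date | start of continuous registration |
| reg_end | date | `reg_start < reg_end`; periods per patient non-overlapping |

### prescriptions.csv
| column | type | notes |
|---|---|---|
| patient_id | text | |
| issue_date | date | must fall inside a registration period of the patient |
| drug_class | text | one of lithium, antidepressant, antipsychotic, anticonvulsant, other |

### pregnancies.csv
| column | type | notes |
|---|---|---|
| patient_id | text | |
| start_date | date | first day of the last menstrual period (gestational day 0) |
| duration_days | integer | forced to 280 when `duration_known` is false; otherwise 100-320 |
| delivery_date | date | `start_date + duration_days` (end of pregnancy for all outcomes) |
| outcome | text | delivery, miscarriage, or termination |
| duration_known | logical | |

## Output tables

### prevalence.csv
`period, n_before, pct_before, n_any, pct_any, n_after6w, pct_after6w, total`
— one row per calendar period plus an `All years` row; percentages are
100·n/total to 3 decimals.

### cohort.csv
`patient_id, start_date, delivery_date, followup_start, censor_date,
last_rx_date, event_observed, time, status, continuation_class`

### restarts.csv
`patient_id, continuation_class, restarted_during_pregnancy,
on_drug_at_183d_postpartum`

### comparators.csv
`patient_id, index_date, band, matched_case_id`

### km_curves.csv
`group, time, n_risk, n_event, n_censor, survival` — `time` in days from
follow-up start (91 days before pregnancy start / index date).

### characteristics.csv
`variable, level, group, k, n, pct, lower, upper, ci_defined` — logit-t
95% confidence bounds in percent, 1 decimal; undefined (k = 0 or k = n)
rendered as empty fields.
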