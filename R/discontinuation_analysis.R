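# Stage 4: the discontinuation cohort, time-to-last-prescription
# Kaplan-Meier estimation with gestational censoring, continuation
# classification at six weeks, restart and co-medication description,
# parity estimation, and the characteristics table with logit-transform
# binomial confidence intervals.

#' Assemble the discontinuation cohort
#'
#' One entry per woman continuously prescribed the drug at the start of an
#' eligible (delivered, in-window, fully registered) pregnancy. When a woman
#' has several qualifying pregnancies one is selected uniformly at random
#' (seed the RNG for reproducibility). Follow-up starts 91 days before
#' pregnancy start; observation is censored at gestational day 220 (two
#' months before a full-term delivery, so that a final prescription is not
#' spuriously labelled "last" merely because delivery ended the record) or
#' at an earlier actual delivery. The event is the last prescription of the
#' episode in progress: the final issue followed by more than 91
#' prescription-free days.
#'
#' @param eligible eligible pregnancy rows (from [assess_eligibility()],
#'   `eligible == TRUE`).
#' @param prescriptions prescription table; rows of class `drug` are used.
#' @param drug drug class (default `"lithium"`).
#' @param gap_days refill-gap rule in days (default 91).
#' @param censor_day gestational day of administrative censoring
#'   (default 220).
#' @param six_week_day first gestational day counting as "beyond 6 weeks"
#'   (default 43).
#' @return data frame of class `discontinuation_cohort`, one row per woman:
#'   identifiers and dates, `followup_start`, `censor_date`, `last_rx_date`,
#'   `event_observed`, `time` (days from follow-up start), `status`
#'   (1 event / 0 censored) and `continuation_class`.
#' @export
assemble_cohort <- function(eligible, prescriptions, drug = "lithium",
                            gap_days = 91, censor_day = 220,
                            six_week_day = 43) {
  rx <- prescriptions[prescriptions$drug_class == drug, , drop = FALSE]
  rx_by <- split(rx$issue_date, rx$patient_id)
  out <- list()
  for (pid in unique(eligible$patient_id)) {
    issues <- rx_by[[pid]]
    if (is.null(issues)) next
    issues <- sort(unique(issues))
    pr <- eligible[eligible$patient_id == pid, , drop = FALSE]
    ok <- vapply(seq_len(nrow(pr)), function(i)
      is_continuous_at(issues, pr$start_date[i], gap_days), logical(1))
    pr <- pr[ok, , drop = FALSE]
    if (!nrow(pr)) next
    i <- if (nrow(pr) == 1L) 1L else sample.int(nrow(pr), 1L)
    s <- pr$start_date[i]
    entry <- data.frame(
      patient_id = pid,
      start_date = s,
      delivery_date = pr$delivery_date[i],
      followup_start = s - DAYS_3M,
      censor_date = min(s + censor_day, pr$delivery_date[i]),
      last_rx_date = last_prescription_from(issues, s - 1L, gap_days))
    entry$event_observed <- entry$last_rx_date <= entry$censor_date
    entry$time <- as.integer(
      (if (entry$event_observed) entry$last_rx_date else entry$censor_date) -
        entry$followup_start)
    entry$status <- as.integer(entry$event_observed)
    entry$continuation_class <- classify_continuation(
      entry$last_rx_date, s, six_week_day)
    out[[length(out) + 1L]] <- entry
  }
  res <- do.call(rbind, c(out, list(empty_cohort())))
  rownames(res) <- NULL
  class(res) <- c("discontinuation_cohort", "data.frame")
  res
}

empty_cohort <- function() {
  data.frame(patient_id = character(), start_date = as.Date(character()),
             delivery_date = as.Date(character()),
             followup_start = as.Date(character()),
             censor_date = as.Date(character()),
             last_rx_date = as.Date(character()),
             event_observed = logical(), time = integer(),
             status = integer(), continuation_class = character())
}

#' Classify continuation at six weeks of gestation
#'
#' A woman counts as having continued beyond the first six weeks when her
#' last prescription falls on or after gestational day 43 (the first six
#' weeks being days 0-42, by which point the pregnancy is likely known).
#'
#' @param last_rx_date last-prescription date(s).
#' @param start_date pregnancy start date(s).
#' @param six_week_day boundary day (default 43).
#' @return `"continued_beyond_6w"` or `"stopped_before_6w"` per entry.
#' @export
classify_continuation <- function(last_rx_date, start_date,
                                  six_week_day = 43) {
  ifelse(as_day(last_rx_date) >= as_day(start_date) + six_week_day,
         "continued_beyond_6w", "stopped_before_6w")
}

#' Product-limit (Kaplan-Meier) estimate of time to last prescription
#'
#' Standard product-limit estimator over right-censored times. At tied
#' times, events are ranked before censorings (both leave the risk set
#' after the time point). The curve starts at survival 1 at time 0.
#'
#' @param time follow-up times in days (event or censoring).
#' @param status 1 = event (last prescription observed), 0 = censored.
#' @return data frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, beginning with a `time = 0` row.
#' @export
km_estimate <- function(time, status) {
  check_that(length(time) == length(status) && length(time) > 0,
             "km_estimate: need equal-length, nonempty time and status")
  check_that(all(status %in% c(0, 1)), "km_estimate: status must be 0/1")
  tt <- sort(unique(time))
  n <- length(time)
  n_risk <- n_event <- n_censor <- integer(length(tt))
  surv <- numeric(length(tt))
  at_risk <- n
  s <- 1
  for (k in seq_along(tt)) {
    n_risk[k] <- at_risk
    n_event[k] <- sum(time == tt[k] & status == 1)
    n_censor[k] <- sum(time == tt[k] & status == 0)
    if (n_event[k] > 0) s <- s * (1 - n_event[k] / at_risk)
    surv[k] <- s
    at_risk <- at_risk - n_event[k] - n_censor[k]
  }
  out <- data.frame(time = c(0, tt), n_risk = c(n, n_risk),
                    n_event = c(0L, n_event), n_censor = c(0L, n_censor),
                    survival = c(1, surv))
  # a time-0 observation replaces the synthetic origin row
  out <- out[!duplicated(out$time, fromLast = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival at a given follow-up time
#'
#' Step-function evaluation of a [km_estimate()] curve.
#'
#' @param curve a `km_curve`.
#' @param at follow-up time(s) in days.
#' @return survival probability at `at`.
#' @export
km_survival_at <- function(curve, at) {
  vapply(at, function(a) {
    i <- which(curve$time <= a)
    if (!length(i)) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' Restart and postpartum prescribing flags for one cohort entry
#'
#' `restarted_during_pregnancy`: the event (last prescription) was observed
#' before delivery and a further issue appears after it, up to and including
#' the delivery date. `on_drug_at_183d_postpartum`: whether at least one
#' issue falls in the 91 days up to and including day 183 after delivery
#' (the same refill-gap reading of "receiving prescriptions" at a date);
#' `"lost"` when the woman's registration ends before that day.
#'
#' @param entry one row of the cohort data frame.
#' @param issues the woman's sorted issue dates for the drug.
#' @param registrations her registration rows.
#' @return list with `restarted_during_pregnancy` (logical) and
#'   `on_drug_at_183d_postpartum` (`"yes"`, `"no"`, or `"lost"`).
#' @export
detect_restart <- function(entry, issues, registrations) {
  d <- prep_issues(issues)
  restarted <- entry$event_observed &&
    entry$last_rx_date < entry$delivery_date &&
    any(d > entry$last_rx_date & d <= entry$delivery_date)
  t183 <- entry$delivery_date + DAYS_6M
  regs <- registrations[registrations$patient_id == entry$patient_id, ,
                        drop = FALSE]
  followed <- any(regs$reg_start <= t183 & t183 <= regs$reg_end)
  postpartum <- if (!followed) "lost"
    else if (any(d >= t183 - DAYS_3M & d <= t183)) "yes" else "no"
  list(restarted_during_pregnancy = restarted,
       on_drug_at_183d_postpartum = postpartum)
}

#' Co-medication flags around pregnancy start
#'
#' Flags, per psychotropic class, whether the woman had an issue of that
#' class during the 183-92 days before the anchor (the window in which
#' baseline co-medication is ascertained), and whether an antipsychotic or
#' anticonvulsant -- an alternative mood stabiliser -- was issued in the
#' three months (91 days, inclusive) after her last drug prescription.
#'
#' @param patient_rx the woman's prescription rows (all classes).
#' @param anchor pregnancy start (or index) date.
#' @param last_rx_date last-prescription date, for the alternative-
#'   medication window; `NULL` to skip that flag.
#' @return list with logicals `antidepressant`, `antipsychotic`,
#'   `anticonvulsant` and `alternative_after_stop`.
#' @export
comedication_flags <- function(patient_rx, anchor, last_rx_date = NULL) {
  a <- as_day(anchor)
  in_window <- patient_rx$issue_date >= a - DAYS_6M &
    patient_rx$issue_date <= a - 92L
  flag <- function(cl) any(in_window & patient_rx$drug_class == cl)
  alt <- FALSE
  if (!is.null(last_rx_date)) {
    l <- as_day(last_rx_date)
    alt <- any(patient_rx$drug_class %in% c("antipsychotic", "anticonvulsant") &
                 patient_rx$issue_date > l &
                 patient_rx$issue_date <= l + DAYS_3M)
  }
  list(antidepressant = flag("antidepressant"),
       antipsychotic = flag("antipsychotic"),
       anticonvulsant = flag("anticonvulsant"),
       alternative_after_stop = alt)
}

#' Estimate parity
#'
#' Recorded parity from the medical record takes precedence; otherwise
#' parity is estimated as the larger of the number of previous
#' delivery-outcome pregnancies and the number of older children in the
#' woman's household.
#'
#' @param recorded_parity recorded value or `NA`.
#' @param n_prior_deliveries count of prior pregnancies ending in delivery.
#' @param n_older_children count of household children born before the
#'   index pregnancy.
#' @return non-negative integer parity estimate.
#' @export
estimate_parity <- function(recorded_parity, n_prior_deliveries = 0,
                            n_older_children = 0) {
  if (!is.na(recorded_parity)) return(as.integer(recorded_parity))
  max(as.integer(n_prior_deliveries), as.integer(n_older_children))
}

# household children born before the index pregnancy start (calendar-year
# arithmetic, excluding the mother herself)
count_older_household_children <- function(patients, mother_id, preg_start) {
  hh <- patients$household_id[patients$patient_id == mother_id]
  if (!length(hh) || is.na(hh[1])) return(0L)
  mom_by <- patients$birth_year[patients$patient_id == mother_id][1]
  kids <- patients[!is.na(patients$household_id) &
                     patients$household_id == hh[1] &
                     patients$patient_id != mother_id, , drop = FALSE]
  sum(kids$birth_year > mom_by & kids$birth_year < year_of(preg_start))
}

#' Logit-transform binomial confidence interval for a proportion
#'
#' Point estimate 100 k / n with a 95 per cent interval computed on the
#' log-odds scale: L = ln(p / (1 - p)), standard error
#' sqrt(p (1 - p) / (n - 1)) / (p (1 - p)), bounds the inverse logit of
#' L +/- t(0.975, df) * se, expressed as percentages. The Student-t quantile
#' uses `df` degrees of freedom, conventionally the total cohort size minus
#' one when several subgroup proportions share a table. The interval is
#' undefined (rendered "-") when k = 0 or k = n.
#'
#' @param k numerator count.
#' @param n group size (>= 2).
#' @param df degrees of freedom for the t quantile (default `n - 1`).
#' @param conf confidence level (default 0.95).
#' @return object of class `proportion_ci`: list with `k`, `n`, `df`,
#'   `point_pct`, `lower_pct`, `upper_pct` (percentages rounded half-up to
#'   one decimal; raw values in `point_raw`, `lower_raw`, `upper_raw`) and
#'   `defined`.
#' @examples
#' proportion_ci(5, 35, df = 51)  # 14.3% (5.9, 30.8)
#' @export
proportion_ci <- function(k, n, df = n - 1, conf = 0.95) {
  check_that(n >= 2, "proportion_ci: n must be >= 2")
  check_that(k >= 0 && k <= n, "proportion_ci: k must be in [0, n]")
  check_that(df >= 1, "proportion_ci: df must be >= 1")
  p <- k / n
  defined <- k > 0 && k < n
  lower <- upper <- NA_real_
  if (defined) {
    L <- log(p / (1 - p))
    se <- sqrt(p * (1 - p) / (n - 1)) / (p * (1 - p))
    q <- stats::qt(1 - (1 - conf) / 2, df)
    lower <- 100 * stats::plogis(L - q * se)
    upper <- 100 * stats::plogis(L + q * se)
  }
  structure(list(k = as.integer(k), n = as.integer(n), df = df,
                 point_pct = round_half_up(100 * p, 1),
                 lower_pct = round_half_up(lower, 1),
                 upper_pct = round_half_up(upper, 1),
                 point_raw = 100 * p, lower_raw = lower, upper_raw = upper,
                 defined = defined),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  ci <- if (x$defined) sprintf("(%.1f, %.1f)", x$lower_pct, x$upper_pct)
        else "-"
  cat(sprintf("%d/%d = %.1f%% %s [logit-t, df = %g]\n",
              x$k, x$n, x$point_pct, ci, x$df))
  invisible(x)
}

# prior continuous time on drug, measured from episode start up to the 91st
# day before the anchor; categories <6 months (<183 d), 6-12 months
# (183-365 d), >12 months (>365 d)
prior_time_category <- function(episode_first_rx, anchor) {
  days <- as.integer((as_day(anchor) - DAYS_3M) - as_day(episode_first_rx))
  ifelse(days < DAYS_6M, "<6 months",
         ifelse(days <= DAYS_1Y, "6-12 months", ">12 months"))
}

# age bands used in the characteristics table (coarser than matching bands)
characteristics_age_band <- function(age) {
  cut(age, breaks = c(-Inf, 24, 29, 34, Inf),
      labels = c("<25", "25-29", "30-34", "35+"))
}

#' Characteristics of women who continue versus stop
#'
#' Compares, between the women who continued prescriptions beyond six weeks
#' of gestation and those who stopped before, the distribution of age band
#' at pregnancy start, prior continuous time on the drug (episode start to
#' 91 days before pregnancy; <6, 6-12, >12 months), estimated parity (0, 1,
#' 2, 3+), and co-prescribing of antidepressants, antipsychotics and
#' anticonvulsants in the 183-92 days before pregnancy. Each cell carries a
#' logit-transform confidence interval whose t quantile uses the total
#' cohort size minus one as degrees of freedom.
#'
#' @param cohort a `discontinuation_cohort`.
#' @param tables the validated `ehr_tables` the cohort came from.
#' @param drug drug class (default `"lithium"`).
#' @return long data frame: `variable`, `level`, `group`, `k`, `n`, `pct`,
#'   `lower`, `upper`, `ci_defined`.
#' @export
characteristics_table <- function(cohort, tables, drug = "lithium") {
  pat <- tables$patients
  rx <- tables$prescriptions
  pr <- tables$pregnancies
  n_tot <- nrow(cohort)
  groups <- list(stopped = which(cohort$continuation_class == "stopped_before_6w"),
                 continued = which(cohort$continuation_class == "continued_beyond_6w"))

  # per-woman covariates
  birth <- pat$birth_year[match(cohort$patient_id, pat$patient_id)]
  ageband <- as.character(characteristics_age_band(
    year_of(cohort$start_date) - birth))
  drug_rx <- rx[rx$drug_class == drug, , drop = FALSE]
  prior <- parity <- character(n_tot)
  comed <- matrix(FALSE, n_tot, 3,
                  dimnames = list(NULL, c("antidepressant", "antipsychotic",
                                          "anticonvulsant")))
  for (i in seq_len(n_tot)) {
    pid <- cohort$patient_id[i]
    issues <- sort(unique(drug_rx$issue_date[drug_rx$patient_id == pid]))
    eps <- build_episodes(issues)
    cover <- which(eps$first_rx_date <= cohort$start_date[i] - 1L &
                     eps$last_rx_date >= cohort$start_date[i] - DAYS_3M)
    first_rx <- eps$first_rx_date[max(cover)]
    prior[i] <- prior_time_category(first_rx, cohort$start_date[i])

    rec <- pat$recorded_parity[match(pid, pat$patient_id)]
    priors <- sum(pr$patient_id == pid & pr$outcome == "delivery" &
                    pr$delivery_date < cohort$start_date[i])
    kids <- count_older_household_children(pat, pid, cohort$start_date[i])
    est <- estimate_parity(rec, priors, kids)
    parity[i] <- if (est >= 3) "3+" else as.character(est)

    fl <- comedication_flags(rx[rx$patient_id == pid, , drop = FALSE],
                             cohort$start_date[i])
    comed[i, ] <- c(fl$antidepressant, fl$antipsychotic, fl$anticonvulsant)
  }

  cell <- function(variable, level, member) {
    rows <- lapply(names(groups), function(g) {
      idx <- groups[[g]]
      k <- sum(member[idx])
      n <- length(idx)
      if (n < 2)  # no interval is estimable for an empty or singleton group
        return(data.frame(variable = variable, level = level, group = g,
                          k = k, n = n,
                          pct = if (n) round_half_up(100 * k / n, 1)
                                else NA_real_,
                          lower = NA_real_, upper = NA_real_,
                          ci_defined = FALSE))
      ci <- proportion_ci(k, n, df = n_tot - 1)
      data.frame(variable = variable, level = level, group = g, k = ci$k,
                 n = ci$n, pct = ci$point_pct, lower = ci$lower_pct,
                 upper = ci$upper_pct, ci_defined = ci$defined)
    })
    do.call(rbind, rows)
  }

  out <- list()
  for (lv in c("<25", "25-29", "30-34", "35+"))
    out[[length(out) + 1L]] <- cell("age_band", lv, ageband == lv)
  for (lv in c("<6 months", "6-12 months", ">12 months"))
    out[[length(out) + 1L]] <- cell("prior_time_on_drug", lv, prior == lv)
  for (lv in c("0", "1", "2", "3+"))
    out[[length(out) + 1L]] <- cell("estimated_parity", lv, parity == lv)
  for (cl in colnames(comed))
    out[[length(out) + 1L]] <- cell("comedication", cl, comed[, cl])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
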