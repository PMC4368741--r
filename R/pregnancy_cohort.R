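# Stage 1: eligible pregnancies and the prevalence of prescribing before and
# during pregnancy by calendar period.

#' Assess pregnancy eligibility for the prevalence cohort
#'
#' A pregnancy enters the cohort when (i) its outcome is a delivery
#' (miscarriages and terminations are excluded because their start dates
#' cannot be estimated reliably), (ii) it starts inside the study window, and
#' (iii) one registration period of the woman covers the pregnancy and the
#' six months (183 days) beforehand in full -- the "permanently registered"
#' requirement; a transfer gap disqualifies.
#'
#' @param pregnancies pregnancy table (`patient_id`, `start_date`,
#'   `delivery_date`, `outcome`, ...).
#' @param registrations registration table (`patient_id`, `reg_start`,
#'   `reg_end`).
#' @param study_start,study_end study window `Date`s.
#' @return the pregnancy table with columns `eligible` (logical) and
#'   `exclusion_reason` (`"none"`, `"outcome_loss"`, `"outside_window"`,
#'   `"registration_gap"`) appended. `eligible` is TRUE iff the reason is
#'   `"none"`.
#' @export
assess_eligibility <- function(pregnancies, registrations,
                               study_start = as.Date("1995-01-01"),
                               study_end = as.Date("2012-12-31")) {
  pr <- pregnancies
  n <- nrow(pr)
  reason <- rep("none", n)
  reg_by <- split(registrations, registrations$patient_id)
  for (i in seq_len(n)) {
    if (pr$outcome[i] != "delivery") { reason[i] <- "outcome_loss"; next }
    if (pr$start_date[i] < study_start || pr$start_date[i] > study_end) {
      reason[i] <- "outside_window"; next
    }
    r <- reg_by[[pr$patient_id[i]]]
    need_lo <- pr$start_date[i] - DAYS_6M
    need_hi <- pr$delivery_date[i]
    if (is.null(r) || !any(r$reg_start <= need_lo & need_hi <= r$reg_end))
      reason[i] <- "registration_gap"
  }
  pr$eligible <- reason == "none"
  pr$exclusion_reason <- reason
  pr
}

#' Flag prescribing around each pregnancy
#'
#' For each pregnancy, flags whether the drug was issued in the six months
#' before pregnancy (days -183 to -1 relative to the start), at any time
#' during pregnancy (day 0 to delivery), and during pregnancy after the
#' first six weeks (gestational day >= 43 to delivery, when the woman is
#' likely to be aware of the pregnancy).
#'
#' @param pregnancies pregnancy table rows to flag.
#' @param prescriptions prescription table; only rows with
#'   `drug_class == drug` are used.
#' @param drug drug class of interest (default `"lithium"`).
#' @return `pregnancies` with logical columns `rx_before6m`, `rx_during_any`,
#'   `rx_during_after6w` appended.
#' @export
classify_prescribing <- function(pregnancies, prescriptions,
                                 drug = "lithium") {
  rx <- prescriptions[prescriptions$drug_class == drug, , drop = FALSE]
  rx_by <- split(as.integer(rx$issue_date), rx$patient_id)
  n <- nrow(pregnancies)
  before <- during <- after6w <- logical(n)
  s <- as.integer(pregnancies$start_date)
  dl <- as.integer(pregnancies$delivery_date)
  for (i in seq_len(n)) {
    d <- rx_by[[pregnancies$patient_id[i]]]
    if (is.null(d)) next
    before[i]  <- any(d >= s[i] - DAYS_6M & d <= s[i] - 1L)
    during[i]  <- any(d >= s[i] & d <= dl[i])
    after6w[i] <- any(d >= s[i] + DAYS_6W + 1L & d <= dl[i])
  }
  pregnancies$rx_before6m <- before
  pregnancies$rx_during_any <- during
  pregnancies$rx_during_after6w <- after6w
  pregnancies
}

#' Prevalence of prescribing by calendar period
#'
#' Tabulates, per block of `period_years` calendar years (keyed on the year
#' of pregnancy start) and over all years, the number and percentage of
#' pregnancies with the drug issued in the 6 months before pregnancy, at any
#' time during pregnancy, and during pregnancy after the first 6 weeks.
#' Percentages are 100 * n / total rounded half-up to three decimals, the
#' precision at which prevalences of this magnitude are reported.
#'
#' @param flagged output of [classify_prescribing()] restricted to eligible
#'   pregnancies.
#' @param period_years width of each calendar period (default 3).
#' @param study_start,study_end study window `Date`s; periods tile the years
#'   from the first to the last.
#' @return data frame with one row per period plus an `"All years"` row:
#'   `period`, `n_before`, `pct_before`, `n_any`, `pct_any`, `n_after6w`,
#'   `pct_after6w`, `total`.
#' @export
prevalence_table <- function(flagged, period_years = 3,
                             study_start = as.Date("1995-01-01"),
                             study_end = as.Date("2012-12-31")) {
  check_that(nrow(flagged) > 0, "prevalence_table: empty cohort")
  y0 <- year_of(study_start)
  y1 <- year_of(study_end)
  starts <- seq(y0, y1, by = period_years)
  ends <- pmin(starts + period_years - 1L, y1)
  yr <- year_of(flagged$start_date)
  idx <- findInterval(yr, starts)
  check_that(all(idx >= 1 & yr <= y1),
             "prevalence_table: pregnancy start outside study years")
  one_row <- function(label, rows) {
    total <- length(rows)
    nb <- sum(flagged$rx_before6m[rows])
    na_ <- sum(flagged$rx_during_any[rows])
    n6 <- sum(flagged$rx_during_after6w[rows])
    data.frame(period = label,
               n_before = nb, pct_before = pct_of(nb, total),
               n_any = na_, pct_any = pct_of(na_, total),
               n_after6w = n6, pct_after6w = pct_of(n6, total),
               total = total)
  }
  rows <- lapply(seq_along(starts), function(k) {
    lab <- if (starts[k] == ends[k]) as.character(starts[k])
           else sprintf("%d-%d", starts[k], ends[k])
    one_row(lab, which(idx == k))
  })
  out <- do.call(rbind, c(rows, list(one_row("All years",
                                             seq_len(nrow(flagged))))))
  rownames(out) <- NULL
  out
}
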