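test_that("cohort entry requires the continuity predicate at pregnancy start", {
  tb <- one_woman_tables(c(-150, -60))
  e <- assess_eligibility(tb$pregnancies, tb$registrations)
  coh <- assemble_cohort(e[e$eligible, ], tb$prescriptions)
  expect_identical(nrow(coh), 1L)
  expect_identical(coh$followup_start, D0 - 91)
  expect_identical(coh$censor_date, D0 + 220)   # delivery at +280 is later
  expect_identical(coh$last_rx_date, D0 - 60)
  expect_true(coh$event_observed)
  expect_identical(coh$continuation_class, "stopped_before_6w")

  # nothing in the 91-1 window -> excluded
  tb2 <- one_woman_tables(c(-150, -100))
  e2 <- assess_eligibility(tb2$pregnancies, tb2$registrations)
  expect_identical(nrow(assemble_cohort(e2[e2$eligible, ],
                                        tb2$prescriptions)), 0L)
})

test_that("premature delivery censors before gestational day 220", {
  tb <- one_woman_tables(c(-150, -60, seq(0, 300, by = 28)), duration = 200L)
  e <- assess_eligibility(tb$pregnancies, tb$registrations)
  coh <- assemble_cohort(e[e$eligible, ], tb$prescriptions)
  expect_identical(coh$censor_date, D0 + 200)
  expect_false(coh$event_observed)           # still prescribing at censoring
  expect_identical(coh$time, 291L)           # 91 + 200
  expect_identical(coh$status, 0L)
})

test_that("a woman with two eligible pregnancies contributes exactly one, reproducibly", {
  tb <- one_woman_tables(c(seq(-2000, 2600, by = 28)))
  p2 <- tb$pregnancies
  p2$start_date <- D0 + 1200
  p2$delivery_date <- p2$start_date + 280
  tb$pregnancies <- rbind(tb$pregnancies, p2)
  e <- assess_eligibility(tb$pregnancies, tb$registrations,
                          study_start = D0 - 3000, study_end = D0 + 3000)
  expect_true(all(e$eligible))
  set.seed(20); a <- assemble_cohort(e, tb$prescriptions)
  set.seed(20); b <- assemble_cohort(e, tb$prescriptions)
  expect_identical(nrow(a), 1L)
  expect_identical(a, b)
})

test_that("continuation classification switches at gestational day 43", {
  expect_identical(classify_continuation(D0 + 42, D0), "stopped_before_6w")
  expect_identical(classify_continuation(D0 + 43, D0), "continued_beyond_6w")
  expect_identical(classify_continuation(D0 - 10, D0), "stopped_before_6w")
})

test_that("product-limit estimate matches hand calculations", {
  km <- km_estimate(c(10, 20, 30, 40), c(1, 1, 1, 1))
  expect_equal(km$survival[km$time %in% c(10, 20, 30, 40)],
               c(0.75, 0.5, 0.25, 0))

  km2 <- km_estimate(rep(311, 5), rep(0, 5))
  expect_true(all(km2$survival == 1))

  # events at 50 and 120, censorings at 100, 200, 250:
  # S(50) = 4/5 = 0.8; at 120 the risk set is 3 -> 0.8 * 2/3 = 0.5333
  km3 <- km_estimate(c(50, 120, 100, 200, 250), c(1, 1, 0, 0, 0))
  expect_equal(km3$survival[km3$time == 50], 0.8)
  expect_equal(km3$survival[km3$time == 120], 0.8 * 2 / 3, tolerance = 1e-12)
  expect_equal(km_survival_at(km3, 119), 0.8)
  expect_equal(km_survival_at(km3, 0), 1)

  # tied event and censoring: the event is ranked first, so the censored
  # subject is still in the risk set at that time
  km4 <- km_estimate(c(30, 30, 60), c(1, 0, 1))
  expect_equal(km4$survival[km4$time == 30], 2 / 3, tolerance = 1e-12)
  expect_equal(km4$survival[km4$time == 60], 2 / 3 * 0, tolerance = 1e-12)
})

test_that("product-limit curve matches survival::survfit on random instances", {
  skip_if_not_installed("survival")
  set.seed(801)
  for (rep in 1:200) {
    n <- sample(2:15, 1)
    time <- sample(1:40, n, replace = TRUE)
    status <- stats::rbinom(n, 1, 0.6)
    km <- km_estimate(time, status)
    fit <- survival::survfit(survival::Surv(time, status) ~ 1)
    at <- sort(unique(time))
    expect_equal(km_survival_at(km, at),
                 summary(fit, times = at)$surv, tolerance = 1e-12)
  }
  # curve invariants
  km <- km_estimate(sample(1:100, 50, replace = TRUE),
                    stats::rbinom(50, 1, 0.5))
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(diff(km$n_risk) <= 0))
  expect_identical(km$survival[1], 1)
})

test_that("restart detection distinguishes during-pregnancy, postpartum and lost", {
  entry <- function(issues, duration = 280L, reg_end = D0 + 2000) {
    tb <- one_woman_tables(issues, duration = duration, reg_end = reg_end)
    e <- assess_eligibility(tb$pregnancies, tb$registrations)
    coh <- assemble_cohort(e[e$eligible, ], tb$prescriptions)
    list(entry = coh[1, , drop = FALSE], tb = tb)
  }
  # stop at day 10, restart at day 150, delivery day 280
  x <- entry(c(-150, -60, 10, 150))
  fl <- detect_restart(x$entry, x$tb$prescriptions$issue_date,
                       x$tb$registrations)
  expect_true(fl$restarted_during_pregnancy)

  # issue at delivery + 120 is within the 91-day lookback from day 183
  x2 <- entry(c(-150, -60, 280 + 120))
  fl2 <- detect_restart(x2$entry, x2$tb$prescriptions$issue_date,
                        x2$tb$registrations)
  expect_false(fl2$restarted_during_pregnancy)
  expect_identical(fl2$on_drug_at_183d_postpartum, "yes")

  # issue at delivery + 91 is outside the lookback from day 183 (92 days)
  x3 <- entry(c(-150, -60, 280 + 91))
  fl3 <- detect_restart(x3$entry, x3$tb$prescriptions$issue_date,
                        x3$tb$registrations)
  expect_identical(fl3$on_drug_at_183d_postpartum, "no")

  # registration ends 100 days after delivery -> lost to follow-up
  x4 <- entry(c(-150, -60), reg_end = D0 + 280 + 100)
  fl4 <- detect_restart(x4$entry, x4$tb$prescriptions$issue_date,
                        x4$tb$registrations)
  expect_identical(fl4$on_drug_at_183d_postpartum, "lost")
})

test_that("co-medication windows are the 183-92 days before the anchor", {
  rx <- function(off, cl) data.frame(patient_id = "W1",
                                     issue_date = D0 + off, drug_class = cl)
  fl <- comedication_flags(rx(-100, "antidepressant"), D0)
  expect_true(fl$antidepressant)
  expect_false(fl$antipsychotic)
  expect_false(comedication_flags(rx(-50, "antidepressant"), D0)$antidepressant)
  expect_false(comedication_flags(rx(-91, "antidepressant"), D0)$antidepressant)
  expect_true(comedication_flags(rx(-92, "antipsychotic"), D0)$antipsychotic)
  expect_true(comedication_flags(rx(-183, "anticonvulsant"), D0)$anticonvulsant)

  # alternative mood stabiliser in the 91 days after stopping, inclusive
  last <- D0 + 10
  expect_true(comedication_flags(rx(10 + 91, "antipsychotic"), D0,
                                 last)$alternative_after_stop)
  expect_false(comedication_flags(rx(10 + 92, "antipsychotic"), D0,
                                  last)$alternative_after_stop)
  expect_false(comedication_flags(rx(10 + 30, "antidepressant"), D0,
                                  last)$alternative_after_stop)
})

test_that("parity estimation prefers the record, else max(deliveries, household)", {
  expect_identical(estimate_parity(2, 1, 5), 2L)
  expect_identical(estimate_parity(NA, 1, 2), 2L)
  expect_identical(estimate_parity(NA, 3, 1), 3L)
  expect_identical(estimate_parity(NA, 0, 0), 0L)
})

test_that("logit-t confidence intervals reproduce published-style cells", {
  ci <- proportion_ci(5, 35, df = 51)
  expect_equal(ci$point_pct, 14.3)
  expect_equal(ci$lower_pct, 5.9)
  expect_equal(ci$upper_pct, 30.8)

  ci0 <- proportion_ci(0, 17, df = 51)
  expect_equal(ci0$point_pct, 0)
  expect_false(ci0$defined)
  expect_false(proportion_ci(17, 17, df = 51)$defined)

  # bounds for k/n = 1/2 are equidistant from 50 on the logit scale
  ci5 <- proportion_ci(5, 10, df = 51)
  expect_equal(ci5$point_pct, 50)
  expect_equal(stats::qlogis(ci5$upper_raw / 100),
               -stats::qlogis(ci5$lower_raw / 100), tolerance = 1e-10)

  expect_error(proportion_ci(1, 1), "n must be")
  expect_error(proportion_ci(5, 4), "k must be")
})

test_that("characteristics table has the published layout and consistent counts", {
  tb <- simulate_ehr(sim_config(n_women = 800, pregnancy_prob = 0.4,
                                seed = 809))
  e <- assess_eligibility(tb$pregnancies, tb$registrations)
  set.seed(810)
  coh <- assemble_cohort(e[e$eligible, ], tb$prescriptions)
  ch <- characteristics_table(coh, tb)
  expect_setequal(unique(ch$variable),
                  c("age_band", "prior_time_on_drug", "estimated_parity",
                    "comedication"))
  expect_setequal(unique(ch$group), c("stopped", "continued"))
  n_stop <- sum(coh$continuation_class == "stopped_before_6w")
  n_cont <- nrow(coh) - n_stop
  # each categorical variable partitions each group
  for (v in c("age_band", "prior_time_on_drug", "estimated_parity")) {
    expect_identical(sum(ch$k[ch$variable == v & ch$group == "stopped"]),
                     n_stop)
    expect_identical(sum(ch$k[ch$variable == v & ch$group == "continued"]),
                     n_cont)
  }
  # CIs undefined exactly when k = 0 or k = n
  deg <- ch$k == 0 | ch$k == ch$n
  expect_identical(ch$ci_defined, !deg)
})

test_that("prior-time category boundary: an episode starting 250 days before start", {
  # 250 - 91 = 159 days of prior continuous time -> under 6 months
  expect_identical(preglith:::prior_time_category(D0 - 250, D0), "<6 months")
  expect_identical(preglith:::prior_time_category(D0 - 91 - 183, D0),
                   "6-12 months")
  expect_identical(preglith:::prior_time_category(D0 - 91 - 366, D0),
                   ">12 months")
})
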