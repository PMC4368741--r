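regs1 <- function(from, to) data.frame(patient_id = "W1",
                                       reg_start = from, reg_end = to)
S0 <- as.Date("1995-01-01")
S1 <- as.Date("2012-12-31")

test_that("non-pregnant periods apply the 1-year-after / 2-years-before rule", {
  # no pregnancies, full registration, age always in range -> whole window
  p <- nonpregnant_periods(1970, data.frame()[0, ], regs1(S0 - 100, S1 + 100))
  expect_identical(p$period_start, S0)
  expect_identical(p$period_end, S1)

  # one pregnancy: exclusion zone [S - 730, D + 364]
  preg <- data.frame(patient_id = "W1", start_date = as.Date("2004-03-01"),
                     delivery_date = as.Date("2004-12-06"))
  p2 <- nonpregnant_periods(1970, preg, regs1(S0, S1))
  expect_identical(nrow(p2), 2L)
  expect_identical(p2$period_end[1], preg$start_date - 731)
  expect_identical(p2$period_start[2], preg$delivery_date + 365)

  # back-to-back pregnancies 18 months apart leave no eligible days between
  preg2 <- data.frame(patient_id = "W1",
                      start_date = as.Date(c("2004-03-01", "2006-03-01")),
                      delivery_date = as.Date(c("2004-12-06", "2006-12-06")))
  p3 <- nonpregnant_periods(1970, preg2, regs1(S0, S1))
  between <- p3$period_start > preg2$delivery_date[1] &
    p3$period_end < preg2$start_date[2]
  expect_false(any(between))

  # age bounds: a woman born 1990 is 14 before 2004
  p4 <- nonpregnant_periods(1990, data.frame()[0, ], regs1(S0, S1))
  expect_identical(p4$period_start, as.Date("2004-01-01"))
})

test_that("index dates are uniform over the union of eligible days", {
  one_day <- data.frame(period_start = as.Date("2000-05-05"),
                        period_end = as.Date("2000-05-05"))
  set.seed(1)
  expect_identical(draw_index_date(one_day), as.Date("2000-05-05"))
  expect_identical(nrow(preglith:::empty_periods()), 0L)
  expect_true(is.na(draw_index_date(preglith:::empty_periods())))

  periods <- data.frame(period_start = as.Date(c("2000-01-01", "2001-01-01")),
                        period_end = as.Date(c("2000-01-10", "2001-01-30")))
  set.seed(42)
  draws <- replicate(10000, draw_index_date(periods))
  in_second <- draws >= as.integer(as.Date("2001-01-01"))
  # second period holds 30 of 40 days
  expect_gt(stats::chisq.test(table(in_second), p = c(0.25, 0.75))$p.value,
            1e-3)
  # uniform within the union, day by day
  expect_gt(stats::chisq.test(table(factor(draws,
                                           levels = unique(sort(draws)))))$p.value,
            1e-4)
  set.seed(7); a <- draw_index_date(periods)
  set.seed(7); b <- draw_index_date(periods)
  expect_identical(a, b)
})

test_that("age bands fold the 14s and 50s into the edge bands", {
  expect_identical(age_band(c(14, 15, 19, 20, 37, 45, 49, 50)),
                   c("15-19", "15-19", "15-19", "20-24", "35-39",
                     "45-49", "45-49", "45-49"))
})

test_that("control sampling matches bands, is 2:1 and without replacement", {
  cases <- data.frame(case_id = c("A", "B"), band = c("25-29", "25-29"))
  cands <- data.frame(patient_id = paste0("N", 1:6),
                      index_date = as.Date("2001-01-01") + 1:6,
                      band = c(rep("25-29", 5), "30-34"))
  set.seed(11)
  ctl <- sample_controls(cases, cands)
  expect_identical(nrow(ctl), 4L)
  expect_identical(ctl$band, rep("25-29", 4))
  expect_false(any(duplicated(ctl$patient_id)))
  expect_identical(ctl$matched_case_id, c("A", "A", "B", "B"))

  # exactly enough candidates -> all selected
  set.seed(12)
  ctl2 <- sample_controls(cases[1, ], cands[1:2, ])
  expect_setequal(ctl2$patient_id, c("N1", "N2"))

  expect_error(sample_controls(cases, cands[1:3, ]),
               "shortfall in age band 25-29")
})

test_that("sampled comparators satisfy the same continuity predicate as cases", {
  tb <- simulate_ehr(sim_config(n_women = 400, seed = 701))
  set.seed(702)
  cand <- comparator_candidates(tb, character())
  expect_gt(nrow(cand), 0)
  rx <- tb$prescriptions[tb$prescriptions$drug_class == "lithium", ]
  for (i in seq_len(nrow(cand))) {
    d <- sort(rx$issue_date[rx$patient_id == cand$patient_id[i]])
    expect_true(is_continuous_at(d, cand$index_date[i]))
  }
  # bands recorded for candidates match their age at index
  by <- tb$patients$birth_year[match(cand$patient_id, tb$patients$patient_id)]
  expect_identical(cand$band,
                   age_band(as.integer(format(cand$index_date, "%Y")) - by))
})
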