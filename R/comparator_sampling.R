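# Stage 3: non-pregnant periods, simulated index dates, and age-band-matched
# sampling of non-pregnant continuously-prescribed comparators.

# intersect two closed integer intervals; NULL when empty
int_intersect <- function(a_lo, a_hi, b_lo, b_hi) {
  lo <- max(a_lo, b_lo); hi <- min(a_hi, b_hi)
  if (lo > hi) NULL else c(lo, hi)
}

# subtract closed interval [c_lo, c_hi] from a list of closed intervals
int_subtract <- function(ints, c_lo, c_hi) {
  out <- list()
  for (iv in ints) {
    if (c_hi < iv[1] || c_lo > iv[2]) { out <- c(out, list(iv)); next }
    if (iv[1] < c_lo) out <- c(out, list(c(iv[1], c_lo - 1L)))
    if (iv[2] > c_hi) out <- c(out, list(c(c_hi + 1L, iv[2])))
  }
  out
}

#' Non-pregnant periods eligible for index-date simulation
#'
#' Returns the stretches of time in which a woman counts as "non-pregnant"
#' for comparator purposes: inside the study window, inside one of her
#' registration periods, aged 14-50 (age = calendar year minus birth year),
#' at least 1 year (365 days) after the end of any previous pregnancy and at
#' least 2 years (730 days) before the start of any subsequent one. Around
#' each pregnancy from start S to end D the excluded zone is therefore
#' [S - 730, D + 364]. Women with no pregnancies contribute their full
#' eligible registration overlap.
#'
#' @param birth_year the woman's birth year.
#' @param pregnancies her pregnancy rows (may have zero rows); all outcomes
#'   count as pregnancies here.
#' @param registrations her registration rows.
#' @param study_start,study_end study window `Date`s.
#' @return data frame `period_start`, `period_end` (`Date`), possibly empty.
#' @export
nonpregnant_periods <- function(birth_year, pregnancies, registrations,
                                study_start = as.Date("1995-01-01"),
                                study_end = as.Date("2012-12-31")) {
  age_lo <- as.integer(as.Date(sprintf("%d-01-01", birth_year + 14)))
  age_hi <- as.integer(as.Date(sprintf("%d-12-31", birth_year + 50)))
  base <- int_intersect(as.integer(study_start), as.integer(study_end),
                        age_lo, age_hi)
  if (is.null(base)) return(empty_periods())
  ints <- list()
  for (i in seq_len(nrow(registrations))) {
    iv <- int_intersect(base[1], base[2],
                        as.integer(registrations$reg_start[i]),
                        as.integer(registrations$reg_end[i]))
    if (!is.null(iv)) ints <- c(ints, list(iv))
  }
  for (i in seq_len(nrow(pregnancies)))
    ints <- int_subtract(ints,
                         as.integer(pregnancies$start_date[i]) - DAYS_2Y,
                         as.integer(pregnancies$delivery_date[i]) + DAYS_1Y - 1L)
  if (!length(ints)) return(empty_periods())
  m <- do.call(rbind, ints)
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(period_start = as.Date(m[, 1], origin = "1970-01-01"),
             period_end = as.Date(m[, 2], origin = "1970-01-01"))
}

empty_periods <- function() {
  data.frame(period_start = as.Date(character()),
             period_end = as.Date(character()))
}

#' Draw a uniform random index date within non-pregnant periods
#'
#' Samples one day uniformly over the union of the supplied periods, to
#' stand in for a pregnancy start date in the comparator group. Uses the
#' current RNG state, so results are reproducible under [set.seed()].
#'
#' @param periods data frame from [nonpregnant_periods()].
#' @return a `Date`, or `NA` (with class `Date`) when the union is empty.
#' @export
draw_index_date <- function(periods) {
  if (!nrow(periods)) return(as.Date(NA))
  lens <- as.integer(periods$period_end - periods$period_start) + 1L
  total <- sum(lens)
  u <- sample.int(total, 1L)
  k <- findInterval(u - 1L, cumsum(c(0L, lens)), rightmost.closed = FALSE)
  periods$period_start[k] + (u - 1L - c(0L, cumsum(lens))[k])
}

#' Five-year age band label
#'
#' Bands are 15-19, 20-24, ..., 45-49; age 14 folds into the lowest band and
#' age 50 into the highest.
#'
#' @param age integer age(s) in years (calendar-year arithmetic).
#' @param width band width in years (default 5).
#' @return character vector of band labels.
#' @export
age_band <- function(age, width = 5) {
  a <- pmin(pmax(as.integer(age), 15L), 49L)
  lo <- 15L + width * ((a - 15L) %/% width)
  sprintf("%d-%d", lo, lo + width - 1L)
}

#' Sample age-band-matched non-pregnant comparators
#'
#' Draws `ratio` comparator women per case, sampled uniformly without
#' replacement among candidate women in the case's five-year age band. A
#' woman serves as a comparator at most once across the whole draw. Uses the
#' current RNG state.
#'
#' @param cases data frame with `case_id` and `band` (from [age_band()]).
#' @param candidates data frame with `patient_id`, `index_date`, `band`;
#'   every candidate must already satisfy the continuous-prescribing
#'   predicate at her own index date.
#' @param ratio comparators per case (default 2).
#' @return data frame `patient_id`, `index_date`, `band`, `matched_case_id`.
#'   Errors with an explicit shortfall message naming the band when a
#'   stratum runs out of candidates.
#' @export
sample_controls <- function(cases, candidates, ratio = 2) {
  pool <- candidates
  out <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    b <- cases$band[i]
    avail <- which(pool$band == b)
    if (length(avail) < ratio)
      stop(sprintf(
        "comparator shortfall in age band %s: need %d, have %d candidates",
        b, ratio, length(avail)), call. = FALSE)
    pick <- avail[sample.int(length(avail), ratio)]
    out[[i]] <- data.frame(patient_id = pool$patient_id[pick],
                           index_date = pool$index_date[pick],
                           band = b,
                           matched_case_id = cases$case_id[i])
    pool <- pool[-pick, , drop = FALSE]
  }
  res <- do.call(rbind, c(out, list(data.frame(
    patient_id = character(), index_date = as.Date(character()),
    band = character(), matched_case_id = character()))))
  rownames(res) <- NULL
  res
}

#' Build the comparator candidate pool from EHR tables
#'
#' For every woman who is not a case: derive her non-pregnant periods, draw
#' one index date uniformly within them, and keep her as a candidate only if
#' she was continuously prescribed the drug at that index date (the same
#' predicate cases must satisfy at pregnancy start). Women whose drawn date
#' fails the predicate are discarded, not redrawn, to avoid biasing the pool
#' toward long prescribing histories.
#'
#' @param tables validated `ehr_tables`.
#' @param exclude_ids patient ids of cases, excluded from the pool.
#' @param drug drug class (default `"lithium"`).
#' @param study_start,study_end study window `Date`s.
#' @return data frame `patient_id`, `index_date`, `band`.
#' @export
comparator_candidates <- function(tables, exclude_ids = character(),
                                  drug = "lithium",
                                  study_start = as.Date("1995-01-01"),
                                  study_end = as.Date("2012-12-31")) {
  pat <- tables$patients
  pat <- pat[!(pat$patient_id %in% exclude_ids), , drop = FALSE]
  rx <- tables$prescriptions
  rx <- rx[rx$drug_class == drug, , drop = FALSE]
  rx_by <- split(rx$issue_date, rx$patient_id)
  reg_by <- split(tables$registrations, tables$registrations$patient_id)
  pr_by <- split(tables$pregnancies, tables$pregnancies$patient_id)
  no_preg <- tables$pregnancies[0, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(pat))) {
    pid <- pat$patient_id[i]
    issues <- rx_by[[pid]]
    if (is.null(issues)) next
    regs <- reg_by[[pid]]
    if (is.null(regs)) next
    pregs <- pr_by[[pid]]
    if (is.null(pregs)) pregs <- no_preg
    per <- nonpregnant_periods(pat$birth_year[i], pregs, regs,
                               study_start, study_end)
    idx <- draw_index_date(per)
    if (is.na(idx)) next
    if (!is_continuous_at(sort(issues), idx)) next
    out[[length(out) + 1L]] <- data.frame(
      patient_id = pid, index_date = idx,
      band = age_band(year_of(idx) - pat$birth_year[i]))
  }
  res <- do.call(rbind, c(out, list(data.frame(
    patient_id = character(), index_date = as.Date(character()),
    band = character()))))
  rownames(res) <- NULL
  res
}
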