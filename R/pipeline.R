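# End-to-end orchestration: simulate/load -> pregnancy cohort & prevalence
# -> discontinuation cohort -> comparators -> KM curves -> characteristics,
# with three independent seed streams and a run-metadata log.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full discontinuation study
#'
#' Executes every stage of the analysis on a table set (either supplied, or
#' generated by [simulate_ehr()] from a [sim_config()]): pregnancy
#' eligibility and prescribing prevalence by calendar period, assembly of
#' the continuously-prescribed discontinuation cohort, age-band-matched
#' non-pregnant comparator sampling via simulated index dates, product-limit
#' curves of time to last prescription for both groups, restart and
#' postpartum prescribing description, and the characteristics table with
#' logit-t confidence intervals. Identical inputs and seeds give identical
#' outputs; the three RNG streams (multiple-pregnancy choice, index dates,
#' comparator sampling) are seeded independently so changing one stage's
#' seed leaves the others untouched.
#'
#' @param input a `sim_config` or an `ehr_tables` list.
#' @param out_dir optional directory; when given, every output table plus a
#'   `run_metadata.txt` key-value log is written there.
#' @param seeds list with integer elements `cohort_choice`, `index_dates`,
#'   `control_sampling`.
#' @param drug drug class under study (default `"lithium"`).
#' @param ratio comparators per case (default 2).
#' @param gap_days refill-gap rule (default 91).
#' @param censor_day gestational censoring day (default 220).
#' @param six_week_day first gestational day beyond six weeks (default 43).
#' @param period_years calendar-period width for the prevalence table.
#' @return list of class `study_run`: `tables`, `eligibility`, `prevalence`,
#'   `cohort`, `restarts`, `comparators`, `km_curves` (long data frame with
#'   a `group` column), `characteristics`, and `counts` (stage-by-stage
#'   record counts).
#' @export
run_study <- function(input, out_dir = NULL,
                      seeds = list(cohort_choice = 101L, index_dates = 202L,
                                   control_sampling = 303L),
                      drug = "lithium", ratio = 2, gap_days = 91,
                      censor_day = 220, six_week_day = 43,
                      period_years = 3) {
  tables <- if (inherits(input, "sim_config"))
    stage("simulate", simulate_ehr(input)) else input
  stage("validate", validate_ehr(tables))
  study_start <- if (inherits(input, "sim_config")) input$study_start
                 else as.Date("1995-01-01")
  study_end <- if (inherits(input, "sim_config")) input$study_end
               else as.Date("2012-12-31")

  elig <- stage("eligibility",
                assess_eligibility(tables$pregnancies, tables$registrations,
                                   study_start, study_end))
  eligible <- elig[elig$eligible, , drop = FALSE]
  flagged <- stage("prescribing_flags",
                   classify_prescribing(eligible, tables$prescriptions, drug))
  prevalence <- if (nrow(flagged))
    stage("prevalence", prevalence_table(flagged, period_years,
                                         study_start, study_end))
  else NULL

  cohort <- stage("cohort", with_seed(seeds$cohort_choice,
    assemble_cohort(eligible, tables$prescriptions, drug, gap_days,
                    censor_day, six_week_day)))

  restarts <- stage("restarts", describe_restarts(cohort, tables, drug))

  comparators <- NULL
  if (nrow(cohort)) {
    candidates <- stage("index_dates", with_seed(seeds$index_dates,
      comparator_candidates(tables, cohort$patient_id, drug,
                            study_start, study_end)))
    birth <- tables$patients$birth_year[
      match(cohort$patient_id, tables$patients$patient_id)]
    cases <- data.frame(case_id = cohort$patient_id,
                        band = age_band(year_of(cohort$start_date) - birth))
    comparators <- stage("control_sampling", with_seed(seeds$control_sampling,
      sample_controls(cases, candidates, ratio)))
  }

  km <- stage("km", {
    curves <- list()
    if (nrow(cohort)) {
      kmp <- km_estimate(cohort$time, cohort$status)
      curves$pregnant <- data.frame(group = "pregnant", kmp)
    }
    if (!is.null(comparators) && nrow(comparators)) {
      ce <- comparator_followup(comparators, tables, drug, gap_days,
                                censor_day)
      kmc <- km_estimate(ce$time, ce$status)
      curves$comparator <- data.frame(group = "comparator", kmc)
    }
    if (length(curves)) do.call(rbind, curves) else NULL
  })

  chars <- if (nrow(cohort))
    stage("characteristics", characteristics_table(cohort, tables, drug))
  else NULL

  counts <- c(women_loaded = nrow(tables$patients),
              pregnancies = nrow(tables$pregnancies),
              pregnancies_eligible = nrow(eligible),
              cohort_size = nrow(cohort),
              continued_beyond_6w = sum(cohort$continuation_class ==
                                          "continued_beyond_6w"),
              comparators_sampled = if (is.null(comparators)) 0L
                                    else nrow(comparators))

  res <- structure(list(tables = tables, eligibility = elig,
                        prevalence = prevalence, cohort = cohort,
                        restarts = restarts, comparators = comparators,
                        km_curves = km, characteristics = chars,
                        counts = counts, seeds = seeds),
                   class = "study_run")
  if (!is.null(out_dir)) write_study_run(res, out_dir)
  res
}

# follow-up entries for comparator women, mirroring cases: follow-up starts
# 91 days before the index date, censoring at index + censor_day
comparator_followup <- function(comparators, tables, drug = "lithium",
                                gap_days = 91, censor_day = 220) {
  rx <- tables$prescriptions
  rx <- rx[rx$drug_class == drug, , drop = FALSE]
  rx_by <- split(rx$issue_date, rx$patient_id)
  n <- nrow(comparators)
  time <- status <- integer(n)
  for (i in seq_len(n)) {
    idx <- comparators$index_date[i]
    issues <- sort(unique(rx_by[[comparators$patient_id[i]]]))
    last_rx <- last_prescription_from(issues, idx - 1L, gap_days)
    censor <- idx + censor_day
    ev <- last_rx <= censor
    time[i] <- as.integer((if (ev) last_rx else censor) - (idx - DAYS_3M))
    status[i] <- as.integer(ev)
  }
  data.frame(patient_id = comparators$patient_id, time = time,
             status = status)
}

# per-woman restart and postpartum prescribing description for the cohort
describe_restarts <- function(cohort, tables, drug = "lithium") {
  if (!nrow(cohort)) return(NULL)
  rx <- tables$prescriptions
  rx <- rx[rx$drug_class == drug, , drop = FALSE]
  rx_by <- split(rx$issue_date, rx$patient_id)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    entry <- cohort[i, , drop = FALSE]
    fl <- detect_restart(entry, sort(unique(rx_by[[entry$patient_id]])),
                         tables$registrations)
    data.frame(patient_id = entry$patient_id,
               continuation_class = entry$continuation_class,
               restarted_during_pregnancy = fl$restarted_during_pregnancy,
               on_drug_at_183d_postpartum = fl$on_drug_at_183d_postpartum)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_study_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(res$prevalence))
    write_table(res$prevalence, file.path(out_dir, "prevalence.csv"))
  if (nrow(res$cohort))
    write_table(as.data.frame(res$cohort), file.path(out_dir, "cohort.csv"))
  if (!is.null(res$restarts))
    write_table(res$restarts, file.path(out_dir, "restarts.csv"))
  if (!is.null(res$comparators))
    write_table(res$comparators, file.path(out_dir, "comparators.csv"))
  if (!is.null(res$km_curves))
    write_table(res$km_curves, file.path(out_dir, "km_curves.csv"))
  if (!is.null(res$characteristics))
    write_table(res$characteristics, file.path(out_dir, "characteristics.csv"))
  meta <- c(sprintf("package_version=%s",
                    as.character(utils::packageVersion("preglith"))),
            sprintf("r_version=%s", R.version.string),
            sprintf("seed_cohort_choice=%d", res$seeds$cohort_choice),
            sprintf("seed_index_dates=%d", res$seeds$index_dates),
            sprintf("seed_control_sampling=%d", res$seeds$control_sampling),
            sprintf("%s=%d", names(res$counts), res$counts))
  writeLines(meta, file.path(out_dir, "run_metadata.txt"))
  invisible(out_dir)
}

#' @export
print.study_run <- function(x, ...) {
  cat("Discontinuation study run\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  if (nrow(x$cohort)) {
    n <- nrow(x$cohort)
    k <- sum(x$cohort$continuation_class == "continued_beyond_6w")
    cat(sprintf("  continued beyond 6 weeks: %d/%d (%.0f%%)\n", k, n,
                round_half_up(100 * k / n, 0)))
  }
  invisible(x)
}
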