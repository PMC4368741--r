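# Core record tables, their invariants, and delimited-text I/O.
#
# Four input tables (comma-separated, ISO-8601 dates):
#   patients:      patient_id, birth_year, household_id, recorded_parity
#   registrations: patient_id, reg_start, reg_end
#   prescriptions: patient_id, issue_date, drug_class
#   pregnancies:   patient_id, start_date, duration_days, delivery_date,
#                  outcome, duration_known
# See inst/extdata/schema.md for the full column contract.

DRUG_CLASSES <- c("lithium", "antidepressant", "antipsychotic",
                  "anticonvulsant", "other")
PREGNANCY_OUTCOMES <- c("delivery", "miscarriage", "termination")

EHR_SCHEMAS <- list(
  patients      = c("patient_id", "birth_year", "household_id",
                    "recorded_parity"),
  registrations = c("patient_id", "reg_start", "reg_end"),
  prescriptions = c("patient_id", "issue_date", "drug_class"),
  pregnancies   = c("patient_id", "start_date", "duration_days",
                    "delivery_date", "outcome", "duration_known")
)

fail_rows <- function(table, what, rows) {
  stop(sprintf("%s: %s (rows: %s)", table, what,
               paste(utils::head(rows, 10), collapse = ", ")),
       call. = FALSE)
}

parse_date_col <- function(x, table, col) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(as.character(x)))
  if (length(bad)) fail_rows(table, sprintf("unparseable date in '%s'", col), bad)
  if (anyNA(d)) fail_rows(table, sprintf("missing date in '%s'", col), which(is.na(d)))
  d
}

check_columns <- function(df, table) {
  want <- EHR_SCHEMAS[[table]]
  miss <- setdiff(want, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", table,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df[want]
}

#' Read and validate the four EHR input tables
#'
#' Reads comma-separated files with ISO-8601 dates, coerces types, enforces
#' every record-level invariant, and reports violations with row numbers.
#' A pregnancy with `duration_known = FALSE` has its duration forced to the
#' conventional 280 days of a full-term pregnancy (and its end date
#' recomputed), mirroring routine practice when gestational length is not
#' recorded.
#'
#' @param patients,registrations,prescriptions,pregnancies file paths.
#' @return A validated list of class `ehr_tables` with elements `patients`,
#'   `registrations`, `prescriptions`, `pregnancies` (data frames; date
#'   columns are `Date`).
#' @seealso [write_ehr_tables()], [validate_ehr()]
#' @export
read_ehr_tables <- function(patients, registrations, prescriptions,
                            pregnancies) {
  paths <- list(patients = patients, registrations = registrations,
                prescriptions = prescriptions, pregnancies = pregnancies)
  for (p in paths)
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)

  raw <- lapply(paths, utils::read.csv, colClasses = "character",
                na.strings = c("NA", ""))
  raw <- Map(check_columns, raw, names(raw))

  pat <- raw$patients
  pat$birth_year <- as.integer(pat$birth_year)
  pat$recorded_parity <- as.integer(pat$recorded_parity)

  reg <- raw$registrations
  reg$reg_start <- parse_date_col(reg$reg_start, "registrations", "reg_start")
  reg$reg_end   <- parse_date_col(reg$reg_end, "registrations", "reg_end")

  rx <- raw$prescriptions
  rx$issue_date <- parse_date_col(rx$issue_date, "prescriptions", "issue_date")

  pr <- raw$pregnancies
  pr$start_date    <- parse_date_col(pr$start_date, "pregnancies", "start_date")
  pr$duration_days <- as.integer(pr$duration_days)
  pr$duration_known <- as.logical(pr$duration_known)
  # unknown duration => assume a 280-day full-term pregnancy
  force280 <- !is.na(pr$duration_known) & !pr$duration_known
  pr$duration_days[force280] <- 280L
  pr$delivery_date <- pr$start_date + pr$duration_days

  tables <- structure(list(patients = pat, registrations = reg,
                           prescriptions = rx, pregnancies = pr),
                      class = "ehr_tables")
  validate_ehr(tables)
  tables
}

#' Validate an in-memory set of EHR tables
#'
#' Exhaustively checks every declared invariant: unique patient identifiers,
#' plausible birth years, ordered non-overlapping registration periods,
#' recognised drug classes and pregnancy outcomes, prescriptions falling
#' inside a registration period of their patient, and internally consistent
#' pregnancy dating.
#'
#' @param tables a list with elements `patients`, `registrations`,
#'   `prescriptions`, `pregnancies` (as from [read_ehr_tables()] or
#'   [simulate_ehr()]).
#' @return `tables`, invisibly, if valid; otherwise an error naming the
#'   offending table and rows.
#' @export
validate_ehr <- function(tables) {
  pat <- tables$patients; reg <- tables$registrations
  rx <- tables$prescriptions; pr <- tables$pregnancies

  dup <- which(duplicated(pat$patient_id))
  if (length(dup)) fail_rows("patients", "duplicate patient_id", dup)
  bad <- which(is.na(pat$birth_year) | pat$birth_year < 1945 |
                 pat$birth_year > 2005)
  if (length(bad)) fail_rows("patients", "birth_year outside [1945, 2005]", bad)

  bad <- which(!(reg$reg_start < reg$reg_end))
  if (length(bad)) fail_rows("registrations", "reg_start !< reg_end", bad)
  for (pid in unique(reg$patient_id[duplicated(reg$patient_id)])) {
    r <- reg[reg$patient_id == pid, ]
    r <- r[order(r$reg_start), ]
    if (any(r$reg_start[-1] <= r$reg_end[-nrow(r)]))
      fail_rows("registrations", paste0("overlapping periods for ", pid),
                which(tables$registrations$patient_id == pid))
  }

  bad <- which(!(rx$drug_class %in% DRUG_CLASSES))
  if (length(bad)) fail_rows("prescriptions", "unknown drug_class", bad)
  if (nrow(rx)) {
    reg_by <- split(seq_len(nrow(reg)), reg$patient_id)
    covered <- logical(nrow(rx))
    for (idx in split(seq_len(nrow(rx)), rx$patient_id)) {
      ri <- reg_by[[rx$patient_id[idx[1]]]]
      if (is.null(ri)) next
      d <- as.integer(rx$issue_date[idx])
      ok <- rep(FALSE, length(idx))
      for (j in ri)
        ok <- ok | (as.integer(reg$reg_start[j]) <= d &
                      d <= as.integer(reg$reg_end[j]))
      covered[idx] <- ok
    }
    if (any(!covered))
      fail_rows("prescriptions", "issue_date outside all registration periods",
                which(!covered))
  }

  bad <- which(!(pr$outcome %in% PREGNANCY_OUTCOMES))
  if (length(bad)) fail_rows("pregnancies", "unknown outcome", bad)
  bad <- which(is.na(pr$duration_days) | pr$duration_days <= 0L)
  if (length(bad)) fail_rows("pregnancies", "non-positive duration_days", bad)
  bad <- which(!pr$duration_known & pr$duration_days != 280L)
  if (length(bad))
    fail_rows("pregnancies", "unknown duration must be the assumed 280 days", bad)
  bad <- which(pr$duration_known &
                 (pr$duration_days < 100L | pr$duration_days > 320L))
  if (length(bad))
    fail_rows("pregnancies", "known duration_days outside [100, 320]", bad)
  bad <- which(pr$delivery_date != pr$start_date + pr$duration_days)
  if (length(bad))
    fail_rows("pregnancies", "delivery_date != start_date + duration_days", bad)

  invisible(tables)
}

#' Write a data frame as a delimited text table
#'
#' Comma-separated, ISO-8601 dates, no row names; the format read back by
#' [read_ehr_tables()] and [utils::read.csv()], so `read(write(x))` is
#' field-for-field stable.
#'
#' @param df data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  stopifnot(is.data.frame(df))
  out <- df
  for (j in seq_along(out))
    if (inherits(out[[j]], "Date")) out[[j]] <- format(out[[j]], "%Y-%m-%d")
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

#' Write the four EHR input tables to a directory
#'
#' @param tables an `ehr_tables` list.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_ehr_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(EHR_SCHEMAS))
    write_table(tables[[nm]], file.path(dir, paste0(nm, ".csv")))
  invisible(dir)
}

#' @export
print.ehr_tables <- function(x, ...) {
  cat("EHR table set:\n")
  for (nm in names(EHR_SCHEMAS))
    cat(sprintf("  %-14s %6d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}
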