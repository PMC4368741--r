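# Gap-based prescribing-episode construction and the two eligibility rules
# built on it: the continuous-prescribing predicate used to enter the
# discontinuation cohort, and the last-prescription rule that defines the
# event of interest.
#
# Conventions (inclusive day counts):
#   * consecutive issues <= gap_days apart belong to one episode; a gap of
#     exactly gap_days (default 91) does NOT break an episode;
#   * an issue is the "last prescription" of an episode when no further issue
#     follows within gap_days days;
#   * "continuously prescribed at an anchor date" requires an issue in
#     [anchor-183, anchor-92] and a later issue in [anchor-91, anchor-1]
#     whose immediately preceding issue is <= gap_days before it.

prep_issues <- function(issue_dates) {
  d <- as_day(issue_dates)
  if (is.unsorted(as.integer(d), strictly = FALSE))
    stop("issue dates must be sorted ascending", call. = FALSE)
  unique(d)  # same-day duplicate issues collapse to one
}

#' Partition issue dates into prescribing episodes
#'
#' Splits an ordered sequence of prescription issue dates wherever the gap to
#' the next issue exceeds `gap_days` days (the refill-gap rule). The default
#' of 91 days allows a patient on one- or two-monthly repeat prescriptions to
#' collect a refill early or late without breaking the episode.
#'
#' @param issue_dates sorted `Date` (or coercible) vector; same-day
#'   duplicates are collapsed.
#' @param gap_days maximum within-episode gap in days (default 91).
#' @return data frame of class `rx_episodes`, one row per episode:
#'   `episode`, `first_rx_date`, `last_rx_date`, `n_issues`.
#' @examples
#' d <- as.Date("2000-01-01") + c(0, 30, 60, 200, 230)
#' build_episodes(d)  # two episodes: the 140-day gap breaks the run
#' @export
build_episodes <- function(issue_dates, gap_days = 91) {
  d <- prep_issues(issue_dates)
  if (!length(d))
    return(structure(data.frame(episode = integer(),
                                first_rx_date = as.Date(character()),
                                last_rx_date = as.Date(character()),
                                n_issues = integer()),
                     class = c("rx_episodes", "data.frame")))
  gaps <- diff(as.integer(d))
  ep <- cumsum(c(1L, as.integer(gaps > gap_days)))
  first <- d[!duplicated(ep)]
  last <- d[!duplicated(ep, fromLast = TRUE)]
  structure(data.frame(episode = seq_along(first), first_rx_date = first,
                       last_rx_date = last,
                       n_issues = as.integer(table(ep))),
            class = c("rx_episodes", "data.frame"))
}

#' Continuous-prescribing predicate at an anchor date
#'
#' TRUE when the patient was continuously prescribed in the three months
#' before `anchor_date`: at least one issue during the 183-92 days before the
#' anchor, followed by at least one further issue during the 91-1 days before
#' the anchor that itself comes no more than `gap_days` days after the issue
#' immediately preceding it. This is the entry condition of the
#' discontinuation cohort, applied identically to pregnancy start dates and
#' to comparator index dates.
#'
#' @param issue_dates sorted issue dates for one patient and drug.
#' @param anchor_date pregnancy start or index date.
#' @param gap_days maximum refill gap in days (default 91).
#' @return logical scalar.
#' @export
is_continuous_at <- function(issue_dates, anchor_date, gap_days = 91) {
  d <- as.integer(prep_issues(issue_dates))
  a <- as.integer(as_day(anchor_date))
  if (!any(d >= a - DAYS_6M & d <= a - 92L)) return(FALSE)
  recent <- d[d >= a - DAYS_3M & d <= a - 1L]
  for (r in recent) {
    prev <- d[d < r]
    if (length(prev) && r - max(prev) <= gap_days) return(TRUE)
  }
  FALSE
}

#' Last prescription of the episode in progress at a date
#'
#' Returns the final issue date of the prescribing episode containing the
#' latest issue on or before `from_date`: the issue after which more than
#' `gap_days` prescription-free days follow (or the final issue on record).
#'
#' @param issue_dates sorted issue dates for one patient and drug.
#' @param from_date a date covered by a prescribing episode.
#' @param gap_days maximum refill gap in days (default 91).
#' @return the last-prescription `Date` of that episode.
#' @export
last_prescription_from <- function(issue_dates, from_date, gap_days = 91) {
  d <- prep_issues(issue_dates)
  f <- as_day(from_date)
  at <- which(d <= f)
  if (!length(at))
    stop("no prescribing episode covers from_date", call. = FALSE)
  i <- max(at)
  while (i < length(d) && as.integer(d[i + 1L] - d[i]) <= gap_days)
    i <- i + 1L
  d[i]
}
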