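# Independent brute-force oracles and small fixture builders.

D0 <- as.Date("2000-06-01")  # a generic anchor date for window fixtures

# Episode partition oracle: connected components of the graph joining any
# two issue dates at most gap_days apart (for sorted dates this induces the
# same partition as the consecutive-gap rule, but is computed from all
# pairs rather than a linear scan).
brute_episodes <- function(days, gap_days = 91) {
  days <- sort(unique(as.integer(days)))
  n <- length(days)
  if (!n) return(list())
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(days[i] - days[j]) <= gap_days && comp[i] != comp[j]) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(days, comp), identity))
}

# last-prescription oracle: step forward one issue at a time
brute_last_rx <- function(days, from, gap_days = 91) {
  days <- sort(unique(as.integer(days)))
  cur <- max(days[days <= from])
  repeat {
    nxt <- days[days > cur & days <= cur + gap_days]
    if (!length(nxt)) return(cur)
    cur <- min(nxt)
  }
}

# minimal valid table set: one woman, fully registered, with the supplied
# lithium issue offsets (days relative to `anchor`), one delivered pregnancy
# starting at `anchor`
one_woman_tables <- function(issue_offsets, anchor = D0, birth_year = 1970,
                             duration = 280L, outcome = "delivery",
                             extra_rx = NULL, recorded_parity = NA,
                             reg_start = anchor - 2000,
                             reg_end = anchor + 2000) {
  offs <- sort(issue_offsets)
  rx <- data.frame(patient_id = rep("W1", length(offs)),
                   issue_date = anchor + offs,
                   drug_class = rep("lithium", length(offs)))
  if (!is.null(extra_rx)) rx <- rbind(rx, extra_rx)
  structure(list(
    patients = data.frame(patient_id = "W1", birth_year = birth_year,
                          household_id = "H1",
                          recorded_parity = as.integer(recorded_parity)),
    registrations = data.frame(patient_id = "W1", reg_start = reg_start,
                               reg_end = reg_end),
    prescriptions = rx,
    pregnancies = data.frame(patient_id = "W1", start_date = anchor,
                             duration_days = as.integer(duration),
                             delivery_date = anchor + duration,
                             outcome = outcome, duration_known = TRUE)),
    class = "ehr_tables")
}

# random small issue sets for oracle-equivalence sweeps
random_issue_days <- function(n_max = 12, lo = -400, hi = 400) {
  n <- sample.int(n_max, 1)
  sort(sample(lo:hi, n))
}
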