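# Independent oracles used to cross-check the engine implementations.
# These are written in a deliberately different style (plain base-R loops,
# minute-resolution scanning) so that agreement with the package's vectorised
# code is meaningful.

# Scheduled dose instants for the oracle, as POSIXct (UTC = naive local time).
oracle_slots <- function(schedule, start, days) {
  out <- c()
  for (d in seq_len(days) - 1L) {
    for (m in schedule$dose_minutes) {
      out <- c(out, as.numeric(as.POSIXct(as.Date(start), tz = "UTC")) + d * 86400 + m * 60)
    }
  }
  out
}

# Brute-force slot matcher: for each slot in time order, scan outward minute
# by minute from the scheduled instant until an unmatched event is found or
# half the target interval is exhausted. At equal distance the earlier event
# wins. Returns a list with match (event index or NA) per slot.
oracle_match <- function(events, schedule, period) {
  period <- as.Date(period)
  days <- as.integer(period[2] - period[1])
  sched <- oracle_slots(schedule, period[1], days)
  t0 <- as.numeric(as.POSIXct(period[1], tz = "UTC"))
  t1 <- as.numeric(as.POSIXct(period[2], tz = "UTC"))
  ev_t <- as.numeric(events$timestamp)
  keep <- which(ev_t >= t0 & ev_t < t1)
  ev_t <- ev_t[keep]
  half_min <- schedule$target_interval * 30  # half interval, in minutes
  used <- rep(FALSE, length(ev_t))
  match <- rep(NA_integer_, length(sched))
  for (s in seq_along(sched)) {
    found <- NA_integer_
    for (d in 0:half_min) {
      before <- which(!used & ev_t == sched[s] - d * 60)
      after <- which(!used & ev_t == sched[s] + d * 60)
      cand <- c(before, after)
      if (length(cand)) { found <- min(cand); break }
    }
    if (!is.na(found)) { match[s] <- keep[found]; used[found] <- TRUE }
  }
  list(scheduled = sched, match = match,
       unscheduled = keep[!used])
}

oracle_slot_status <- function(events, schedule, period) {
  m <- oracle_match(events, schedule, period)
  window_sec <- schedule$window * 3600
  status <- character(length(m$scheduled))
  for (s in seq_along(m$scheduled)) {
    j <- m$match[s]
    if (is.na(j)) { status[s] <- "missed"; next }
    dt <- abs(as.numeric(events$timestamp[j]) - m$scheduled[s])
    if (dt > window_sec) {
      status[s] <- "taken_out_of_window"
    } else if (events$pills_taken[j] == schedule$pills_per_dose) {
      status[s] <- "taken_ok"
    } else {
      status[s] <- "taken_dosage_error"
    }
  }
  status
}

# Minute-resolution replay of the alarm process: for every slot, walk the
# clock minute by minute from the window break through the last escalation;
# an alarm due at minute t fires iff the slot's matched intake (if any) is
# strictly later than t. Dosage / timing feedback fires at the intake minute.
oracle_feedback <- function(events, schedule, period, patient_id = "PX") {
  m <- oracle_match(events, schedule, period)
  status <- oracle_slot_status(events, schedule, period)
  window_sec <- schedule$window * 3600
  latency_sec <- schedule$alarm_latency * 60
  gap_min <- schedule$escalation_gap
  rows <- list()
  for (s in seq_along(m$scheduled)) {
    j <- m$match[s]
    intake <- if (is.na(j)) Inf else as.numeric(events$timestamp[j])
    brk <- m$scheduled[s] + window_sec + latency_sec
    due <- brk + (0:schedule$max_escalations) * gap_min * 60
    k <- 0L
    for (minute in seq(brk, max(due), by = 60)) {
      if (minute %in% due) {
        esc <- match(minute, due) - 1L
        if (intake > minute) {
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = patient_id, timestamp = minute,
            kind = "missed_dose", escalation_index = esc, slot_index = s - 1L)
        }
        k <- k + 1L
      }
      if (intake <= minute) break
    }
    if (status[s] == "taken_out_of_window") {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patient_id, timestamp = intake,
        kind = "timing_error", escalation_index = 0L, slot_index = s - 1L)
    }
    if (status[s] == "taken_dosage_error") {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patient_id, timestamp = intake,
        kind = "dosage_error", escalation_index = 0L, slot_index = s - 1L)
    }
  }
  if (!length(rows)) {
    return(data.frame(patient_id = character(), timestamp = numeric(),
                      kind = character(), escalation_index = integer(),
                      slot_index = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$timestamp, out$slot_index, out$escalation_index), , drop = FALSE]
}

# Exhaustive day-by-day recount of the four adherence metrics.
oracle_metrics <- function(events, schedule, period) {
  period <- as.Date(period)
  days <- as.integer(period[2] - period[1])
  n_doses <- length(schedule$dose_minutes)
  lo <- schedule$target_interval * (1 - schedule$interval_margin)
  hi <- schedule$target_interval * (1 + schedule$interval_margin)
  pills_total <- 0
  correct_days <- 0
  interval_days <- 0
  holiday_days <- 0
  for (d in seq_len(days) - 1L) {
    day_start <- as.numeric(as.POSIXct(period[1], tz = "UTC")) + d * 86400
    tt <- as.numeric(events$timestamp)
    sel <- tt >= day_start & tt < day_start + 86400
    day_ev <- events[sel, , drop = FALSE]
    pills_total <- pills_total + sum(day_ev$pills_taken)
    if (nrow(day_ev) == 0) holiday_days <- holiday_days + 1
    if (nrow(day_ev) == n_doses && all(day_ev$pills_taken == schedule$pills_per_dose)) {
      correct_days <- correct_days + 1
    }
    if (nrow(day_ev) >= 2) {
      ts <- sort(as.numeric(day_ev$timestamp))
      gap_h <- (ts[2] - ts[1]) / 3600
      if (gap_h >= lo && gap_h <= hi) interval_days <- interval_days + 1
    }
  }
  prescribed <- days * n_doses * schedule$pills_per_dose
  c(dose_taking = min(100, 100 * pills_total / prescribed),
    dose_frequency = 100 * correct_days / days,
    dose_interval = 100 * interval_days / days,
    drug_holidays = 100 * holiday_days / days)
}

# Random single-patient event log at whole-minute resolution, exercising
# misses, jitter, late/early out-of-window intakes, wrong pill counts and
# occasional unscheduled extra openings.
random_event_log <- function(schedule, days = NULL, start = as.Date("2024-03-01"),
                             patient_id = "PX") {
  if (is.null(days)) days <- sample(1:14, 1)
  sched <- oracle_slots(schedule, start, days)
  times <- c(); pills <- c()
  for (s in sched) {
    u <- runif(1)
    if (u < 0.15) next                      # missed
    if (u < 0.30) {                         # out of window (late or early)
      off <- sample(c(-1, 1), 1) * sample((schedule$window * 60 + 1):(schedule$window * 60 + 150), 1)
    } else {
      off <- sample(seq(-schedule$window * 60, schedule$window * 60), 1)
    }
    times <- c(times, s + off * 60)
    pills <- c(pills, if (runif(1) < 0.1) schedule$pills_per_dose + 1L else schedule$pills_per_dose)
  }
  # occasional unscheduled opening
  if (runif(1) < 0.3 && days >= 2) {
    times <- c(times, as.numeric(as.POSIXct(start, tz = "UTC")) +
                 sample(0:(days * 1440 - 1), 1) * 60)
    pills <- c(pills, 1L)
  }
  if (!length(times)) {
    return(tibble::tibble(patient_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                          drug_id = character(), pills_taken = integer()))
  }
  ord <- order(times)
  tibble::tibble(
    patient_id = patient_id,
    timestamp = as.POSIXct(times[ord], origin = "1970-01-01", tz = "UTC"),
    drug_id = "drugA",
    pills_taken = as.integer(pills[ord])
  )
}

# Events for a patient who takes every dose exactly on schedule.
perfect_event_log <- function(schedule, days, start = as.Date("2024-01-01"),
                              patient_id = "P1", pills = schedule$pills_per_dose) {
  sched <- oracle_slots(schedule, start, days)
  tibble::tibble(
    patient_id = patient_id,
    timestamp = as.POSIXct(sched, origin = "1970-01-01", tz = "UTC"),
    drug_id = "drugA",
    pills_taken = as.integer(rep(pills, length(sched)))
  )
}
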