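#' Match intake events to scheduled dose slots
#'
#' Builds one dose slot per scheduled dose for each patient over the period
#' and assigns each pill-box opening to at most one slot. A slot's candidate
#' intake is the not-yet-matched event nearest to the scheduled time, searched
#' within +/- half the target interval so that matching is unambiguous for a
#' twice-daily schedule; slots are processed greedily in time order and ties
#' in distance go to the earlier event. Each matched slot is classified:
#'
#' * `taken_ok` — intake within `[scheduled - window, scheduled + window]`
#'   and the prescribed pill count;
#' * `taken_dosage_error` — in-window but the wrong pill count;
#' * `taken_out_of_window` — matched but outside the window (timing takes
#'   precedence over dosage, so one event never yields two violation kinds);
#' * `missed` — no matched event.
#'
#' Openings not matched to any slot (unscheduled extra intakes) are returned
#' separately via [unscheduled_intakes()].
#'
#' @param events Validated event tibble (see [read_event_log()]); may cover
#'   several patients.
#' @param schedule An [rx_schedule()].
#' @param period Length-2 vector coercible to Date: the half-open day range
#'   `[start, end)`.
#' @param patients Optional character vector of patients to build slots for;
#'   defaults to the patients present in `events`.
#' @return A tibble of dose slots: `patient_id`, `slot_index` (0-based from
#'   the first scheduled dose of the period), `scheduled` (POSIXct), `status`,
#'   `intake_time`, `pills_taken`; the unmatched events are attached as the
#'   `"unscheduled"` attribute.
#' @export
match_intakes_to_slots <- function(events, schedule, period, patients = NULL) {
  stopifnot(inherits(schedule, "rx_schedule"))
  period <- as.Date(period)
  days <- as.integer(period[2] - period[1])
  if (is.na(days) || days < 1L) stop("`period` must cover at least one day", call. = FALSE)
  if (is.null(patients)) patients <- unique(events$patient_id)

  grid <- slot_grid(schedule, period[1], days)
  half_range <- schedule$target_interval * 3600 / 2
  window_sec <- schedule$window * 3600
  t0 <- as.numeric(as.POSIXct(period[1], tz = "UTC"))
  t1 <- as.numeric(as.POSIXct(period[2], tz = "UTC"))

  out <- vector("list", length(patients))
  unsched <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    pid <- patients[i]
    ev <- events[events$patient_id == pid, , drop = FALSE]
    ev_t <- as.numeric(ev$timestamp)
    in_period <- ev_t >= t0 & ev_t < t1
    ev <- ev[in_period, , drop = FALSE]
    ev_t <- ev_t[in_period]
    n_ev <- length(ev_t)
    sched_t <- as.numeric(grid$scheduled)
    n_slot <- length(sched_t)
    match_idx <- rep(NA_integer_, n_slot)
    taken <- rep(FALSE, n_ev)
    for (s in seq_len(n_slot)) {
      if (n_ev == 0L) break
      d <- abs(ev_t - sched_t[s])
      d[taken] <- Inf
      j <- which.min(d)
      if (length(j) && d[j] <= half_range) {
        match_idx[s] <- j
        taken[j] <- TRUE
      }
    }
    intake_time <- ev$timestamp[match_idx]
    pills <- ev$pills_taken[match_idx]
    dist <- abs(as.numeric(intake_time) - sched_t)
    in_window <- !is.na(match_idx) & dist <= window_sec
    status <- dplyr::case_when(
      is.na(match_idx) ~ "missed",
      !in_window ~ "taken_out_of_window",
      pills == schedule$pills_per_dose ~ "taken_ok",
      TRUE ~ "taken_dosage_error"
    )
    out[[i]] <- tibble::tibble(
      patient_id = pid,
      slot_index = grid$slot_index,
      scheduled = grid$scheduled,
      status = status,
      intake_time = intake_time,
      pills_taken = pills
    )
    unsched[[i]] <- ev[!taken, , drop = FALSE]
  }
  slots <- dplyr::bind_rows(out)
  attr(slots, "unscheduled") <- dplyr::bind_rows(unsched)
  slots
}

#' Unscheduled extra intakes left over from slot matching
#'
#' @param slots The result of [match_intakes_to_slots()].
#' @return Tibble of pill-box openings that were not assigned to any dose
#'   slot. These are surfaced for reporting but generate no feedback by
#'   default.
#' @export
unscheduled_intakes <- function(slots) {
  attr(slots, "unscheduled") %||% tibble::tibble()
}

#' Generate the feedback/alarm stream for classified dose slots
#'
#' Reproduces the reminder-escalation logic of a centralized electronic
#' monitoring system. For a dose still untaken at the break of the allowed
#' window, a `missed_dose` alarm fires at `scheduled + window` (plus the
#' configured delivery latency), followed by up to `max_escalations` further
#' alarms at `escalation_gap`-minute intervals; the chain stops immediately
#' once an intake is matched to the slot, so only alarms strictly earlier
#' than the intake are emitted. A late intake additionally yields one
#' `timing_error` at the intake instant (the violation factually occurred),
#' as does an early out-of-window intake; an in-window intake with the wrong
#' pill count yields one `dosage_error` at the intake instant.
#'
#' @param slots Slot tibble from [match_intakes_to_slots()].
#' @param schedule The [rx_schedule()] used for matching.
#' @return Tibble of feedback events: `patient_id`, `timestamp`, `kind`
#'   (`missed_dose`/`dosage_error`/`timing_error`), `escalation_index`
#'   (0 for the first alarm; positive only for `missed_dose`), `slot_index`;
#'   ordered by patient and timestamp.
#' @export
generate_feedback <- function(slots, schedule) {
  stopifnot(inherits(schedule, "rx_schedule"))
  gap <- schedule$escalation_gap * 60
  break_off <- schedule$window * 3600 + schedule$alarm_latency * 60
  k <- 0:schedule$max_escalations

  alarm_src <- slots |>
    dplyr::filter(.data$status %in% c("missed", "taken_out_of_window")) |>
    dplyr::mutate(late = .data$status == "taken_out_of_window" &
                    .data$intake_time > .data$scheduled + break_off) |>
    dplyr::filter(.data$status == "missed" | .data$late)
  alarms <- alarm_src |>
    tidyr::crossing(escalation_index = k) |>
    dplyr::mutate(timestamp = .data$scheduled + break_off + .data$escalation_index * gap) |>
    dplyr::filter(.data$status == "missed" | .data$timestamp < .data$intake_time) |>
    dplyr::transmute(.data$patient_id, .data$timestamp, kind = "missed_dose",
                     .data$escalation_index, .data$slot_index)

  dosage <- slots |>
    dplyr::filter(.data$status == "taken_dosage_error") |>
    dplyr::transmute(.data$patient_id, timestamp = .data$intake_time,
                     kind = "dosage_error", escalation_index = 0L, .data$slot_index)

  timing <- slots |>
    dplyr::filter(.data$status == "taken_out_of_window") |>
    dplyr::transmute(.data$patient_id, timestamp = .data$intake_time,
                     kind = "timing_error", escalation_index = 0L, .data$slot_index)

  dplyr::bind_rows(alarms, dosage, timing) |>
    dplyr::arrange(.data$patient_id, .data$timestamp, .data$slot_index,
                   .data$escalation_index)
}

#' Count feedback occurrences by kind
#'
#' With `dedupe = TRUE` (the counting convention of per-violation feedback
#' tallies), the escalation chain of one missed slot counts as a single
#' missed-dose occurrence; with `dedupe = FALSE`, raw message counts are
#' returned (up to `1 + max_escalations` per missed slot).
#'
#' @param feedback Tibble from [generate_feedback()].
#' @param dedupe Logical, default `TRUE`.
#' @return Tibble with columns `kind` and `n`.
#' @export
count_feedback_by_kind <- function(feedback, dedupe = TRUE) {
  if (nrow(feedback) == 0) {
    return(tibble::tibble(kind = character(), n = integer()))
  }
  fb <- if (dedupe) {
    dplyr::distinct(feedback, .data$patient_id, .data$slot_index, .data$kind)
  } else {
    feedback
  }
  fb |>
    dplyr::count(.data$kind, name = "n") |>
    dplyr::arrange(.data$kind)
}
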