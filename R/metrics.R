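#' @title Electronic-monitoring adherence metrics
#' @description
#' The four standard metrics computed from pill-box intake logs over a
#' half-open day range `[start, end)`:
#'
#' * **dose-taking adherence** — pills taken / pills prescribed x 100,
#'   capped at 100 (extra unscheduled pills cannot push it above 100);
#' * **dose-frequency adherence** — days of correct daily dosing / days x
#'   100, where a day is correct iff the number of openings equals the number
#'   of scheduled doses and every opening delivered the prescribed pill
#'   count (timing is deliberately not part of this metric — it lives in
#'   dose-interval adherence, keeping the metrics non-redundant);
#' * **dose-interval adherence** — days whose within-day interval between
#'   the first and second intake lies in the allowed range
#'   (`target_interval * (1 +/- margin)`, i.e. 9–15 h for a 12-h schedule at
#'   +/-25%) / days x 100; for a twice-daily schedule exactly one candidate
#'   interval exists per day, so a perfect patient scores 100;
#' * **drug holidays** — days with no intake at all / days x 100.
#'
#' Days are calendar dates of the local clock. Events outside the period are
#' ignored.
#' @name adherence-metrics
NULL

# Per patient x calendar day summary used by all four metrics.
daily_intake_stats <- function(events, schedule, period) {
  period <- as.Date(period)
  t0 <- as.POSIXct(period[1], tz = "UTC")
  t1 <- as.POSIXct(period[2], tz = "UTC")
  events |>
    dplyr::filter(.data$timestamp >= t0, .data$timestamp < t1) |>
    dplyr::mutate(day = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::group_by(.data$patient_id, .data$day) |>
    dplyr::summarise(
      n_intakes = dplyr::n(),
      pills = sum(.data$pills_taken),
      all_correct_pills = all(.data$pills_taken == schedule$pills_per_dose),
      interval_h = if (dplyr::n() >= 2) {
        as.numeric(difftime(sort(.data$timestamp)[2], sort(.data$timestamp)[1],
                            units = "hours"))
      } else NA_real_,
      .groups = "drop"
    )
}

check_period <- function(period) {
  period <- as.Date(period)
  days <- as.integer(period[2] - period[1])
  if (is.na(days) || days < 1L) stop("`period` must cover at least one day", call. = FALSE)
  days
}

#' Dose-taking adherence
#'
#' Pills taken over the period divided by pills prescribed over the same
#' period, times 100, capped at 100.
#'
#' @param events Event tibble for one patient (extra patients are an error).
#' @param schedule An [rx_schedule()].
#' @param period Length-2 Date range, half-open `[start, end)`.
#' @return A percentage in `[0, 100]`.
#' @family adherence metrics
#' @export
dose_taking_adherence <- function(events, schedule, period) {
  days <- check_period(period)
  one_patient(events)
  prescribed <- days * length(schedule$dose_minutes) * schedule$pills_per_dose
  if (prescribed == 0) stop("schedule prescribes zero pills over the period", call. = FALSE)
  d <- daily_intake_stats(events, schedule, period)
  min(100, 100 * sum(d$pills) / prescribed)
}

#' Dose-frequency adherence
#'
#' Fraction of days with correct daily dosing (right number of openings,
#' each with the prescribed pill count), times 100.
#'
#' @inheritParams dose_taking_adherence
#' @return A percentage in `[0, 100]`.
#' @family adherence metrics
#' @export
dose_frequency_adherence <- function(events, schedule, period) {
  days <- check_period(period)
  one_patient(events)
  n_doses <- length(schedule$dose_minutes)
  d <- daily_intake_stats(events, schedule, period)
  correct <- sum(d$n_intakes == n_doses & d$all_correct_pills)
  100 * correct / days
}

#' Dose-interval adherence
#'
#' Fraction of days whose within-day first-to-second intake interval lies in
#' the allowed range (see [allowed_interval_bounds()]), times 100. Days with
#' fewer than two intakes contribute no correct interval. The overnight
#' (evening to next morning) interval is not counted here; it is available
#' from [overnight_intervals()] as a diagnostic.
#'
#' @inheritParams dose_taking_adherence
#' @return A percentage in `[0, 100]`.
#' @family adherence metrics
#' @export
dose_interval_adherence <- function(events, schedule, period) {
  days <- check_period(period)
  one_patient(events)
  bounds <- allowed_interval_bounds(schedule)
  d <- daily_intake_stats(events, schedule, period)
  correct <- sum(!is.na(d$interval_h) &
                   d$interval_h >= bounds[["low"]] & d$interval_h <= bounds[["high"]])
  100 * correct / days
}

#' Drug holidays
#'
#' Fraction of calendar days in the period with zero intake events, times
#' 100.
#'
#' @inheritParams dose_taking_adherence
#' @return A percentage in `[0, 100]`.
#' @family adherence metrics
#' @export
drug_holidays <- function(events, schedule, period) {
  days <- check_period(period)
  one_patient(events)
  d <- daily_intake_stats(events, schedule, period)
  100 * (days - nrow(d)) / days
}

#' Overnight between-day dosing intervals (diagnostic)
#'
#' The intervals from each day's last intake to the next day's first intake,
#' which dose-interval adherence deliberately excludes.
#'
#' @inheritParams dose_taking_adherence
#' @return Tibble with `day` and `overnight_h`.
#' @export
overnight_intervals <- function(events, schedule, period) {
  check_period(period)
  one_patient(events)
  period <- as.Date(period)
  ev <- events |>
    dplyr::filter(.data$timestamp >= as.POSIXct(period[1], tz = "UTC"),
                  .data$timestamp < as.POSIXct(period[2], tz = "UTC")) |>
    dplyr::mutate(day = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(first = min(.data$timestamp), last = max(.data$timestamp),
                     .groups = "drop") |>
    dplyr::arrange(.data$day)
  if (nrow(ev) < 2) return(tibble::tibble(day = as.Date(character()), overnight_h = double()))
  consec <- which(diff(as.integer(ev$day)) == 1L)
  tibble::tibble(
    day = ev$day[consec],
    overnight_h = as.numeric(difftime(ev$first[consec + 1L], ev$last[consec],
                                      units = "hours"))
  )
}

#' Adherence summary for one patient over one follow-up period
#'
#' Computes all four metrics over the half-open 4-week window ending at the
#' given visit: period `k` covers days `[start + 28*(k-1), start + 28*k)`.
#'
#' @param events Event tibble for the patient.
#' @param schedule An [rx_schedule()].
#' @param start_date The patient's study start date.
#' @param period_index Integer 1..6 (visits at 4, 8, 12, 16, 20, 24 weeks).
#' @param period_days Days per follow-up period (default 28).
#' @param n_periods Number of follow-up periods (default 6).
#' @return One-row tibble: `patient_id`, `period`, `dose_taking`,
#'   `dose_frequency`, `dose_interval`, `drug_holidays`.
#' @export
summarize_period <- function(events, schedule, start_date, period_index,
                             period_days = 28L, n_periods = 6L) {
  if (!is.numeric(period_index) || length(period_index) != 1L ||
      period_index < 1 || period_index > n_periods || period_index != round(period_index)) {
    stop("`period_index` must be an integer in 1..", n_periods, call. = FALSE)
  }
  pid <- one_patient(events)
  start_date <- as.Date(start_date)
  p0 <- start_date + (period_index - 1L) * period_days
  win <- c(p0, p0 + period_days)
  tibble::tibble(
    patient_id = pid,
    period = as.integer(period_index),
    dose_taking = dose_taking_adherence(events, schedule, win),
    dose_frequency = dose_frequency_adherence(events, schedule, win),
    dose_interval = dose_interval_adherence(events, schedule, win),
    drug_holidays = drug_holidays(events, schedule, win)
  )
}

#' Per-patient, per-period adherence summaries for a whole cohort
#'
#' Vectorised equivalent of calling [summarize_period()] for every patient
#' and period; used by the trial comparison and the per-period adherence
#' figure.
#'
#' @param events Event tibble covering the cohort.
#' @param cohort Cohort tibble (`patient_id`, `arm`, `start_date`), see
#'   [read_cohort()].
#' @param schedule An [rx_schedule()].
#' @param periods Integer vector of period indices (default `1:6`).
#' @param period_days Days per period (default 28).
#' @return Tibble with one row per patient x period and the four metric
#'   columns.
#' @export
summarize_adherence <- function(events, cohort, schedule, periods = 1:6,
                                period_days = 28L) {
  stopifnot(all(c("patient_id", "start_date") %in% names(cohort)))
  n_doses <- length(schedule$dose_minutes)
  ppd <- schedule$pills_per_dose
  bounds <- allowed_interval_bounds(schedule)
  start_map <- cohort |> dplyr::select("patient_id", "start_date")

  day_stats <- events |>
    dplyr::inner_join(start_map, by = "patient_id") |>
    dplyr::mutate(day_off = as.integer(as.Date(.data$timestamp, tz = "UTC") -
                                         .data$start_date),
                  period = .data$day_off %/% period_days + 1L) |>
    dplyr::filter(.data$period %in% periods) |>
    dplyr::group_by(.data$patient_id, .data$period, .data$day_off) |>
    dplyr::summarise(
      n_intakes = dplyr::n(),
      pills = sum(.data$pills_taken),
      all_correct_pills = all(.data$pills_taken == ppd),
      interval_h = if (dplyr::n() >= 2) {
        ts <- sort(.data$timestamp)
        as.numeric(difftime(ts[2], ts[1], units = "hours"))
      } else NA_real_,
      .groups = "drop"
    )

  per_pp <- day_stats |>
    dplyr::group_by(.data$patient_id, .data$period) |>
    dplyr::summarise(
      pills = sum(.data$pills),
      correct_days = sum(.data$n_intakes == n_doses & .data$all_correct_pills),
      interval_days = sum(!is.na(.data$interval_h) &
                            .data$interval_h >= bounds[["low"]] &
                            .data$interval_h <= bounds[["high"]]),
      intake_days = dplyr::n(),
      .groups = "drop"
    )

  tidyr::crossing(patient_id = cohort$patient_id, period = as.integer(periods)) |>
    dplyr::left_join(per_pp, by = c("patient_id", "period")) |>
    dplyr::mutate(dplyr::across(c("pills", "correct_days", "interval_days", "intake_days"),
                                ~ tidyr::replace_na(.x, 0))) |>
    dplyr::transmute(
      .data$patient_id, .data$period,
      dose_taking = pmin(100, 100 * .data$pills / (period_days * n_doses * ppd)),
      dose_frequency = 100 * .data$correct_days / period_days,
      dose_interval = 100 * .data$interval_days / period_days,
      drug_holidays = 100 * (period_days - .data$intake_days) / period_days
    ) |>
    dplyr::arrange(.data$patient_id, .data$period)
}

one_patient <- function(events) {
  pid <- unique(events$patient_id)
  if (length(pid) > 1L) {
    stop("expected events for a single patient; got ", length(pid), call. = FALSE)
  }
  if (length(pid) == 0L) NA_character_ else pid
}
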