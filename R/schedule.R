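#' Prescription schedule for fixed-clock-time dosing
#'
#' Describes a fixed daily dosing regimen as monitored by a smart pill box:
#' the scheduled clock times, the pills due at each dose, the allowed intake
#' window around each scheduled time, the interval margin used for
#' dose-interval adherence, and the missed-dose alarm escalation parameters.
#'
#' The defaults describe the twice-daily immunosuppressant regimen typical of
#' kidney-transplant maintenance therapy: doses at 08:00 and 20:00 (a 12-hour
#' target interval), an allowed window of +/- 3 hours around each scheduled
#' time, and a +/- 25% interval margin so that the allowed between-dose
#' interval runs from 9 to 15 hours. When a dose is still untaken at the
#' break of the window, the first missed-dose alarm fires, followed by up to
#' `max_escalations` further alarms at `escalation_gap`-minute intervals.
#'
#' @param dose_times Character vector of clock times, `"HH:MM"`, strictly
#'   increasing within the day. Default `c("08:00", "20:00")`.
#' @param target_interval Target between-dose interval in hours (default 12).
#'   With exactly two doses per day the scheduled times must be separated by
#'   this interval.
#' @param pills_per_dose Positive integer, pills due at each scheduled dose.
#' @param window Allowed deviation from the scheduled time, in hours
#'   (default 3): an intake within `[scheduled - window, scheduled + window]`
#'   is on time.
#' @param interval_margin Fractional margin on the target interval (default
#'   0.25) defining the allowed dosing interval
#'   `target_interval * (1 -/+ interval_margin)`.
#' @param escalation_gap Minutes between successive missed-dose alarms
#'   (default 30).
#' @param max_escalations Maximum number of alarms after the first
#'   (default 2, so at most 3 messages per missed dose).
#' @param alarm_latency Delivery latency in minutes between the window break
#'   and the first alarm (default 0; alarms fire exactly at the break).
#'
#' @return An object of class `rx_schedule`.
#' @examples
#' sched <- rx_schedule()
#' allowed_interval_bounds(sched)
#' @export
rx_schedule <- function(dose_times = c("08:00", "20:00"),
                        target_interval = 12,
                        pills_per_dose = 1L,
                        window = 3,
                        interval_margin = 0.25,
                        escalation_gap = 30,
                        max_escalations = 2L,
                        alarm_latency = 0) {
  mins <- parse_clock_times(dose_times)
  if (length(mins) < 1L) {
    stop("`dose_times` must contain at least one clock time", call. = FALSE)
  }
  if (is.unsorted(mins, strictly = TRUE)) {
    stop("`dose_times` must be strictly increasing within the day", call. = FALSE)
  }
  if (!is.numeric(target_interval) || target_interval <= 0) {
    stop("`target_interval` must be a positive number of hours", call. = FALSE)
  }
  if (length(mins) == 2L && !isTRUE(all.equal(diff(mins) / 60, target_interval))) {
    stop("with two doses per day, `dose_times` must be separated by `target_interval` hours",
         call. = FALSE)
  }
  pills_per_dose <- as.integer(pills_per_dose)
  if (is.na(pills_per_dose) || pills_per_dose < 1L) {
    stop("`pills_per_dose` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(window) || window <= 0) {
    stop("`window` must be a positive number of hours", call. = FALSE)
  }
  if (!is.numeric(interval_margin) || interval_margin <= 0 || interval_margin >= 1) {
    stop("`interval_margin` must lie strictly between 0 and 1", call. = FALSE)
  }
  max_escalations <- as.integer(max_escalations)
  if (is.na(max_escalations) || max_escalations < 0L) {
    stop("`max_escalations` must be a non-negative integer", call. = FALSE)
  }
  if (!is.numeric(escalation_gap) || escalation_gap <= 0) {
    stop("`escalation_gap` must be a positive number of minutes", call. = FALSE)
  }
  if (!is.numeric(alarm_latency) || alarm_latency < 0) {
    stop("`alarm_latency` must be a non-negative number of minutes", call. = FALSE)
  }
  structure(
    list(
      dose_times = format_clock_times(mins),
      dose_minutes = mins,
      target_interval = as.numeric(target_interval),
      pills_per_dose = pills_per_dose,
      window = as.numeric(window),
      interval_margin = as.numeric(interval_margin),
      escalation_gap = as.numeric(escalation_gap),
      max_escalations = max_escalations,
      alarm_latency = as.numeric(alarm_latency)
    ),
    class = "rx_schedule"
  )
}

#' @export
print.rx_schedule <- function(x, ...) {
  lo_hi <- allowed_interval_bounds(x)
  cat("<rx_schedule>\n")
  cat("  dose times      : ", paste(x$dose_times, collapse = ", "),
      "  (", x$pills_per_dose, " pill(s)/dose)\n", sep = "")
  cat("  target interval : ", x$target_interval, " h, margin ±",
      100 * x$interval_margin, "% -> allowed ", lo_hi[[1]], "–",
      lo_hi[[2]], " h\n", sep = "")
  cat("  intake window   : ±", x$window, " h\n", sep = "")
  cat("  alarms          : up to ", 1L + x$max_escalations,
      " missed-dose messages, ", x$escalation_gap, " min apart\n", sep = "")
  invisible(x)
}

#' Allowed dosing-interval bounds
#'
#' The allowed between-dose interval under a schedule:
#' `target_interval * (1 - interval_margin)` to
#' `target_interval * (1 + interval_margin)`. For the default 12-hour
#' schedule with a 25% margin this is 9 to 15 hours.
#'
#' @param schedule An [rx_schedule()].
#' @return Named numeric vector `c(low = , high = )`, in hours.
#' @examples
#' allowed_interval_bounds(rx_schedule())  # c(low = 9, high = 15)
#' @export
allowed_interval_bounds <- function(schedule) {
  stopifnot(inherits(schedule, "rx_schedule"))
  c(low = schedule$target_interval * (1 - schedule$interval_margin),
    high = schedule$target_interval * (1 + schedule$interval_margin))
}

# "HH:MM" -> minutes since midnight
parse_clock_times <- function(x) {
  if (!is.character(x)) stop("`dose_times` must be character \"HH:MM\"", call. = FALSE)
  ok <- grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", x)
  if (!all(ok)) {
    stop("malformed clock time(s): ", paste(x[!ok], collapse = ", "), call. = FALSE)
  }
  h <- as.integer(sub(":.*$", "", x))
  m <- as.integer(sub("^.*:", "", x))
  h * 60L + m
}

format_clock_times <- function(mins) {
  sprintf("%02d:%02d", mins %/% 60L, mins %% 60L)
}

# Scheduled dose instants for one patient over [start_date, start_date + days).
# Slot indices are 0-based from the first scheduled dose on the start date.
slot_grid <- function(schedule, start_date, days) {
  start_date <- as.Date(start_date)
  stopifnot(days >= 1)
  day_off <- rep(seq_len(days) - 1L, each = length(schedule$dose_minutes))
  within <- rep(schedule$dose_minutes, times = days)
  scheduled <- as.POSIXct(start_date, tz = "UTC") + day_off * 86400 + within * 60
  tibble::tibble(
    slot_index = seq_along(scheduled) - 1L,
    scheduled = scheduled
  )
}
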