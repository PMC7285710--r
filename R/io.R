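#' Read and validate a pill-box intake-event log
#'
#' The event log is a CSV with header `patient_id,timestamp,drug_id,pills_taken`,
#' one row per pill-box opening. Timestamps are ISO 8601 local clock times
#' (`YYYY-MM-DDTHH:MM:SS`, a space separator is also accepted, seconds
#' optional) and are treated as timezone-naive. Validation is total: a
#' malformed timestamp, a non-positive pill count, or a missing column raises
#' an error naming the offending data line; nothing is silently coerced.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `patient_id` (character), `timestamp`
#'   (POSIXct), `drug_id` (character), `pills_taken` (integer), sorted by
#'   patient and timestamp; ties keep file order (the earlier record is
#'   matched to a dose slot first downstream).
#' @seealso [write_event_log()], [validate_events()]
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("event log not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("patient_id", "timestamp", "drug_id", "pills_taken")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("event log is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(raw), need)
  if (length(extra)) {
    stop("event log has unknown column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  ts <- parse_iso_timestamp(raw$timestamp)
  bad_ts <- which(is.na(ts))
  if (length(bad_ts)) {
    stop("malformed timestamp at data line ", bad_ts[1], ": '",
         raw$timestamp[bad_ts[1]], "'", call. = FALSE)
  }
  pills <- suppressWarnings(as.integer(raw$pills_taken))
  bad_pill <- which(is.na(pills) | pills < 1L)
  if (length(bad_pill)) {
    stop("invalid pills_taken at data line ", bad_pill[1], ": '",
         raw$pills_taken[bad_pill[1]], "' (a recorded opening must have >= 1 pill)",
         call. = FALSE)
  }
  ev <- tibble::tibble(
    patient_id = raw$patient_id,
    timestamp = ts,
    drug_id = raw$drug_id,
    pills_taken = pills
  )
  validate_events(ev)
}

#' Validate an in-memory event table
#'
#' Applies the same invariants as [read_event_log()] to a tibble of events
#' and returns it sorted per patient by timestamp (stable, so rows that tie
#' on timestamp keep their original order).
#'
#' @param events Tibble with columns `patient_id`, `timestamp`, `drug_id`,
#'   `pills_taken`.
#' @return The validated, per-patient time-sorted tibble.
#' @export
validate_events <- function(events) {
  need <- c("patient_id", "timestamp", "drug_id", "pills_taken")
  missing_cols <- setdiff(need, names(events))
  if (length(missing_cols)) {
    stop("events are missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!inherits(events$timestamp, "POSIXct")) {
    stop("`timestamp` must be POSIXct", call. = FALSE)
  }
  if (anyNA(events$timestamp)) stop("events contain NA timestamps", call. = FALSE)
  if (anyNA(events$pills_taken) || any(events$pills_taken < 1L)) {
    stop("every recorded opening must have pills_taken >= 1", call. = FALSE)
  }
  events |>
    dplyr::mutate(.file_order = dplyr::row_number()) |>
    dplyr::arrange(.data$patient_id, .data$timestamp, .data$.file_order) |>
    dplyr::select(-".file_order") |>
    tibble::as_tibble()
}

#' Write an event log as CSV
#'
#' Inverse of [read_event_log()]: writes `patient_id,timestamp,drug_id,pills_taken`
#' with ISO 8601 timestamps, so that write-then-read reproduces the event
#' table exactly.
#'
#' @param events Validated event tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  out <- events |>
    dplyr::mutate(timestamp = format_iso_timestamp(.data$timestamp)) |>
    dplyr::select("patient_id", "timestamp", "drug_id", "pills_taken")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read cohort metadata
#'
#' CSV `patient_id,arm,start_date` with `arm` one of `intervention`/`control`
#' and `start_date` the first study day (`YYYY-MM-DD`).
#'
#' @param path Path to the CSV file.
#' @return Tibble with `patient_id` (character), `arm` (character),
#'   `start_date` (Date).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("patient_id", "arm", "start_date")
  if (!all(need %in% names(raw))) {
    stop("cohort file must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  bad_arm <- which(!raw$arm %in% c("intervention", "control"))
  if (length(bad_arm)) {
    stop("unknown arm at data line ", bad_arm[1], ": '", raw$arm[bad_arm[1]], "'",
         call. = FALSE)
  }
  sd <- as.Date(raw$start_date, format = "%Y-%m-%d")
  bad_d <- which(is.na(sd))
  if (length(bad_d)) {
    stop("malformed start_date at data line ", bad_d[1], ": '",
         raw$start_date[bad_d[1]], "'", call. = FALSE)
  }
  tibble::tibble(patient_id = raw$patient_id, arm = raw$arm, start_date = sd)
}

#' Read per-visit drug trough levels
#'
#' CSV `patient_id,visit,drug_id,level` with `visit` an integer 1..6
#' (follow-up visits at 4, 8, 12, 16, 20 and 24 weeks) and `level` the
#' pre-dose blood concentration (ng/mL for tacrolimus, ug/mL for
#' mycophenolic acid).
#'
#' @param path Path to the CSV file.
#' @return Tibble with `patient_id`, `visit` (integer), `drug_id`, `level`
#'   (double).
#' @export
read_troughs <- function(path) {
  if (!file.exists(path)) stop("trough file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("patient_id", "visit", "drug_id", "level")
  if (!all(need %in% names(raw))) {
    stop("trough file must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  visit <- suppressWarnings(as.integer(raw$visit))
  bad_v <- which(is.na(visit) | visit < 1L | visit > 6L)
  if (length(bad_v)) {
    stop("visit index outside 1..6 at data line ", bad_v[1], call. = FALSE)
  }
  level <- suppressWarnings(as.numeric(raw$level))
  bad_l <- which(is.na(level) | level < 0)
  if (length(bad_l)) {
    stop("invalid trough level at data line ", bad_l[1], call. = FALSE)
  }
  tibble::tibble(patient_id = raw$patient_id, visit = visit,
                 drug_id = raw$drug_id, level = level)
}

#' Read a YAML configuration file
#'
#' The configuration carries three optional blocks: `schedule` (fields of
#' [rx_schedule()]), `simulation` (fields of [behavior_params()] plus cohort
#' sizes/horizon) and `analysis`. All unset fields take the package defaults,
#' so an empty file yields the standard twice-daily 12-hour schedule with a
#' +/-3 h window, +/-25% interval margin, 30-minute escalation gap and two
#' escalations.
#'
#' @param path Path to a YAML file (may be empty).
#' @return A list with elements `schedule` (an `rx_schedule`), `simulation`
#'   (list) and `analysis` (list).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  sched_args <- raw$schedule %||% list()
  allowed <- names(formals(rx_schedule))
  unknown <- setdiff(names(sched_args), allowed)
  if (length(unknown)) {
    stop("unknown schedule field(s) in config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  schedule <- do.call(rx_schedule, sched_args)
  list(
    schedule = schedule,
    simulation = raw$simulation %||% list(),
    analysis = raw$analysis %||% list()
  )
}

#' Write a trial report
#'
#' Writes a [compare_groups()] / [feedback_subgroup_analysis()] result as a
#' machine-readable JSON file and, alongside it, a human-readable
#' tab-separated table mirroring the rows of a two-arm outcome table
#' (mean +/- SD per group, p-values, event counts). The JSON preserves full
#' double precision so that [read_report()] round-trips bit-exactly.
#'
#' @param result A `trial_result` object.
#' @param path Output JSON path; the TSV is written next to it with a
#'   `.tsv` extension.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "trial_result"))
  if (nrow(result$outcomes) == 0 && nrow(result$events) == 0) {
    stop("no patients: the result contains no outcome rows", call. = FALSE)
  }
  payload <- list(
    groups = result$groups,
    n = as.list(result$n),
    note = "each outcome tested at alpha = 0.05; no multiplicity adjustment",
    outcomes = result$outcomes,
    events = result$events
  )
  # digits = I(17): doubles must survive the round trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  tsv_path <- sub("\\.[A-Za-z0-9]+$", "", path)
  tsv_path <- paste0(tsv_path, ".tsv")
  fmt <- function(m, s) sprintf("%.1f ± %.1f", m, s)
  human <- dplyr::bind_rows(
    result$outcomes |>
      dplyr::transmute(
        outcome = ifelse(is.na(.data$period), .data$outcome,
                         paste0(.data$outcome, " [period ", .data$period, "]")),
        group_1 = fmt(.data$mean_1, .data$sd_1),
        group_2 = fmt(.data$mean_2, .data$sd_2),
        p_value = .data$p_value, method = .data$method),
    result$events |>
      dplyr::transmute(
        outcome = .data$outcome,
        group_1 = sprintf("%d (%.1f%%)", .data$k_1, 100 * .data$k_1 / .data$n_1),
        group_2 = sprintf("%d (%.1f%%)", .data$k_2, 100 * .data$k_2 / .data$n_2),
        p_value = .data$p_value, method = .data$method)
  )
  names(human)[2:3] <- result$groups
  readr::write_tsv(human, tsv_path, progress = FALSE)
  invisible(path)
}

#' Read back a JSON trial report
#'
#' @param path Path written by [write_report()].
#' @return A `trial_result` object equal (bit-exactly in its numeric fields)
#'   to the one written.
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(
    groups = raw$groups,
    n = unlist(raw$n),
    outcomes = tibble::as_tibble(raw$outcomes) |>
      dplyr::mutate(period = as.integer(.data$period),
                    dplyr::across(c("mean_1", "sd_1", "mean_2", "sd_2",
                                    "statistic", "p_value"), as.numeric)),
    events = tibble::as_tibble(raw$events) |>
      dplyr::mutate(p_value = as.numeric(.data$p_value))
  )
  class(out) <- "trial_result"
  out
}

parse_iso_timestamp <- function(x) {
  x2 <- sub("T", " ", x, fixed = TRUE)
  x2 <- ifelse(grepl("^\\d{4}-\\d{2}-\\d{2} \\d{2}:\\d{2}$", x2),
               paste0(x2, ":00"), x2)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2} \\d{2}:\\d{2}:\\d{2}$", x2)
  out <- rep(as.POSIXct(NA_character_, tz = "UTC"), length(x2))
  out[ok] <- as.POSIXct(x2[ok], tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  out
}

format_iso_timestamp <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
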