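#' Intrapatient coefficient of variation of trough levels
#'
#' `CV% = 100 * SD / mean` of a patient's trough-level series, the standard
#' within-patient variability measure for immunosuppressant exposure. The
#' sample (n-1) standard deviation is used throughout, since a trough series
#' is a small sample of visits (typically 6).
#'
#' @param levels Numeric vector of at least two trough levels with a
#'   positive mean.
#' @return CV as a percentage.
#' @examples
#' coefficient_of_variation(c(4, 6))  # 28.28
#' @export
coefficient_of_variation <- function(levels) {
  levels <- as.numeric(levels)
  if (length(levels) < 2L || anyNA(levels)) {
    stop("CV requires at least two non-missing trough levels", call. = FALSE)
  }
  m <- mean(levels)
  if (m <= 0) stop("CV requires a positive mean trough level", call. = FALSE)
  100 * stats::sd(levels) / m
}

#' Two-sample pooled t-test
#'
#' Two-sided Student t-test assuming equal variances (the classical
#' "independent sample t-test"); a Welch option is available for sensitivity
#' analyses.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param var_equal Pool the variances (default `TRUE`).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample must contain at least two values", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stop("degenerate samples: both groups are constant", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    method = if (var_equal) "student_t_pooled" else "welch_t"
  )
}

#' Paired t-test
#'
#' Two-sided paired t-test on the within-subject differences. Identical
#' `before`/`after` vectors are the no-change limit and return `statistic 0,
#' p = 1`; a constant non-zero difference has zero variance and is rejected
#' with an explicit error.
#'
#' @param before,after Numeric vectors of equal length >= 2.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) {
    stop("`before` and `after` must have equal length", call. = FALSE)
  }
  if (length(before) < 2L) stop("need at least two pairs", call. = FALSE)
  d <- after - before
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(statistic = 0, df = length(d) - 1L, p_value = 1,
                            method = "paired_t"))
    }
    stop("degenerate pairs: all differences equal the same non-zero constant, ",
         "so the paired t-statistic is undefined", call. = FALSE)
  }
  tt <- stats::t.test(after, before, paired = TRUE)
  tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    method = "paired_t"
  )
}

#' Compare two event counts (2x2 table)
#'
#' Pearson chi-squared test on the 2x2 table of events vs non-events,
#' falling back to Fisher's exact test when any expected cell count is
#' below 5 (the usual "as appropriate" convention). The method actually
#' used is always reported.
#'
#' @param k_1,n_1 Events and group size in group 1.
#' @param k_2,n_2 Events and group size in group 2.
#' @return One-row tibble: `p_value`, `method` (`"chi_squared"` or
#'   `"fisher_exact"`), `statistic` (NA for Fisher).
#' @export
count_comparison <- function(k_1, n_1, k_2, n_2) {
  counts <- c(k_1, n_1 - k_1, k_2, n_2 - k_2)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers with k <= n", call. = FALSE)
  }
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    tibble::tibble(p_value = ft$p.value, method = "fisher_exact", statistic = NA_real_)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    tibble::tibble(p_value = ct$p.value, method = "chi_squared",
                   statistic = unname(ct$statistic))
  }
}

# Continuous outcome rows for a two-group split.
# values: tibble(patient_id, outcome, period (int or NA), value)
compare_continuous <- function(values, groups_map, group_levels, var_equal = TRUE) {
  values |>
    dplyr::inner_join(groups_map, by = "patient_id") |>
    dplyr::group_by(.data$outcome, .data$period) |>
    dplyr::group_modify(function(df, key) {
      x1 <- df$value[df$group == group_levels[1]]
      x2 <- df$value[df$group == group_levels[2]]
      x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
      row <- tibble::tibble(
        n_1 = length(x1), mean_1 = mean(x1), sd_1 = stats::sd(x1),
        n_2 = length(x2), mean_2 = mean(x2), sd_2 = stats::sd(x2),
        statistic = NA_real_, p_value = NA_real_, method = "not_computable"
      )
      if (length(x1) >= 2 && length(x2) >= 2 &&
          (stats::sd(x1) > 0 || stats::sd(x2) > 0)) {
        tt <- two_sample_t(x1, x2, var_equal = var_equal)
        row$statistic <- tt$statistic
        row$p_value <- tt$p_value
        row$method <- tt$method
      }
      row
    }) |>
    dplyr::ungroup()
}

compare_events <- function(clinical, groups_map, group_levels) {
  ev_cols <- setdiff(names(clinical), "patient_id")
  long <- clinical |>
    tidyr::pivot_longer(dplyr::all_of(ev_cols), names_to = "outcome",
                        values_to = "event") |>
    dplyr::inner_join(groups_map, by = "patient_id")
  long |>
    dplyr::group_by(.data$outcome) |>
    dplyr::group_modify(function(df, key) {
      k1 <- sum(df$event[df$group == group_levels[1]])
      n1 <- sum(df$group == group_levels[1])
      k2 <- sum(df$event[df$group == group_levels[2]])
      n2 <- sum(df$group == group_levels[2])
      if (n1 == 0 || n2 == 0) {
        return(tibble::tibble(k_1 = k1, n_1 = n1, k_2 = k2, n_2 = n2,
                              p_value = NA_real_, method = "not_computable"))
      }
      cc <- count_comparison(k1, n1, k2, n2)
      tibble::tibble(k_1 = k1, n_1 = n1, k_2 = k2, n_2 = n2,
                     p_value = cc$p_value, method = cc$method)
    }) |>
    dplyr::ungroup()
}

# Per-patient per-drug trough summaries: mean level and CV.
trough_outcomes <- function(troughs) {
  troughs |>
    dplyr::group_by(.data$patient_id, .data$drug_id) |>
    dplyr::summarise(
      trough = mean(.data$level),
      cv = if (dplyr::n() >= 2 && mean(.data$level) > 0) {
        coefficient_of_variation(.data$level)
      } else NA_real_,
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(c("trough", "cv"), names_to = "stat", values_to = "value") |>
    dplyr::transmute(.data$patient_id,
                     outcome = paste(.data$drug_id, .data$stat, sep = "_"),
                     period = NA_integer_, .data$value)
}

build_trial_result <- function(groups_map, group_levels, adherence = NULL,
                               troughs = NULL, clinical = NULL, var_equal = TRUE) {
  values <- list()
  if (!is.null(troughs) && nrow(troughs) > 0) {
    values$troughs <- trough_outcomes(troughs)
  }
  if (!is.null(adherence) && nrow(adherence) > 0) {
    values$adherence <- adherence |>
      tidyr::pivot_longer(c("dose_taking", "dose_frequency", "dose_interval",
                            "drug_holidays"),
                          names_to = "outcome", values_to = "value") |>
      dplyr::transmute(.data$patient_id, .data$outcome,
                       period = as.integer(.data$period), .data$value)
  }
  outcomes <- if (length(values)) {
    compare_continuous(dplyr::bind_rows(values), groups_map, group_levels,
                       var_equal = var_equal)
  } else {
    tibble::tibble(outcome = character(), period = integer(),
                   n_1 = integer(), mean_1 = double(), sd_1 = double(),
                   n_2 = integer(), mean_2 = double(), sd_2 = double(),
                   statistic = double(), p_value = double(), method = character())
  }
  events <- if (!is.null(clinical) && ncol(clinical) > 1) {
    compare_events(clinical, groups_map, group_levels)
  } else {
    tibble::tibble(outcome = character(), k_1 = integer(), n_1 = integer(),
                   k_2 = integer(), n_2 = integer(), p_value = double(),
                   method = character())
  }
  n <- c(sum(groups_map$group == group_levels[1]),
         sum(groups_map$group == group_levels[2]))
  names(n) <- group_levels
  structure(list(groups = group_levels, n = n, outcomes = outcomes,
                 events = events),
            class = "trial_result")
}

#' Arm-wise trial comparison
#'
#' Reproduces the reporting structure of a two-arm adherence-trial outcome
#' table: per continuous outcome (drug trough means, trough CVs, and each
#' adherence metric in each follow-up period) the arm means +/- SD and a
#' pooled two-sample t-test p-value; per clinical event a 2x2 count
#' comparison (chi-squared with Fisher fallback). Each patient's drug-level
#' outcomes are the mean (and CV) of that patient's visit series. No
#' multiplicity adjustment is applied; each outcome is tested at alpha =
#' 0.05 and the written report says so.
#'
#' @param cohort Cohort tibble (`patient_id`, `arm`, `start_date`); both
#'   arms must contain at least two patients.
#' @param adherence Optional per-patient x period metric tibble from
#'   [summarize_adherence()].
#' @param troughs Optional trough tibble from [read_troughs()].
#' @param clinical Optional tibble `patient_id` + one logical column per
#'   clinical event.
#' @param var_equal Pool the t-test variances (default `TRUE`).
#' @return A `trial_result` object with tibbles `$outcomes` (continuous
#'   rows: group 1 = intervention, group 2 = control) and `$events`
#'   (count rows); see [tidy.trial_result()].
#' @export
compare_groups <- function(cohort, adherence = NULL, troughs = NULL,
                           clinical = NULL, var_equal = TRUE) {
  stopifnot(all(c("patient_id", "arm") %in% names(cohort)))
  group_levels <- c("intervention", "control")
  n_arm <- table(factor(cohort$arm, levels = group_levels))
  if (any(n_arm == 0)) stop("both arms must be non-empty", call. = FALSE)
  if (any(n_arm < 2)) stop("each arm must contain at least two patients", call. = FALSE)
  groups_map <- tibble::tibble(patient_id = cohort$patient_id, group = cohort$arm)
  build_trial_result(groups_map, group_levels, adherence = adherence,
                     troughs = troughs, clinical = clinical, var_equal = var_equal)
}

#' Feedback-subgroup comparison within the intervention arm
#'
#' Splits the intervention arm at >= 1 deduplicated feedback occurrence
#' (one occurrence per violated slot, escalations not double-counted) and
#' compares the two subgroups on the same outcome rows as [compare_groups()].
#' An empty subgroup does not error: the comparisons are flagged
#' `not_computable` (p-value `NA`).
#'
#' @param cohort Cohort tibble; only `arm == "intervention"` patients enter.
#' @param feedback Feedback tibble from [generate_feedback()] for the
#'   intervention arm.
#' @param adherence,troughs,clinical,var_equal As in [compare_groups()].
#' @return A `trial_result` with groups `c("feedback", "no_feedback")`.
#' @export
feedback_subgroup_analysis <- function(cohort, feedback, adherence = NULL,
                                       troughs = NULL, clinical = NULL,
                                       var_equal = TRUE) {
  iv <- cohort[cohort$arm == "intervention", , drop = FALSE]
  if (nrow(iv) == 0) stop("no intervention patients in cohort", call. = FALSE)
  per_patient <- feedback_counts_per_patient(feedback)
  groups_map <- iv |>
    dplyr::left_join(per_patient, by = "patient_id") |>
    dplyr::mutate(n_feedback = tidyr::replace_na(.data$n_feedback, 0L),
                  group = ifelse(.data$n_feedback >= 1L, "feedback", "no_feedback")) |>
    dplyr::select("patient_id", "group")
  sub <- function(df) if (is.null(df)) NULL else df[df$patient_id %in% iv$patient_id, , drop = FALSE]
  build_trial_result(groups_map, c("feedback", "no_feedback"),
                     adherence = sub(adherence), troughs = sub(troughs),
                     clinical = sub(clinical), var_equal = var_equal)
}

#' Deduplicated feedback occurrences per patient
#'
#' @param feedback Tibble from [generate_feedback()].
#' @return Tibble `patient_id`, `n_feedback` (one per violated slot x kind).
#' @export
feedback_counts_per_patient <- function(feedback) {
  if (is.null(feedback) || nrow(feedback) == 0) {
    return(tibble::tibble(patient_id = character(), n_feedback = integer()))
  }
  feedback |>
    dplyr::distinct(.data$patient_id, .data$slot_index, .data$kind) |>
    dplyr::count(.data$patient_id, name = "n_feedback")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("<trial_result> ", x$groups[1], " (n = ", x$n[1], ") vs ",
      x$groups[2], " (n = ", x$n[2], ")\n", sep = "")
  cat("  ", nrow(x$outcomes), " continuous outcome row(s), ",
      nrow(x$events), " event-count row(s)\n", sep = "")
  if (nrow(x$outcomes)) print(x$outcomes, n = 10)
  if (nrow(x$events)) print(x$events, n = 5)
  invisible(x)
}

#' Tidy a trial result into one long tibble
#'
#' @param x A `trial_result`.
#' @param ... Unused.
#' @return Tibble with one row per comparison (continuous and event rows
#'   combined, `type` column distinguishing them).
#' @method tidy trial_result
#' @export
tidy.trial_result <- function(x, ...) {
  dplyr::bind_rows(
    x$outcomes |> dplyr::mutate(type = "continuous"),
    x$events |> dplyr::mutate(type = "event",
                              period = NA_integer_)
  ) |>
    dplyr::relocate("type", "outcome", "period")
}

#' One-line summary of a trial result
#'
#' @param x A `trial_result`.
#' @param ... Unused.
#' @return One-row tibble: group sizes, number of comparisons, smallest
#'   p-value and how many fall below 0.05.
#' @method glance trial_result
#' @export
glance.trial_result <- function(x, ...) {
  p <- c(x$outcomes$p_value, x$events$p_value)
  tibble::tibble(
    n_1 = unname(x$n[1]), n_2 = unname(x$n[2]),
    n_comparisons = length(p),
    n_computable = sum(!is.na(p)),
    min_p = if (all(is.na(p))) NA_real_ else min(p, na.rm = TRUE),
    n_significant = sum(p < 0.05, na.rm = TRUE)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
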