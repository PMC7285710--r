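#' Per-period adherence by arm
#'
#' The standard per-period adherence figure of a two-arm electronic
#' monitoring trial: arm mean of each of the four metrics at each follow-up
#' period.
#'
#' @param adherence Per-patient x period tibble from [summarize_adherence()].
#' @param cohort Cohort tibble (`patient_id`, `arm`).
#' @return A ggplot object, faceted by metric.
#' @export
plot_adherence_by_period <- function(adherence, cohort) {
  metric_levels <- c("dose_taking", "dose_frequency", "dose_interval", "drug_holidays")
  df <- adherence |>
    dplyr::inner_join(cohort |> dplyr::select("patient_id", "arm"),
                      by = "patient_id") |>
    tidyr::pivot_longer(dplyr::all_of(metric_levels),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = factor(.data$metric, levels = metric_levels)) |>
    dplyr::group_by(.data$arm, .data$metric, .data$period) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = stats::sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period, y = .data$mean,
                                   colour = .data$arm, group = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.15) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Follow-up period (4 weeks each)",
                  y = "Arm mean (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a trial result
#'
#' Group means with SD error bars for every continuous outcome row of a
#' [compare_groups()] / [feedback_subgroup_analysis()] result.
#'
#' @param object A `trial_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trial_result
#' @export
autoplot.trial_result <- function(object, ...) {
  df <- object$outcomes |>
    dplyr::mutate(label = ifelse(is.na(.data$period), .data$outcome,
                                 paste0(.data$outcome, " p", .data$period))) |>
    tidyr::pivot_longer(cols = c("mean_1", "mean_2"), names_to = "which",
                        values_to = "mean") |>
    dplyr::mutate(
      group = ifelse(.data$which == "mean_1", object$groups[1], object$groups[2]),
      sd = ifelse(.data$which == "mean_1", .data$sd_1, .data$sd_2)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$mean,
                                   colour = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2,
                           position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Group mean ± SD", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
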