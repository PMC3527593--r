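#' Plot a fitted training response
#'
#' Two stacked panels in the style of season dose-response figures: the daily
#' modelled output with the measured weekly points, and the daily positive
#' (adaptation) and negative (fatigue) influence series.
#'
#' @param object A `banister_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot banister_fit
#' @export
autoplot.banister_fit <- function(object, ...) {
  daily <- object$daily |>
    tidyr::pivot_longer(c("output", "pi", "ni"),
                        names_to = "series", values_to = "value") |>
    dplyr::mutate(panel = ifelse(.data$series == "output",
                                 "modelled output", "influences"),
                  panel = factor(.data$panel,
                                 levels = c("modelled output", "influences")))
  obs <- dplyr::mutate(object$observations, panel = "modelled output",
                       panel = factor(.data$panel,
                                      levels = levels(daily$panel)))
  ggplot2::ggplot(daily, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$series)) +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(y = .data$value), colour = "black",
                        size = 1) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::scale_colour_manual(
      values = c(output = "steelblue4", pi = "forestgreen", ni = "firebrick")
    ) +
    ggplot2::labs(x = "day of season", y = NULL, colour = NULL,
                  title = sprintf("Two-component fit (R2 = %.2f)", object$r2))
}

#' Plot an RR series
#'
#' Tachogram view of a night: interval length against beat time, with
#' artifact-flagged beats highlighted.
#'
#' @param object An `rr_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rr_series
#' @export
autoplot.rr_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$beat_time_s / 60,
                                       y = .data$rr_ms)) +
    ggplot2::geom_line(colour = "grey40", linewidth = 0.2) +
    ggplot2::geom_point(data = dplyr::filter(object, !.data$valid),
                        colour = "firebrick", size = 0.8) +
    ggplot2::labs(x = "time (min)", y = "RR interval (ms)",
                  title = "Nocturnal RR tachogram")
}

#' Scatter of performance vs HF timing indices across a cohort
#'
#' @param cohort Timing table as from [timing_table()].
#' @return A ggplot object with one panel per index.
#' @export
plot_timing_correlation <- function(cohort) {
  long <- dplyr::bind_rows(
    tibble(index = "t_n (days to recover)",
           performance = cohort$t_n_perf, hf = cohort$t_n_hf),
    tibble(index = "t_g (days to peak)",
           performance = cohort$t_g_perf, hf = cohort$t_g_hf)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$performance, y = .data$hf)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue4") +
    ggplot2::facet_wrap(~index, scales = "free") +
    ggplot2::labs(x = "performance output (days)", y = "HF output (days)")
}
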