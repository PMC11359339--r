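#' Plot observed versus predicted first-flowering days
#'
#' Scatter of a prediction table against the 1:1 line, with the 99%
#' prediction interval drawn as a vertical range per vine.
#'
#' @param object A [predict_with_interval()] result containing observations.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flowering_predictions
#' @export
autoplot.flowering_predictions <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$observed_doy, y = .data$predicted_doy)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                            colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$inside)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Observed first flowering (day of year)",
                  y = "Predicted first flowering (day of year)",
                  colour = "Inside 99% PI") +
    ggplot2::theme_minimal()
}

#' Plot the candidate-model comparison
#'
#' Interval-width ranges and coverage for each candidate in a
#' [evaluate_year_split()] result.
#'
#' @param object A `year_split_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot year_split_eval
#' @export
autoplot.year_split_eval <- function(object, ...) {
  cmp <- object$comparison
  ggplot2::ggplot(cmp, ggplot2::aes(y = stats::reorder(.data$model, -.data$aic))) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$interval_min,
                                         xmax = .data$interval_max),
                            linewidth = 2, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(x = .data$interval_max,
                                     size = .data$coverage_pct),
                        alpha = 0.6) +
    ggplot2::labs(x = "99% prediction-interval width (days)", y = NULL,
                  size = "Coverage (%)") +
    ggplot2::theme_minimal()
}

#' Plot a vine's budbreak observations and fitted curves
#'
#' @param object A [fit_budbreak_curves()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot budbreak_fits
#' @export
autoplot.budbreak_fits <- function(object, ...) {
  sv <- object$survey
  grid <- seq(min(sv$gdd_cum), max(sv$gdd_cum), length.out = 200)
  curves <- purrr::map(c("binomial", "poisson", "polynomial"), function(f) {
    fit <- object[[f]]
    tibble::tibble(family = f, gdd_cum = grid,
                   proportion = predict_budbreak_proportion(fit, grid))
  }) |> purrr::list_rbind()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$gdd_cum)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$proportion,
                                    colour = .data$family)) +
    ggplot2::geom_point(
      data = dplyr::mutate(sv, proportion = .data$broken_buds / .data$total_buds),
      ggplot2::aes(y = .data$proportion)
    ) +
    ggplot2::labs(x = "GDD accumulation (degree-days from 1 July)",
                  y = "Proportion of buds broken", colour = "Family") +
    ggplot2::theme_minimal()
}

#' Plot simulated hourly weather with daily means
#'
#' @param weather Hourly weather tibble.
#' @param by_day Summarise to daily means (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_weather <- function(weather, by_day = TRUE) {
  if (by_day) {
    daily <- weather |>
      dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
      dplyr::summarise(temp_c = mean(.data$temp_c), .by = "date")
    ggplot2::ggplot(daily, ggplot2::aes(x = .data$date, y = .data$temp_c)) +
      ggplot2::geom_line(colour = "steelblue") +
      ggplot2::geom_hline(yintercept = 7, linetype = 2) +
      ggplot2::labs(x = NULL, y = "Daily mean temperature (deg C)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(weather, ggplot2::aes(x = .data$timestamp, y = .data$temp_c)) +
      ggplot2::geom_line(colour = "steelblue", linewidth = 0.2) +
      ggplot2::labs(x = NULL, y = "Hourly temperature (deg C)") +
      ggplot2::theme_minimal()
  }
}
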