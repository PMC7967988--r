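#' Plot detected migration events by date
#'
#' Histogram of departure and arrival days-of-year, the standard phenology
#' view of a tracked population.
#'
#' @param events Events tibble from [detect_events()].
#' @param binwidth Bin width in days.
#' @return A ggplot object.
#' @export
plot_event_phenology <- function(events, binwidth = 3) {
  ggplot2::ggplot(events,
                  ggplot2::aes(x = .data$day_of_year, fill = .data$kind)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6, colour = "grey30") +
    ggplot2::labs(x = "Day of year", y = "Events", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the LASSO cross-validation curve
#'
#' @param object A `lasso_screen`.
#' @param ... Unused.
#' @return A ggplot object: CV error against log lambda with the 1-SE band
#'   and the chosen penalty marked.
#' @export
autoplot.lasso_screen <- function(object, ...) {
  cv <- object$cv
  ggplot2::ggplot(cv, ggplot2::aes(x = log(.data$lambda), y = .data$cvm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cvm - .data$cvsd,
                                      ymax = .data$cvm + .data$cvsd),
                         fill = "grey85") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(object$lambda), linetype = 2) +
    ggplot2::labs(x = "log(lambda)", y = "CV mean squared error") +
    ggplot2::theme_minimal()
}

#' Plot confirmatory-model coefficients
#'
#' @param object A `driver_fit`.
#' @param ... Unused.
#' @return A ggplot object: estimates with approximate 95% intervals,
#'   significant terms highlighted.
#' @export
autoplot.driver_fit <- function(object, ...) {
  co <- object$coefficients
  if (nrow(co) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no predictors selected") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(co, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$estimate),
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std_error,
      xmax = .data$estimate + 1.96 * .data$std_error)) +
    ggplot2::labs(x = "Estimate (days per SD of predictor)", y = NULL,
                  colour = paste0("p < ", object$alpha)) +
    ggplot2::theme_minimal()
}
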