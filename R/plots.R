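#' Bar chart of a benchmark report
#'
#' Fold-averaged MSE per method and environment (error bars = one
#' standard error of the five fold MSEs), faceted by whether the
#' G-by-E interaction entered the predictor.
#'
#' @param object A `benchmark_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot benchmark_report
#' @export
autoplot.benchmark_report <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$env_id, y = .data$mse,
                               fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.85),
                      width = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mse - .data$se, ymax = .data$mse + .data$se),
      position = ggplot2::position_dodge(width = 0.85), width = 0.25) +
    ggplot2::facet_wrap(ggplot2::vars(.data$ge)) +
    ggplot2::labs(x = "environment", y = "mean squared error",
                  fill = "method") +
    ggplot2::theme_minimal()
}

#' Observed-versus-predicted plot for a protocol result
#'
#' Out-of-fold predictions against observed trait values, coloured by
#' environment, with the identity line.
#'
#' @param object A `protocol_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot protocol_result
#' @export
autoplot.protocol_result <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$predicted, y = .data$observed,
                               colour = .data$env_id)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(title = sprintf("out-of-fold predictions (%s)", object$method),
                  x = "predicted", y = "observed", colour = "environment") +
    ggplot2::theme_minimal()
}
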