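#' Fit an ordinary-least-squares calibration line
#'
#' The calibration step regresses *observed* values of a held-out
#' validation slice on the model's *predictions* for that slice:
#' `observed = b0 + b1 * predicted + error`, solved in closed form from
#' the normal equations. Applying the fitted line to test-set
#' predictions removes any affine bias the base model carries, and by
#' the OLS projection property can never increase the squared error on
#' the points it was fitted to.
#'
#' @param observed Numeric vector of observed trait values (length >= 2).
#' @param predicted Numeric vector of the model's predictions for the
#'   same records; must not be constant.
#' @return Object of class `calibration_line`: `intercept` (trait
#'   units), `slope` (dimensionless), `n_points`, `mse_before`,
#'   `mse_after` (validation MSE without / with calibration).
#' @seealso [apply_calibration()], [run_dl_m2()]
#' @export
#' @examples
#' fit_calibration_line(c(1, 2, 3), c(1.1, 1.9, 3.2))
fit_calibration_line <- function(observed, predicted) {
  if (length(observed) != length(predicted)) abort("length mismatch.")
  if (length(observed) < 2L) abort("need at least 2 points to calibrate.")
  if (!all(is.finite(observed)) || !all(is.finite(predicted))) {
    abort("calibration inputs must be finite.")
  }
  sxx <- sum((predicted - mean(predicted))^2)
  if (sxx == 0) {
    abort("constant predictions: calibration slope is undefined.",
          class = "gpcalib_degenerate_calibration")
  }
  slope <- sum((predicted - mean(predicted)) * (observed - mean(observed))) / sxx
  intercept <- mean(observed) - slope * mean(predicted)
  structure(
    list(intercept = intercept, slope = slope,
         n_points = length(observed),
         mse_before = mse(observed, predicted),
         mse_after = mse(observed, intercept + slope * predicted)),
    class = "calibration_line"
  )
}

#' Apply a calibration line to predictions
#'
#' Elementwise `intercept + slope * p`.
#'
#' @param line A `calibration_line` (or any list with `intercept` and
#'   `slope`).
#' @param predictions Numeric vector.
#' @return Calibrated predictions, same length and names.
#' @export
apply_calibration <- function(line, predictions) {
  if (!all(is.finite(predictions))) abort("`predictions` must be finite.")
  line$intercept + line$slope * predictions
}

identity_calibration <- function(n_points = 0L, mse_val = NA_real_) {
  structure(
    list(intercept = 0, slope = 1, n_points = n_points,
         mse_before = mse_val, mse_after = mse_val),
    class = "calibration_line"
  )
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("Calibration line: y_cal = %.4g + %.4g * y_hat  (n = %d)\n",
              x$intercept, x$slope, x$n_points))
  cat(sprintf("  validation MSE %.4g -> %.4g\n", x$mse_before, x$mse_after))
  invisible(x)
}
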