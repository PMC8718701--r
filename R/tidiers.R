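#' Tidy a GBLUP fit
#'
#' One row per parameter: the REML variance components and the
#' per-environment fixed means.
#'
#' @param x A `gblup_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `type`, `estimate`.
#' @method tidy gblup_fit
#' @export
tidy.gblup_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = c("sigma2_g", "sigma2_gL", "sigma2_e"),
                   type = "variance",
                   estimate = c(x$varcomp$sigma2_g, x$varcomp$sigma2_gL,
                                x$varcomp$sigma2_e)),
    tibble::tibble(term = names(x$mu_and_loc), type = "fixed_mean",
                   estimate = unname(x$mu_and_loc))
  )
}

#' Glance at a GBLUP fit
#'
#' @param x A `gblup_fit`.
#' @param ... Unused.
#' @return One-row tibble with the variance components, restricted
#'   log-likelihood, record count and flags.
#' @method glance gblup_fit
#' @export
glance.gblup_fit <- function(x, ...) {
  tibble::tibble(sigma2_g = x$varcomp$sigma2_g,
                 sigma2_gL = x$varcomp$sigma2_gL,
                 sigma2_e = x$varcomp$sigma2_e,
                 reml_loglik = x$reml_loglik,
                 n = x$n, include_ge = x$include_ge,
                 convergence = x$convergence)
}

#' Tidy a calibration line
#'
#' @param x A `calibration_line`.
#' @param ... Unused.
#' @return Tibble with `term` (intercept/slope) and `estimate`.
#' @method tidy calibration_line
#' @export
tidy.calibration_line <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.calibration_line
#' @method glance calibration_line
#' @export
glance.calibration_line <- function(x, ...) {
  tibble::tibble(n_points = x$n_points, mse_before = x$mse_before,
                 mse_after = x$mse_after)
}

#' Tidy a protocol result
#'
#' Fold-by-environment MSE cells (including pooled `"across"` rows).
#'
#' @param x A `protocol_result`.
#' @param ... Unused.
#' @return Tibble `method, ge, fold, env_id, mse`.
#' @method tidy protocol_result
#' @export
tidy.protocol_result <- function(x, ...) {
  fold_env_mse(x) |>
    dplyr::select("method", "ge", "fold", "env_id", "mse")
}

#' @rdname tidy.protocol_result
#' @method glance protocol_result
#' @export
glance.protocol_result <- function(x, ...) {
  tibble::tibble(method = x$method,
                 ge = if (x$include_ge) "GE" else "NO GE",
                 mean_mse = x$mean_mse,
                 n_records = nrow(x$predictions),
                 n_folds = nrow(x$fold_mse))
}

#' Tidy a benchmark report
#'
#' @param x A `benchmark_report`.
#' @param ... Unused.
#' @return The fold-averaged MSE cells tibble.
#' @method tidy benchmark_report
#' @export
tidy.benchmark_report <- function(x, ...) x$cells
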