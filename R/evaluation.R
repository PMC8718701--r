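#' Mean squared error
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return Mean of squared differences.
#' @export
#' @examples
#' mse(c(1, 2, 3), c(2, 2, 2))
mse <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1L) {
    abort("`observed` and `predicted` must have equal length >= 1.")
  }
  mean((observed - predicted)^2)
}

#' Percent change in MSE relative to a baseline
#'
#' `100 * (mse_baseline - mse_method) / mse_baseline`: positive values
#' mean the method improves on the baseline. The baseline (usually the
#' worse model) sits in the denominator; report raw MSEs alongside so
#' any other convention is recomputable.
#'
#' @param mse_baseline,mse_method Positive scalars.
#' @return Percent change (scalar).
#' @export
#' @examples
#' percent_mse_change(2, 1) # 50: the method halves the error
percent_mse_change <- function(mse_baseline, mse_method) {
  if (!is.numeric(mse_baseline) || !is.numeric(mse_method) ||
      mse_baseline <= 0 || mse_method <= 0) {
    abort("both MSEs must be positive.")
  }
  100 * (mse_baseline - mse_method) / mse_baseline
}

# fold-wise MSE cells for one protocol result: one row per fold per
# environment plus pooled "across" rows
fold_env_mse <- function(result) {
  per_env <- result$predictions |>
    dplyr::group_by(.data$fold, .data$env_id) |>
    dplyr::summarise(mse = mse(.data$observed, .data$predicted),
                     .groups = "drop")
  across <- result$predictions |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(mse = mse(.data$observed, .data$predicted),
                     .groups = "drop") |>
    dplyr::mutate(env_id = "across")
  dplyr::bind_rows(per_env, across) |>
    dplyr::mutate(method = result$method,
                  ge = if (result$include_ge) "GE" else "NO GE")
}

#' Assemble a benchmark report from protocol results
#'
#' Averages fold-wise MSEs per environment and pooled across
#' environments (the averaging order is fold-MSE first, then mean over
#' folds — not a pooled-record MSE), attaches standard errors
#' (SD of the fold MSEs / sqrt(k)), and tabulates every ordered
#' pairwise percent change within the same environment and
#' G-by-E setting. All results must come from the same split plan.
#'
#' @param results List of `protocol_result` objects (e.g. from
#'   [run_gblup_cv()], [run_dl_m1()], [run_dl_m2()]).
#' @param config Optional list stored verbatim in the metadata.
#' @return Object of class `benchmark_report`: `cells` (tibble
#'   `method, ge, env_id, mse, se, n_folds`), `percent_change` (tibble
#'   of ordered method pairs with both raw MSEs), `fold_mse` (the
#'   underlying fold-level cells) and `metadata`.
#' @export
build_report <- function(results, config = NULL) {
  stopifnot(length(results) >= 1L,
            all(purrr::map_lgl(results, inherits, "protocol_result")))
  infos <- purrr::map(results, "plan_info")
  if (length(unique(purrr::map_chr(infos, \(i) paste(i, collapse = "/")))) != 1L) {
    abort("all results must share the same split plan.")
  }
  fold_cells <- dplyr::bind_rows(purrr::map(results, fold_env_mse))
  cells <- fold_cells |>
    dplyr::group_by(.data$method, .data$ge, .data$env_id) |>
    dplyr::summarise(se = sd(.data$mse) / sqrt(dplyr::n()),
                     n_folds = dplyr::n(),
                     mse = mean(.data$mse), .groups = "drop") |>
    dplyr::select("method", "ge", "env_id", "mse", "se", "n_folds")

  pairs <- cells |>
    dplyr::rename(mse_baseline = "mse") |>
    dplyr::select("method", "ge", "env_id", "mse_baseline") |>
    dplyr::rename(baseline = "method") |>
    dplyr::inner_join(
      cells |>
        dplyr::select("method", "ge", "env_id", mse_method = "mse"),
      by = c("ge", "env_id"), relationship = "many-to-many") |>
    dplyr::filter(.data$baseline != .data$method) |>
    dplyr::mutate(pct_change = 100 * (.data$mse_baseline - .data$mse_method) /
                    .data$mse_baseline)

  structure(
    list(cells = cells, percent_change = pairs, fold_mse = fold_cells,
         metadata = list(
           config = config,
           methods = purrr::map_chr(results, "method"),
           plan = infos[[1L]],
           package_version = as.character(utils::packageVersion("gpcalib")))),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Benchmark report (fold-averaged MSE, lower is better)\n")
  print(x$cells, n = Inf)
  invisible(x)
}
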