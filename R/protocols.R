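# The three evaluation protocols share record-level outer folds: a line
# held out in one environment typically stays in training through its
# records in other environments, which mirrors the sparse-testing use of
# genomic prediction (predicting lines into environments where they were
# not grown) rather than cross-generation prediction.

#' Build a (nested) cross-validation split plan
#'
#' Records are shuffled by `seed` and dealt into `k` outer folds whose
#' sizes differ by at most one. For each outer fold the remaining
#' training records are split 80/20 into inner-training and validation;
#' with `nested = TRUE` the inner-training set is split 80/20 again into
#' inner-inner-training and inner-validation. On the full data these
#' fractions are 80% training / 20% test, 64% / 16%, and 51.2% / 12.8%.
#' Assignment is record-level and uniform (not stratified by
#' environment).
#'
#' @param pheno Phenotype tibble `(line_id, env_id, value)`.
#' @param k Number of outer folds (>= 2), default 5.
#' @param seed Integer master seed.
#' @param nested Also create the inner-inner split used by the
#'   calibrated protocol?
#' @return Object of class `split_plan`: `k`, `seed`, `nested`, `n`,
#'   and `splits` — a list of `k` entries, each with sorted integer
#'   index vectors `test`, `train`, `inner_train`, `validation` and
#'   (when nested) `inner_inner_train`, `inner_validation`.
#' @export
#' @examples
#' pheno <- tibble::tibble(line_id = rep(letters[1:10], 2),
#'                         env_id = rep(c("E1", "E2"), each = 10),
#'                         value = rnorm(20))
#' lengths(make_split_plan(pheno, k = 5, seed = 1)$splits[[1]])
make_split_plan <- function(pheno, k = 5L, seed = 1L, nested = FALSE) {
  pheno <- validate_phenotypes(pheno)
  n <- nrow(pheno)
  if (!is_count(k, 2L)) abort("`k` must be an integer >= 2.")
  if (k > n) abort("`k` exceeds the number of records.")
  perm <- withr::with_seed(derive_seed(seed, 10L), sample.int(n))
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  splits <- purrr::map(seq_len(k), function(f) {
    test <- sort(perm[starts[f]:ends[f]])
    train <- setdiff(seq_len(n), test)
    tr_perm <- withr::with_seed(derive_seed(seed, 10L + f), sample(train))
    n_val <- round(0.2 * length(train))
    validation <- sort(tr_perm[seq_len(n_val)])
    inner_train <- sort(tr_perm[-seq_len(n_val)])
    out <- list(test = test, train = sort(train),
                inner_train = inner_train, validation = validation)
    if (nested) {
      it_perm <- withr::with_seed(derive_seed(seed, 100L + f),
                                  sample(inner_train))
      n_ival <- round(0.2 * length(inner_train))
      out$inner_validation <- sort(it_perm[seq_len(n_ival)])
      out$inner_inner_train <- sort(it_perm[-seq_len(n_ival)])
    }
    out
  })
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 nested = nested, n = n, splits = splits),
            class = "split_plan")
}

plan_info <- function(plan) list(k = plan$k, seed = plan$seed, n = plan$n)

new_protocol_result <- function(method, include_ge, predictions, plan,
                                chosen = NULL, calibration = NULL,
                                varcomp = NULL, final_train_sizes = NULL) {
  fold_mse <- predictions |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(mse = mse(.data$observed, .data$predicted),
                     .groups = "drop")
  structure(
    list(method = method, include_ge = include_ge,
         predictions = predictions, fold_mse = fold_mse,
         mean_mse = mean(fold_mse$mse),
         chosen = chosen, calibration = calibration, varcomp = varcomp,
         final_train_sizes = final_train_sizes,
         plan_info = plan_info(plan)),
    class = "protocol_result"
  )
}

pred_tibble <- function(pheno, idx, fold, predicted) {
  tibble::tibble(record = idx, fold = fold,
                 line_id = pheno$line_id[idx], env_id = pheno$env_id[idx],
                 observed = pheno$value[idx],
                 predicted = unname(predicted))
}

grid_search <- function(X, y, grid, train_idx, score_idx, learner, seed, fold) {
  scores <- purrr::map_dbl(seq_len(nrow(grid)), function(g) {
    model <- learner(X[train_idx, , drop = FALSE], y[train_idx],
                     grid[g, ], derive_seed(seed, fold * 100L + g))
    mse(y[score_idx], predict(model, X[score_idx, , drop = FALSE]))
  })
  list(best = which.min(scores), scores = scores) # ties: first in grid order
}

#' Conventional deep-learning protocol (DL_M1)
#'
#' For every outer fold: train each of the eight grid configurations on
#' the inner-training records, score them by MSE on the validation
#' records, select the minimiser (ties broken by grid order), refit the
#' winner on the *whole* training set (inner-training + validation,
#' 80% of the data), and predict the test fold. The fold MSEs are
#' averaged for the headline number.
#'
#' @param pheno Phenotype tibble `(line_id, env_id, value)`.
#' @param design `design_set` built from the same records.
#' @param plan `split_plan` from [make_split_plan()].
#' @param seed Master seed for per-fold, per-configuration training
#'   streams; defaults to the plan's seed.
#' @param learner Base learner (default [mlp_learner()]); see
#'   [oracle_learner()] for validation mocks.
#' @param grid Hyperparameter tibble; defaults to
#'   [hyperparameter_grid()] on the concatenated predictor width.
#' @return A `protocol_result` with out-of-fold `predictions`, per-fold
#'   `fold_mse`, chosen hyperparameters (`chosen`), and the refit
#'   training sizes (`final_train_sizes`).
#' @export
run_dl_m1 <- function(pheno, design, plan, seed = plan$seed,
                      learner = mlp_learner(), grid = NULL) {
  pheno <- validate_phenotypes(pheno)
  stopifnot(inherits(plan, "split_plan"), inherits(design, "design_set"))
  X <- design_matrix(design)
  y <- pheno$value
  grid <- grid %||% hyperparameter_grid(ncol(X))

  preds <- list(); chosen <- list(); sizes <- integer(plan$k)
  for (f in seq_len(plan$k)) {
    sp <- plan$splits[[f]]
    gs <- grid_search(X, y, grid, sp$inner_train, sp$validation,
                      learner, seed, f)
    final <- learner(X[sp$train, , drop = FALSE], y[sp$train],
                     grid[gs$best, ], derive_seed(seed, f * 100L))
    preds[[f]] <- pred_tibble(pheno, sp$test, f,
                              predict(final, X[sp$test, , drop = FALSE]))
    chosen[[f]] <- dplyr::mutate(grid[gs$best, ], fold = f,
                                 validation_mse = gs$scores[gs$best],
                                 .before = 1L)
    sizes[f] <- length(sp$train)
  }
  new_protocol_result("dl_m1", design$include_ge,
                      dplyr::bind_rows(preds), plan,
                      chosen = dplyr::bind_rows(chosen),
                      final_train_sizes = sizes)
}

#' Calibrated deep-learning protocol (DL_M2)
#'
#' For every outer fold: grid-search on the inner-inner-training records
#' scored on inner-validation; refit the winning configuration on the
#' inner-training set (51.2% + 12.8% = 64% of the data); predict both
#' the validation slice (16%) and the test fold (20%); fit an OLS
#' [fit_calibration_line()] of observed validation values on their
#' predictions; and report `intercept + slope * prediction` as the
#' calibrated test predictions. If the validation predictions are
#' constant the slope is undefined and the identity line is used with a
#' warning.
#'
#' Note the final model sees strictly less training data than DL_M1's
#' (64% vs 80% of the records); the calibration line is what buys the
#' difference back when the base learner is biased.
#'
#' @inheritParams run_dl_m1
#' @param plan A *nested* `split_plan`
#'   (`make_split_plan(..., nested = TRUE)`).
#' @return A `protocol_result`; `calibration` holds the per-fold
#'   `calibration_line` objects.
#' @export
run_dl_m2 <- function(pheno, design, plan, seed = plan$seed,
                      learner = mlp_learner(), grid = NULL) {
  pheno <- validate_phenotypes(pheno)
  stopifnot(inherits(plan, "split_plan"), inherits(design, "design_set"))
  if (!plan$nested) abort("the calibrated protocol needs a nested split plan.")
  X <- design_matrix(design)
  y <- pheno$value
  grid <- grid %||% hyperparameter_grid(ncol(X))

  preds <- list(); chosen <- list(); calib <- list()
  sizes <- integer(plan$k)
  for (f in seq_len(plan$k)) {
    sp <- plan$splits[[f]]
    gs <- grid_search(X, y, grid, sp$inner_inner_train, sp$inner_validation,
                      learner, seed, f)
    final <- learner(X[sp$inner_train, , drop = FALSE], y[sp$inner_train],
                     grid[gs$best, ], derive_seed(seed, f * 100L))
    pred_val <- predict(final, X[sp$validation, , drop = FALSE])
    pred_test <- predict(final, X[sp$test, , drop = FALSE])
    line <- tryCatch(
      fit_calibration_line(y[sp$validation], pred_val),
      gpcalib_degenerate_calibration = function(e) {
        warn(sprintf("fold %d: constant validation predictions; using the identity line.", f))
        identity_calibration(length(sp$validation),
                             mse(y[sp$validation], pred_val))
      })
    preds[[f]] <- pred_tibble(pheno, sp$test, f,
                              apply_calibration(line, pred_test))
    calib[[f]] <- line
    chosen[[f]] <- dplyr::mutate(grid[gs$best, ], fold = f,
                                 validation_mse = gs$scores[gs$best],
                                 .before = 1L)
    sizes[f] <- length(sp$inner_train)
  }
  new_protocol_result("dl_m2", design$include_ge,
                      dplyr::bind_rows(preds), plan,
                      chosen = dplyr::bind_rows(chosen),
                      calibration = calib, final_train_sizes = sizes)
}

#' GBLUP under the same outer cross-validation
#'
#' For every outer fold the mixed model is REML-fitted on the training
#' records and used to predict the test records. No hyperparameter
#' tuning and no calibration are involved, so only the outer folds of
#' the plan are used.
#'
#' @inheritParams run_dl_m1
#' @param include_ge Fit the G-by-E interaction term? Defaults to the
#'   design's flag.
#' @return A `protocol_result`; `varcomp` holds the per-fold REML
#'   variance-component estimates.
#' @export
run_gblup_cv <- function(pheno, design, plan, include_ge = design$include_ge) {
  pheno <- validate_phenotypes(pheno)
  stopifnot(inherits(plan, "split_plan"), inherits(design, "design_set"))
  preds <- list(); vc <- list()
  for (f in seq_len(plan$k)) {
    sp <- plan$splits[[f]]
    fit <- fit_gblup(pheno[sp$train, ], design_subset(design, sp$train),
                     include_ge = include_ge)
    preds[[f]] <- pred_tibble(pheno, sp$test, f,
                              predict_gblup(fit, design_subset(design, sp$test)))
    vc[[f]] <- tibble::tibble(fold = f,
                              sigma2_g = fit$varcomp$sigma2_g,
                              sigma2_gL = fit$varcomp$sigma2_gL,
                              sigma2_e = fit$varcomp$sigma2_e,
                              reml_loglik = fit$reml_loglik)
  }
  new_protocol_result("gblup", include_ge, dplyr::bind_rows(preds), plan,
                      varcomp = dplyr::bind_rows(vc),
                      final_train_sizes = lengths(purrr::map(plan$splits, "train")))
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("Protocol '%s' (%s): %d records, %d folds\n",
              x$method, if (x$include_ge) "GE" else "NO GE",
              nrow(x$predictions), nrow(x$fold_mse)))
  cat(sprintf("  mean out-of-fold MSE = %.4g\n", x$mean_mse))
  invisible(x)
}
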