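# Base-learner interface used by the cross-validation protocols: a learner
# is `function(X, y, hp, seed)` returning an object with a `predict(model,
# newdata)` method. The network learner is the default; oracle learners
# with a controlled bias support protocol validation and calibration
# experiments, where the behaviour under test is the protocol itself, not
# network training.

#' Network base learner for the benchmark protocols
#'
#' Wraps [train_mlp()] into the learner interface consumed by
#' [run_dl_m1()] and [run_dl_m2()].
#'
#' @param batch_size Minibatch size passed through to [train_mlp()].
#' @return A function `(X, y, hp, seed)` returning an `mlp_model`.
#' @export
mlp_learner <- function(batch_size = 32L) {
  function(X, y, hp, seed) train_mlp(X, y, hp, seed = seed, batch_size = batch_size)
}

#' Synthetic oracle learner with a controlled affine bias
#'
#' A testing utility: a "learner" that ignores the training data and
#' predicts `intercept + slope * values[record] + noise[record]`, where
#' `values` is a supplied per-record target (e.g. the observed
#' phenotypes, or the simulator's true genetic values) keyed by the
#' record rownames that [build_design()] stamps on every design block.
#' With `intercept = 0, slope = 1, noise_sd = 0` it is a perfect
#' predictor; other settings emulate a systematically biased base
#' learner whose error an affine calibration can remove. The optional
#' noise is drawn once per record at construction, so the learner is
#' deterministic.
#'
#' @param values Named numeric vector: per-record prediction targets,
#'   names = record ids (design-matrix rownames).
#' @param intercept,slope Affine distortion applied to `values`.
#' @param noise_sd Standard deviation of per-record Gaussian noise
#'   (default 0).
#' @param seed Seed for the noise draw.
#' @return A learner function `(X, y, hp, seed)` returning an
#'   `oracle_model`.
#' @export
oracle_learner <- function(values, intercept = 0, slope = 1,
                           noise_sd = 0, seed = 1L) {
  if (is.null(names(values))) abort("`values` must be named by record id.")
  noise <- if (noise_sd > 0) {
    withr::with_seed(as.integer(seed),
                     stats::setNames(rnorm(length(values), sd = noise_sd),
                                     names(values)))
  } else {
    stats::setNames(rep(0, length(values)), names(values))
  }
  force(intercept); force(slope)
  function(X, y, hp, seed) {
    structure(
      list(values = values, intercept = intercept, slope = slope,
           noise = noise),
      class = "oracle_model"
    )
  }
}

#' @export
predict.oracle_model <- function(object, newdata, ...) {
  ids <- rownames(newdata)
  if (is.null(ids) || !all(ids %in% names(object$values))) {
    abort("oracle learner requires design rows named by known record ids.")
  }
  drop(object$intercept + object$slope * object$values[ids] + object$noise[ids])
}
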