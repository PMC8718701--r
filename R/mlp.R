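# Dense feed-forward network for continuous traits: ReLU hidden layers of
# one shared width, linear single-unit output, inverted dropout after each
# hidden layer, Adam on minibatch mean-squared error. Written in plain
# matrix ops; the networks used in genomic prediction benchmarks at this
# scale (hundreds of inputs, thousands of records) train in seconds.

#' The fixed eight-point hyperparameter grid
#'
#' Cartesian product of two hidden-layer widths (1.5x and 3x the number
#' of network inputs), two depths (1 and 4 hidden layers) and two
#' dropout rates (0.15 and 0.30), with the learning rate fixed at 0.001
#' and training fixed at 1,000 epochs in every entry. Order is
#' multiplier-major, then depth, then dropout, and is stable across
#' calls — grid-search tie-breaking depends on it.
#'
#' @param n_inputs Number of predictor columns (>= 1); only used to
#'   validate and to document the resulting widths.
#' @return A tibble with 8 rows and columns `units_multiplier`,
#'   `n_hidden_layers`, `dropout`, `learning_rate`, `epochs`,
#'   `hidden_units` (the realised width `round(multiplier * n_inputs)`,
#'   half-up, floored at 1).
#' @export
#' @examples
#' hyperparameter_grid(100)
hyperparameter_grid <- function(n_inputs) {
  if (!is_count(n_inputs, 1L)) abort("`n_inputs` must be an integer >= 1.")
  grid <- tidyr::expand_grid(
    units_multiplier = c(1.5, 3),
    n_hidden_layers = c(1L, 4L),
    dropout = c(0.15, 0.30)
  )
  dplyr::mutate(grid,
                learning_rate = 0.001,
                epochs = 1000L,
                hidden_units = round_half_up(.data$units_multiplier * n_inputs))
}

#' Train a dense feed-forward network
#'
#' Architecture and training follow the package's benchmark protocol:
#' `n_hidden_layers` equal-width ReLU hidden layers of
#' `round(units_multiplier * ncol(X))` units (half-up, floor 1), a
#' single linear output unit, inverted dropout after each hidden layer
#' during training only, Glorot-uniform initialisation, and Adam
#' (`beta1 = 0.9`, `beta2 = 0.999`) minimising minibatch mean squared
#' error for exactly `epochs` epochs. Inputs and response are
#' standardised by training-set means and standard deviations;
#' predictions are returned on the original trait scale. Everything is
#' deterministic given `seed`.
#'
#' @param X Numeric predictor matrix (records x inputs), no missing values.
#' @param y Numeric response vector, `length(y) == nrow(X)`.
#' @param hp One row of [hyperparameter_grid()] (or a list with the same
#'   fields).
#' @param seed Integer seed for initialisation, shuffling and dropout.
#' @param batch_size Minibatch size (default 32; capped at `nrow(X)`).
#' @return Object of class `mlp_model` (weights, standardisation
#'   statistics, architecture, seed).
#' @seealso [predict.mlp_model()], [mlp_learner()]
#' @export
train_mlp <- function(X, y, hp, seed = 1L, batch_size = 32L) {
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X) || !all(is.finite(X))) {
    abort("`X` must be a finite numeric matrix.")
  }
  if (length(y) != nrow(X) || nrow(X) < 2L) {
    abort("`y` must match `nrow(X)` and n must be >= 2.")
  }
  if (!all(is.finite(y))) abort("`y` must be finite.")
  hp <- as.list(hp)
  width <- round_half_up(hp$units_multiplier * ncol(X))
  depth <- as.integer(hp$n_hidden_layers)
  lr <- hp$learning_rate
  stopifnot(width >= 1L, depth >= 1L, lr > 0, hp$epochs >= 1L)

  x_center <- colMeans(X)
  x_scale <- apply(X, 2L, sd)
  x_scale[x_scale == 0 | !is.finite(x_scale)] <- 1
  y_center <- mean(y)
  y_scale <- sd(y)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  Xs <- sweep(sweep(X, 2L, x_center), 2L, x_scale, `/`)
  ys <- (y - y_center) / y_scale

  sizes <- c(ncol(X), rep(width, depth), 1L)
  n <- nrow(Xs)
  bs <- min(batch_size, n)

  model <- withr::with_seed(as.integer(seed), {
    glorot <- function(fin, fout) {
      lim <- sqrt(6 / (fin + fout))
      matrix(runif(fin * fout, -lim, lim), fin, fout)
    }
    W <- purrr::map(seq_len(length(sizes) - 1L),
                    \(l) glorot(sizes[l], sizes[l + 1L]))
    b <- purrr::map(seq_len(length(sizes) - 1L), \(l) rep(0, sizes[l + 1L]))
    mW <- purrr::map(W, \(w) w * 0); vW <- mW
    mb <- purrr::map(b, \(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0L
    nl <- length(W)

    for (epoch in seq_len(hp$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        a <- Xs[idx, , drop = FALSE]
        acts <- vector("list", nl + 1L); acts[[1L]] <- a
        masks <- vector("list", nl)
        for (l in seq_len(nl)) {
          z <- sweep(acts[[l]] %*% W[[l]], 2L, b[[l]], `+`)
          if (l < nl) {
            z <- pmax(z, 0)
            if (hp$dropout > 0) {
              keep <- matrix(runif(length(z)) >= hp$dropout,
                             nrow(z), ncol(z)) / (1 - hp$dropout)
              z <- z * keep
              masks[[l]] <- keep
            }
          }
          acts[[l + 1L]] <- z
        }
        # d(MSE)/d(output)
        delta <- 2 * (acts[[nl + 1L]] - ys[idx]) / length(idx)
        t_step <- t_step + 1L
        for (l in rev(seq_len(nl))) {
          gW <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- delta %*% t(W[[l]])
            if (!is.null(masks[[l - 1L]])) delta <- delta * masks[[l - 1L]]
            delta <- delta * (acts[[l]] > 0)
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
          W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
          b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
        }
      }
    }
    list(W = W, b = b)
  })

  structure(
    list(W = model$W, b = model$b, sizes = sizes,
         x_center = x_center, x_scale = x_scale,
         y_center = y_center, y_scale = y_scale,
         hp = hp, seed = as.integer(seed), batch_size = bs),
    class = "mlp_model"
  )
}

#' Predict from a trained network
#'
#' Forward pass with dropout disabled; output is de-standardised back to
#' the trait scale.
#'
#' @param object An `mlp_model`.
#' @param newdata Numeric matrix with the training input width (a single
#'   row is accepted).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$sizes[1L]) {
    abort(sprintf("`newdata` has %d columns; the network expects %d.",
                  ncol(X), object$sizes[1L]))
  }
  a <- sweep(sweep(X, 2L, object$x_center), 2L, object$x_scale, `/`)
  nl <- length(object$W)
  for (l in seq_len(nl)) {
    a <- sweep(a %*% object$W[[l]], 2L, object$b[[l]], `+`)
    if (l < nl) a <- pmax(a, 0)
  }
  drop(a) * object$y_scale + object$y_center
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("Feed-forward network: %s (ReLU hidden, linear output)\n",
              paste(x$sizes, collapse = "-")))
  cat(sprintf("  dropout %.2f, lr %g, %d epochs, batch %d, seed %d\n",
              x$hp$dropout, x$hp$learning_rate, x$hp$epochs,
              x$batch_size, x$seed))
  invisible(x)
}
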