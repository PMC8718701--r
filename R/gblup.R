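# REML machinery for the ridge form of the G-by-E GBLUP:
#   y = XE beta + XG u + XGE w + e,  u ~ N(0, s2_g I), w ~ N(0, s2_gL I)
# which induces Var(g) = s2_g G and Var(gL) = s2_gL (I (x) G) on the
# original line / line-by-environment effects.

# restricted log-likelihood profiled over sigma2_e, at variance ratios
# lambda = (s2_g, s2_gL) / s2_e. Kg = XG XG', KgL = XGE XGE'.
reml_profile <- function(lambda_g, lambda_gl, y, X, Kg, KgL) {
  n <- length(y)
  p <- ncol(X)
  H <- diag(n) + lambda_g * Kg
  if (!is.null(KgL) && lambda_gl > 0) H <- H + lambda_gl * KgL
  R <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Hi_X <- backsolve(R, forwardsolve(t(R), X))
  Hi_y <- backsolve(R, forwardsolve(t(R), y))
  XtHiX <- crossprod(X, Hi_X)
  XtHiy <- crossprod(X, Hi_y)
  B <- tryCatch(chol(XtHiX), error = function(e) NULL)
  if (is.null(B)) return(NULL)
  beta <- backsolve(B, forwardsolve(t(B), XtHiy))
  yPy <- drop(crossprod(y, Hi_y) - crossprod(XtHiy, beta))
  if (yPy <= 0) return(NULL)
  sigma2 <- yPy / (n - p)
  ll <- -0.5 * ((n - p) * (log(sigma2) + 1) +
                  2 * sum(log(diag(R))) + 2 * sum(log(diag(B))))
  list(loglik = ll, beta = drop(beta), sigma2_e = sigma2,
       Hi_resid = drop(Hi_y - Hi_X %*% beta))
}

#' Fit the GBLUP mixed model with optional G-by-E interaction
#'
#' Fits `Y_ij = mu + Loc_i + g_j + gL_ij + e_ij` by REML on the
#' equivalent ridge parameterisation: fixed environment cell means
#' (full-rank one-hot, no separate global intercept), random `XG`
#' coefficients `u ~ N(0, sigma2_g I)` and, when `include_ge = TRUE`,
#' random `XGE` coefficients `w ~ N(0, sigma2_gL I)`. Because `XG`
#' carries the Cholesky factor of `G`, this induces exactly
#' `g ~ N(0, sigma2_g G)` and `gL ~ N(0, sigma2_gL (I (x) G))`.
#'
#' Variance ratios are optimised on the log scale (Brent's method for
#' one ratio, Nelder-Mead for two; convergence tolerance `1e-8`, at most
#' 500 iterations), with each ratio floored at `1e-10` so the
#' mixed-model equations stay solvable; BLUPs and GLS fixed effects are
#' recovered at the optimum. The fit is fully deterministic.
#'
#' @param pheno Training phenotype tibble `(line_id, env_id, value)`.
#' @param design `design_set` built from the same records (same row order).
#' @param include_ge Fit the interaction variance? Defaults to the
#'   design's `include_ge` (requires the `XGE` block when `TRUE`).
#' @param fixed_lambda Optional named numeric `c(g = , gl = )` of fixed
#'   variance ratios `sigma2_g/sigma2_e` (and `sigma2_gL/sigma2_e`),
#'   skipping REML optimisation — mainly for validation against
#'   closed-form ridge solutions.
#' @return Object of class `gblup_fit`: `mu_and_loc` (named
#'   per-environment fixed means), `u_blup`, `w_blup` (`NULL` without
#'   interaction), `varcomp` (list `sigma2_e`, `sigma2_g`, `sigma2_gL`),
#'   `include_ge`, `reml_loglik`, `lambda`, plus bookkeeping
#'   (`env_ids`, `line_ids`, `n`, `convergence`).
#' @seealso [predict_gblup()], [tidy.gblup_fit()]
#' @export
fit_gblup <- function(pheno, design, include_ge = design$include_ge,
                      fixed_lambda = NULL) {
  pheno <- validate_phenotypes(pheno)
  stopifnot(inherits(design, "design_set"))
  if (nrow(pheno) != design$n_records) {
    abort("`pheno` and `design` describe different record sets.")
  }
  if (nrow(pheno) < 2L) abort("need at least 2 records to fit.")
  if (include_ge && is.null(design$XGE)) {
    abort("`include_ge = TRUE` but the design has no XGE block.")
  }
  y <- pheno$value
  X <- design$XE
  seen <- colSums(X) > 0
  if (!all(seen)) X <- X[, seen, drop = FALSE]
  Kg <- tcrossprod(design$XG)
  # Khatri-Rao identity: XGE XGE' = (XE XE') . (XG XG') elementwise
  KgL <- if (include_ge) tcrossprod(design$XE) * Kg else NULL

  floor_l <- 1e-10
  if (is.null(fixed_lambda)) {
    if (include_ge) {
      obj <- function(par) {
        r <- reml_profile(exp(par[1]), exp(par[2]), y, X, Kg, KgL)
        if (is.null(r)) 1e10 else -r$loglik
      }
      opt <- optim(c(0, 0), obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-8, maxit = 500))
      lambda <- pmax(exp(opt$par), floor_l)
      convergence <- opt$convergence
    } else {
      obj <- function(lg) {
        r <- reml_profile(exp(lg), 0, y, X, Kg, NULL)
        if (is.null(r)) 1e10 else -r$loglik
      }
      opt <- optimize(obj, interval = log(c(1e-8, 1e8)), tol = 1e-8)
      lambda <- c(max(exp(opt$minimum), floor_l), 0)
      convergence <- 0L
    }
  } else {
    lambda <- c(max(fixed_lambda[["g"]], floor_l),
                if (include_ge) max(fixed_lambda[["gl"]], floor_l) else 0)
    convergence <- 0L
  }

  fit <- reml_profile(lambda[1], if (include_ge) lambda[2] else 0, y, X, Kg, KgL)
  if (is.null(fit)) abort("mixed-model solve failed at the selected variance ratios.")

  # BLUP coefficients: u_hat = lambda_g XG' H^{-1} (y - X beta_hat)
  u <- lambda[1] * drop(crossprod(design$XG, fit$Hi_resid))
  w <- if (include_ge) lambda[2] * drop(crossprod(design$XGE, fit$Hi_resid)) else NULL

  mu_and_loc <- stats::setNames(rep(NA_real_, length(design$env_ids)),
                                design$env_ids)
  mu_and_loc[colnames(X)] <- fit$beta

  structure(
    list(mu_and_loc = mu_and_loc,
         u_blup = stats::setNames(u, colnames(design$XG)),
         w_blup = if (include_ge) stats::setNames(w, colnames(design$XGE)),
         varcomp = list(sigma2_e = fit$sigma2_e,
                        sigma2_g = lambda[1] * fit$sigma2_e,
                        sigma2_gL = if (include_ge) lambda[2] * fit$sigma2_e else 0),
         include_ge = include_ge, reml_loglik = fit$loglik,
         lambda = lambda, env_ids = design$env_ids,
         line_ids = design$line_ids, n = length(y),
         convergence = convergence),
    class = "gblup_fit"
  )
}

#' Predict phenotypes from a fitted GBLUP
#'
#' `y_hat = XE beta + XG u + XGE w`. Lines never observed in training
#' are still predicted through the genomic correlation carried by the
#' Cholesky-transformed `XG`/`XGE` blocks; an environment that had no
#' training records falls back to a zero fixed mean.
#'
#' @param fit A `gblup_fit`.
#' @param design_test `design_set` for the records to predict, built
#'   with the same Cholesky factor and environment ordering as the
#'   training design (e.g. via [design_subset()]).
#' @return Numeric vector of predictions, one per test record, named by
#'   record rownames.
#' @export
predict_gblup <- function(fit, design_test) {
  stopifnot(inherits(fit, "gblup_fit"), inherits(design_test, "design_set"))
  if (!identical(colnames(design_test$XG), names(fit$u_blup))) {
    abort("test design lines do not match the fitted coefficients.")
  }
  if (!identical(design_test$env_ids, fit$env_ids)) {
    abort("test design environments do not match the fit.")
  }
  beta <- ifelse(is.na(fit$mu_and_loc), 0, fit$mu_and_loc)
  yhat <- drop(design_test$XE %*% beta + design_test$XG %*% fit$u_blup)
  if (fit$include_ge) {
    if (is.null(design_test$XGE)) abort("fit includes G-by-E but test design has no XGE.")
    yhat <- yhat + drop(design_test$XGE %*% fit$w_blup)
  }
  stats::setNames(yhat, rownames(design_test$XE))
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("GBLUP fit (REML)\n")
  cat(sprintf("  records: %d, environments: %d, lines: %d, G-by-E: %s\n",
              x$n, length(x$env_ids), length(x$line_ids), x$include_ge))
  cat(sprintf("  sigma2_g = %.4g, sigma2_gL = %.4g, sigma2_e = %.4g\n",
              x$varcomp$sigma2_g, x$varcomp$sigma2_gL, x$varcomp$sigma2_e))
  cat(sprintf("  restricted log-likelihood = %.4f\n", x$reml_loglik))
  invisible(x)
}
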