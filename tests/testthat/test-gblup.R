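test_that("pure-noise data drives the genetic variance and BLUPs toward zero", {
  tt <- tiny_trial(n_lines = 250, n_markers = 150, n_env = 2, seed = 21,
                   include_ge = FALSE)
  pheno <- tt$pheno
  pheno$value <- withr::with_seed(99, rnorm(nrow(pheno))) # no signal at all
  fit <- fit_gblup(pheno, tt$design, include_ge = FALSE)
  expect_lt(fit$varcomp$sigma2_g, 0.1)
  expect_lt(max(abs(fit$u_blup)), 0.1 * sd(pheno$value))
})

test_that("with fixed variance ratios the BLUPs equal the closed-form ridge solution", {
  tt <- tiny_trial(n_lines = 4, n_markers = 25, n_env = 3, seed = 22,
                   include_ge = FALSE) # 12 records
  lambda_g <- 0.8
  fit <- fit_gblup(tt$pheno, tt$design, include_ge = FALSE,
                   fixed_lambda = c(g = lambda_g))
  oracle <- dense_mme(tt$pheno$value, tt$design$XE, tt$design$XG, lambda_g)
  expect_equal(unname(fit$u_blup), unname(oracle$u), tolerance = 1e-8)
  expect_equal(unname(fit$mu_and_loc), unname(oracle$beta), tolerance = 1e-8)
  # second MME block row: u = (XG'XG + I/lambda)^{-1} XG' (y - XE beta)
  resid <- tt$pheno$value - drop(tt$design$XE %*% oracle$beta)
  ridge_u <- solve(crossprod(tt$design$XG) + diag(1 / lambda_g, 4),
                   crossprod(tt$design$XG, resid))
  expect_equal(unname(fit$u_blup), unname(drop(ridge_u)), tolerance = 1e-8)
})

test_that("G-by-E predictions match a dense mixed-model-equation solve", {
  tt <- tiny_trial(n_lines = 3, n_markers = 20, n_env = 2, seed = 23) # 6 records
  fit <- fit_gblup(tt$pheno, tt$design, fixed_lambda = c(g = 1.2, gl = 0.6))
  oracle <- dense_mme(tt$pheno$value, tt$design$XE, tt$design$XG, 1.2,
                      tt$design$XGE, 0.6)
  expect_equal(unname(fit$u_blup), unname(oracle$u), tolerance = 1e-8)
  expect_equal(unname(fit$w_blup), unname(oracle$w), tolerance = 1e-8)
  preds <- predict_gblup(fit, tt$design)
  expect_equal(unname(preds), oracle$fitted, tolerance = 1e-8)
})

test_that("the REML optimum dominates randomly perturbed variance ratios", {
  tt <- tiny_trial(n_lines = 30, n_markers = 60, n_env = 2, seed = 24)
  fit <- fit_gblup(tt$pheno, tt$design)
  perturbed <- withr::with_seed(7, {
    purrr::map_dbl(1:20, function(i) {
      lam <- fit$lambda * exp(rnorm(2, sd = 0.5))
      fit_gblup(tt$pheno, tt$design,
                fixed_lambda = c(g = lam[1], gl = lam[2]))$reml_loglik
    })
  })
  expect_true(all(fit$reml_loglik >= perturbed - 1e-6))
})

test_that("with G = I and no interaction, GBLUP equals ridge regression on line incidence", {
  # an identity relationship factor makes XG the raw incidence matrix,
  # so the model is plain ridge with penalty sigma2_e / sigma2_g
  pheno <- balanced_pheno(20, 2)
  pheno$value <- withr::with_seed(31, rnorm(40, sd = 2))
  L <- diag(20); dimnames(L) <- list(unique(pheno$line_id), unique(pheno$line_id))
  d <- build_design(pheno, L, include_ge = FALSE)
  fit <- fit_gblup(pheno, d, include_ge = FALSE)
  lambda_hat <- fit$varcomp$sigma2_g / fit$varcomp$sigma2_e
  oracle <- dense_mme(pheno$value, d$XE, d$XG, lambda_hat)
  expect_equal(unname(fit$u_blup), unname(oracle$u), tolerance = 1e-6)
  expect_equal(unname(predict_gblup(fit, d)), oracle$fitted, tolerance = 1e-6)
})

test_that("predictions are equivariant to test-record permutation", {
  tt <- tiny_trial(n_lines = 15, n_markers = 40, n_env = 2, seed = 26)
  fit <- fit_gblup(tt$pheno, tt$design)
  idx <- seq_len(10)
  p1 <- predict_gblup(fit, design_subset(tt$design, idx))
  p2 <- predict_gblup(fit, design_subset(tt$design, rev(idx)))
  expect_equal(unname(p1), unname(rev(p2)))
})

test_that("variance-component recovery sharpens as the panel grows", {
  rmse_at <- function(n_lines, seeds) {
    errs <- purrr::map_dbl(seeds, function(s) {
      tt <- tiny_trial(n_lines = n_lines, n_markers = 150, n_env = 2,
                       seed = s, ge_ratio = 0, include_ge = FALSE)
      fit <- fit_gblup(tt$pheno, tt$design, include_ge = FALSE)
      fit$varcomp$sigma2_g - 1 # h2 = 0.5, residual_var = 1 -> sigma2_g = 1
    })
    sqrt(mean(errs^2))
  }
  expect_lt(rmse_at(240, 1:10), rmse_at(60, 1:10))
})

test_that("degenerate inputs are rejected", {
  tt <- tiny_trial(n_lines = 5, n_markers = 20, n_env = 2, seed = 27)
  bad <- tt$pheno
  bad$value[1] <- Inf
  expect_error(fit_gblup(bad, tt$design), "finite")
  expect_error(fit_gblup(tt$pheno[1:5, ], tt$design), "different record")
  d0 <- build_design(tt$pheno, tt$grm$chol_factor, include_ge = FALSE)
  expect_error(fit_gblup(tt$pheno, d0, include_ge = TRUE), "XGE")
})
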