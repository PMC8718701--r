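# Shared fixture builders: everything is generated in code at test time.

# simulate a trial and precompute kinship + design in one call
tiny_trial <- function(n_lines = 40, n_markers = 120, n_env = 3, seed = 1,
                       h2 = 0.5, ge_ratio = 0.5, residual_var = 1,
                       include_ge = TRUE, env_means = NULL) {
  cfg <- sim_config(n_lines = n_lines, n_markers = n_markers, n_env = n_env,
                    h2 = h2, ge_ratio = ge_ratio,
                    residual_var = residual_var, env_means = env_means,
                    seed = seed)
  markers <- simulate_markers(cfg)
  trial <- simulate_trial(markers, cfg)
  # small panels occasionally fix a marker; the drop warning is routine here
  grm <- stabilized_cholesky(suppressWarnings(vanraden_relationship(markers)))
  design <- build_design(trial$phenotypes, grm$chol_factor,
                         include_ge = include_ge)
  list(cfg = cfg, markers = markers, pheno = trial$phenotypes,
       truth = trial$truth, grm = grm, design = design)
}

# per-record values named by record id, as oracle_learner() expects
record_values <- function(x) {
  stats::setNames(x, as.character(seq_along(x)))
}

# expected phenotype per record (mu + env mean + true genetic value):
# the "signal" a well-specified learner would recover
expected_values <- function(pheno, truth) {
  tgv <- truth$true_genetic_values
  env_idx <- match(pheno$env_id, colnames(tgv))
  record_values(truth$mu + truth$env_means[env_idx] +
                  tgv[cbind(match(pheno$line_id, rownames(tgv)), env_idx)])
}

# balanced phenotype grid without simulation (for pure-structure tests)
balanced_pheno <- function(n_lines, n_env, values = NULL) {
  line_ids <- sprintf("L%03d", seq_len(n_lines))
  env_ids <- paste0("E", seq_len(n_env))
  tibble::tibble(
    line_id = rep(line_ids, times = n_env),
    env_id = rep(env_ids, each = n_lines),
    value = values %||% seq_len(n_lines * n_env) / 10
  )
}

`%||%` <- rlang::`%||%`

# dense mixed-model-equation solve: independent oracle for GBLUP BLUPs.
# penalties are sigma2_e / sigma2_g etc. on the ridge coefficients.
dense_mme <- function(y, X, Zg, lambda_g, Zw = NULL, lambda_gl = NULL) {
  blocks <- list(X, Zg)
  pen <- c(rep(0, ncol(X)), rep(1 / lambda_g, ncol(Zg)))
  if (!is.null(Zw)) {
    blocks <- c(blocks, list(Zw))
    pen <- c(pen, rep(1 / lambda_gl, ncol(Zw)))
  }
  M <- do.call(cbind, blocks)
  C <- crossprod(M) + diag(pen)
  sol <- solve(C, crossprod(M, y))
  list(beta = unname(sol[seq_len(ncol(X))]),
       u = unname(sol[ncol(X) + seq_len(ncol(Zg))]),
       w = if (!is.null(Zw)) unname(sol[ncol(X) + ncol(Zg) + seq_len(ncol(Zw))]),
       fitted = unname(drop(M %*% sol)))
}
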