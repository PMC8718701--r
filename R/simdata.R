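#' Configuration for the synthetic multi-environment trial simulator
#'
#' Bundles and validates every knob of the simulator. The defaults describe
#' a balanced trial of the size and signal typical of the crop-breeding
#' panels the package is aimed at: a few hundred inbred lines genotyped at
#' ~1,000 biallelic SNPs and phenotyped once per line in each of a handful
#' of environments, with additive marker effects, environment main effects,
#' genomically correlated genotype-by-environment (G-by-E) deviations and
#' Gaussian residual noise.
#'
#' @param n_lines Number of lines (>= 2).
#' @param n_markers Number of biallelic markers (>= 1).
#' @param n_env Number of environments (>= 1).
#' @param maf_range Length-2 numeric, lower/upper bound of the per-marker
#'   minor-allele frequency, each in `(0, 0.5]`.
#' @param h2 Target narrow-sense heritability in `(0, 1)`: the share of
#'   phenotypic variance (within environment, at `ge_ratio = 0`) explained
#'   by the additive genetic values.
#' @param ge_ratio Ratio of the G-by-E variance to the main genetic
#'   variance, `sigma2_gL / sigma2_g` (>= 0). `0` switches interaction off.
#' @param env_means Optional numeric vector of environment main effects
#'   (trait units). Defaults to equally spaced values centred at 0 with
#'   unit spacing, e.g. `c(-1, 0, 1)` for three environments.
#' @param residual_var Residual variance `sigma2_e` (> 0), trait units squared.
#' @param seed Integer seed; the same config reproduces bit-identical data.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' sim_config(n_lines = 50, n_markers = 100, n_env = 3, seed = 1)
sim_config <- function(n_lines = 300, n_markers = 1000, n_env = 3,
                       maf_range = c(0.05, 0.5), h2 = 0.5, ge_ratio = 0.5,
                       env_means = NULL, residual_var = 1, seed = 1) {
  if (!is_count(n_lines, 2L)) abort("`n_lines` must be an integer >= 2.")
  if (!is_count(n_markers, 1L)) abort("`n_markers` must be an integer >= 1.")
  if (!is_count(n_env, 1L)) abort("`n_env` must be an integer >= 1.")
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    abort("`maf_range` must be ordered bounds within (0, 0.5].")
  }
  if (!is.numeric(h2) || length(h2) != 1L || h2 <= 0 || h2 >= 1) {
    abort("`h2` must be a single value in (0, 1).")
  }
  if (!is.numeric(ge_ratio) || length(ge_ratio) != 1L || ge_ratio < 0) {
    abort("`ge_ratio` must be a single value >= 0.")
  }
  if (!is.numeric(residual_var) || length(residual_var) != 1L || residual_var < 0) {
    abort("`residual_var` must be a single value >= 0.")
  }
  if (is.null(env_means)) {
    env_means <- seq_len(n_env) - (n_env + 1) / 2
  }
  if (length(env_means) != n_env || !all(is.finite(env_means))) {
    abort("`env_means` must be a finite vector of length `n_env`.")
  }
  structure(
    list(n_lines = as.integer(n_lines), n_markers = as.integer(n_markers),
         n_env = as.integer(n_env), maf_range = as.numeric(maf_range),
         h2 = h2, ge_ratio = ge_ratio, env_means = as.numeric(env_means),
         residual_var = residual_var, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a marker matrix under Hardy-Weinberg equilibrium
#'
#' Draws one allele frequency per marker uniformly from `maf_range`, then
#' samples each genotype independently as `Binomial(2, p)` allele counts
#' (coded 0/1/2). Markers are unlinked: no linkage disequilibrium is
#' simulated.
#'
#' @param config A [sim_config()].
#' @return A tibble with a `line_id` character column followed by one
#'   integer column per marker (`M1`, `M2`, ...), entries in `{0, 1, 2}`.
#' @export
#' @examples
#' simulate_markers(sim_config(n_lines = 5, n_markers = 4, seed = 1))
simulate_markers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  geno <- withr::with_seed(derive_seed(config$seed, 1L), {
    p <- runif(config$n_markers, config$maf_range[1], config$maf_range[2])
    matrix(rbinom(config$n_lines * config$n_markers, 2L,
                  rep(p, each = config$n_lines)),
           nrow = config$n_lines, ncol = config$n_markers)
  })
  colnames(geno) <- paste0("M", seq_len(config$n_markers))
  dplyr::bind_cols(
    tibble::tibble(line_id = sprintf("L%03d", seq_len(config$n_lines))),
    tibble::as_tibble(geno)
  )
}

#' Simulate a balanced multi-environment trial from genotypes
#'
#' Generates one phenotype record per line per environment under the
#' additive model `Y_ij = mu + Loc_i + g_j + gL_ij + e_ij`. The main
#' genetic values are `g_j = sum_k W_jk beta_k` with `W` the
#' column-centred genotype matrix and `beta` i.i.d. normal marker effects
#' rescaled so the *realised* variance of `g` equals
#' `sigma2_g = h2 * residual_var / (1 - h2)` — i.e. the heritability
#' target holds exactly in each simulated data set when `ge_ratio = 0`.
#' G-by-E deviations use independent per-environment marker effects
#' rescaled the same way to `sigma2_gL = ge_ratio * sigma2_g`, which gives
#' deviations genomically correlated across lines within an environment
#' and independent across environments (the `I (x) G` Kronecker structure
#' of the GBLUP interaction term). Residuals are
#' `Normal(0, residual_var)`.
#'
#' @param markers Marker tibble from [simulate_markers()] (or the same
#'   shape), consistent with `config`.
#' @param config The [sim_config()] used to generate `markers`.
#' @return A list with elements
#'   * `phenotypes`: tibble `(line_id, env_id, value)` with exactly
#'     `n_lines * n_env` rows, environment-major order;
#'   * `truth`: list of class `sim_truth` holding `marker_effects`
#'     (main-effect vector on centred genotypes), `true_genetic_values`
#'     (lines x environments matrix of `g_j + gL_ij`), `env_means`, `mu`,
#'     and the realised variance components `sigma2_g`, `sigma2_gL`
#'     (averaged over environments) and `sigma2_e`.
#' @export
#' @examples
#' cfg <- sim_config(n_lines = 20, n_markers = 50, n_env = 2, seed = 7)
#' trial <- simulate_trial(simulate_markers(cfg), cfg)
#' head(trial$phenotypes)
simulate_trial <- function(markers, config) {
  stopifnot(inherits(config, "sim_config"))
  mm <- validate_markers(markers)
  if (nrow(mm$genotypes) != config$n_lines ||
      ncol(mm$genotypes) != config$n_markers) {
    abort("`markers` dimensions do not match `config`.")
  }
  W <- scale(mm$genotypes, center = TRUE, scale = FALSE)
  sigma2_g <- config$h2 * config$residual_var / (1 - config$h2)
  sigma2_gL <- config$ge_ratio * sigma2_g

  out <- withr::with_seed(derive_seed(config$seed, 2L), {
    g_raw <- drop(W %*% rnorm(config$n_markers))
    v <- mean(g_raw^2) # variance about the (zero) column-centred mean
    sc <- if (v > 0) sqrt(sigma2_g / v) else 0
    g <- g_raw * sc

    gL <- matrix(0, config$n_lines, config$n_env)
    if (sigma2_gL > 0) {
      for (i in seq_len(config$n_env)) {
        d_raw <- drop(W %*% rnorm(config$n_markers))
        vd <- mean(d_raw^2)
        gL[, i] <- if (vd > 0) d_raw * sqrt(sigma2_gL / vd) else 0
      }
    }
    eps <- matrix(rnorm(config$n_lines * config$n_env,
                        sd = sqrt(config$residual_var)),
                  config$n_lines, config$n_env)
    list(g = g, sc = sc, gL = gL, eps = eps)
  })
  # marker effects on the centred-genotype scale (same draw, same scaling)
  marker_effects <- withr::with_seed(derive_seed(config$seed, 2L),
                                     rnorm(config$n_markers)) * out$sc

  mu <- 0
  tgv <- out$g + out$gL # lines x env
  dimnames(tgv) <- list(mm$line_ids, paste0("E", seq_len(config$n_env)))
  y <- sweep(tgv + out$eps, 2L, mu + config$env_means, `+`)

  phenotypes <- tibble::tibble(
    line_id = rep(mm$line_ids, times = config$n_env),
    env_id = rep(colnames(tgv), each = config$n_lines),
    value = as.vector(y)
  )
  truth <- structure(
    list(marker_effects = marker_effects,
         true_genetic_values = tgv,
         env_means = config$env_means, mu = mu,
         sigma2_g = mean(out$g^2),
         sigma2_gL = mean(colMeans(out$gL^2)),
         sigma2_e = mean(out$eps^2)),
    class = "sim_truth"
  )
  list(phenotypes = phenotypes, truth = truth)
}
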