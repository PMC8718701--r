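#' Build the environment / genotype / interaction predictor blocks
#'
#' Constructs the three concatenated predictor blocks shared by the
#' neural-network models and the ridge formulation of GBLUP:
#'
#' * `XE` — records x environments full one-hot incidence (no reference
#'   level dropped; the downstream models carry their own intercepts).
#' * `XG` — records x lines genotype block: the line incidence matrix
#'   post-multiplied by the Cholesky factor `L` of the genomic
#'   relationship matrix, so that `XG XG' = Z (G + jitter I) Z'` and a
#'   ridge penalty on the `XG` coefficients induces the genomic
#'   covariance `sigma2_g G` on the line effects.
#' * `XGE` — records x (environments x lines) interaction block: the
#'   column-wise Khatri-Rao (row-wise Kronecker) product of `XE` and
#'   `XG`, ordered environment-major, whose cross-product reproduces the
#'   Kronecker covariance `I (x) G` of the G-by-E term.
#'
#' Row `r` of every block corresponds to record `r` of `pheno`; rownames
#' carry the record index so that subsetting by fold keeps provenance.
#'
#' @param pheno Phenotype tibble `(line_id, env_id, value)`.
#' @param chol_factor Lower-triangular factor `L` with line ids as
#'   rownames, from [stabilized_cholesky()].
#' @param include_ge Build the `XGE` interaction block? (default `TRUE`).
#' @param env_ids Optional fixed environment ordering; defaults to first
#'   appearance order in `pheno`.
#' @return An object of class `design_set`: list with `XE`, `XG`, `XGE`
#'   (`NULL` when `include_ge = FALSE`), `env_ids`, `line_ids`,
#'   `include_ge`, `n_records`.
#' @export
#' @examples
#' pheno <- tibble::tibble(line_id = rep(c("a", "b"), 2),
#'                         env_id = rep(c("E1", "E2"), each = 2),
#'                         value = rnorm(4))
#' L <- diag(2)
#' dimnames(L) <- list(c("a", "b"), c("a", "b"))
#' dim(build_design(pheno, L)$XGE)
build_design <- function(pheno, chol_factor, include_ge = TRUE,
                         env_ids = NULL) {
  pheno <- validate_phenotypes(pheno)
  if (nrow(pheno) == 0L) abort("`pheno` has no records.")
  L <- as.matrix(chol_factor)
  if (is.null(rownames(L))) abort("`chol_factor` must have line ids as rownames.")
  unknown <- setdiff(unique(pheno$line_id), rownames(L))
  if (length(unknown)) {
    abort(sprintf("line id(s) not present in the relationship factor: %s",
                  paste(head(unknown, 5L), collapse = ", ")))
  }
  env_ids <- env_ids %||% unique(pheno$env_id)
  if (!all(pheno$env_id %in% env_ids)) abort("`env_ids` does not cover `pheno`.")
  line_ids <- rownames(L)

  XE <- incidence_matrix(pheno$env_id, env_ids)
  XG <- L[match(pheno$line_id, line_ids), , drop = FALSE]
  colnames(XG) <- line_ids
  rn <- as.character(seq_len(nrow(pheno)))
  rownames(XE) <- rownames(XG) <- rn

  XGE <- NULL
  if (include_ge) {
    # environment-major Khatri-Rao: column (i, j) = XE[, i] * XG[, j]
    XGE <- matrix(0, nrow(pheno), length(env_ids) * length(line_ids))
    for (i in seq_along(env_ids)) {
      cols <- (i - 1L) * length(line_ids) + seq_along(line_ids)
      XGE[, cols] <- XE[, i] * XG
    }
    dimnames(XGE) <- list(rn, as.vector(outer(line_ids, env_ids,
                                              function(l, e) paste(e, l, sep = ":"))))
  }
  structure(
    list(XE = XE, XG = XG, XGE = XGE, env_ids = env_ids,
         line_ids = line_ids, include_ge = include_ge,
         n_records = nrow(pheno)),
    class = "design_set"
  )
}

#' Subset a design set by record rows
#'
#' Keeps all columns (so coefficients stay conformable across folds) and
#' the original record rownames.
#'
#' @param design A `design_set`.
#' @param idx Integer record indices.
#' @return A `design_set` restricted to the selected records.
#' @export
design_subset <- function(design, idx) {
  stopifnot(inherits(design, "design_set"))
  design$XE <- design$XE[idx, , drop = FALSE]
  design$XG <- design$XG[idx, , drop = FALSE]
  if (!is.null(design$XGE)) design$XGE <- design$XGE[idx, , drop = FALSE]
  design$n_records <- length(idx)
  design
}

#' Concatenate the blocks of a design set into one predictor matrix
#'
#' Column order is `(XE, XG, XGE)`, matching the concatenated predictor
#' fed to the neural networks.
#'
#' @param design A `design_set`.
#' @return A numeric matrix with record rownames.
#' @export
design_matrix <- function(design) {
  stopifnot(inherits(design, "design_set"))
  cbind(design$XE, design$XG, design$XGE)
}
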