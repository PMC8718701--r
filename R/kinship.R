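#' Validate a marker tibble and unpack it
#'
#' Internal: checks the `line_id` + integer-marker-columns layout, the
#' 0/1/2 coding and id uniqueness, and returns the genotype matrix with
#' per-marker allele frequencies (column mean / 2).
#'
#' @noRd
validate_markers <- function(markers) {
  if (!is.data.frame(markers) || ncol(markers) < 2L) {
    abort("`markers` must be a data frame with `line_id` plus marker columns.")
  }
  if (nrow(markers) == 0L) abort("`markers` contains no lines.")
  line_ids <- as.character(markers[[1L]])
  if (anyDuplicated(line_ids)) abort("duplicate line ids in `markers`.")
  geno <- as.matrix(markers[, -1L, drop = FALSE])
  if (!is.numeric(geno)) abort("marker columns must be numeric 0/1/2.")
  bad <- which(!(geno %in% c(0, 1, 2)) | is.na(geno))
  if (length(bad)) {
    r <- ((bad[1L] - 1L) %% nrow(geno)) + 1L
    c_ <- ((bad[1L] - 1L) %/% nrow(geno)) + 1L
    abort(sprintf(
      "invalid genotype at line '%s', marker '%s': values must be 0, 1 or 2.",
      line_ids[r], colnames(geno)[c_]))
  }
  rownames(geno) <- line_ids
  list(line_ids = line_ids, genotypes = geno, allele_freqs = colMeans(geno) / 2)
}

#' VanRaden genomic relationship matrix
#'
#' Computes `G = W W' / (2 * sum_k p_k (1 - p_k))` where `W` is the
#' genotype matrix (allele counts 0/1/2) column-centred by twice the
#' allele frequency, and `p_k` is estimated from the sample
#' (column mean / 2) unless supplied. Monomorphic markers (`p_k` of 0
#' or 1) contribute nothing to either the numerator or the denominator
#' and are dropped with a warning; an all-monomorphic panel is an error
#' because the denominator would be zero.
#'
#' @param markers Marker tibble: `line_id` column followed by 0/1/2
#'   marker columns (the layout produced by [simulate_markers()] and
#'   [read_markers()]).
#' @param allele_freqs Optional externally estimated per-marker allele
#'   frequencies; defaults to the sample estimate.
#' @return An object of class `genomic_relationship`: list with `G`
#'   (lines x lines, dimnames = line ids), `chol_factor` (`NULL` until
#'   [stabilized_cholesky()] is applied), `jitter` (`NA` until then),
#'   `line_ids`, `n_markers_used`, and `denominator`.
#' @seealso [stabilized_cholesky()]
#' @export
#' @examples
#' m <- tibble::tibble(line_id = c("a", "b", "c"),
#'                     M1 = c(0, 2, 1), M2 = c(2, 0, 1))
#' vanraden_relationship(m)$G
vanraden_relationship <- function(markers, allele_freqs = NULL) {
  mm <- validate_markers(markers)
  p <- allele_freqs %||% mm$allele_freqs
  if (length(p) != ncol(mm$genotypes)) {
    abort("`allele_freqs` length must match the number of markers.")
  }
  poly <- p > 0 & p < 1
  if (!any(poly)) {
    abort("all markers are monomorphic: VanRaden denominator is zero.")
  }
  if (!all(poly)) {
    warn(sprintf("dropping %d monomorphic marker(s) from G.", sum(!poly)))
  }
  geno <- mm$genotypes[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(geno, 2L, 2 * p, `-`)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2 # enforce exact symmetry
  dimnames(G) <- list(mm$line_ids, mm$line_ids)
  structure(
    list(G = G, chol_factor = NULL, jitter = NA_real_,
         line_ids = mm$line_ids, n_markers_used = ncol(geno),
         denominator = denom),
    class = "genomic_relationship"
  )
}

#' Cholesky factor with automatic jitter escalation
#'
#' A realised genomic relationship matrix built from finitely many
#' markers is often rank-deficient (and always is after centring, since
#' the rows of `W` sum to zero across lines), so a plain Cholesky
#' factorisation can fail. This helper returns a lower-triangular `L`
#' with `L L' = G + jitter * I`, where `jitter` is the smallest value in
#' the escalation schedule `{0, base_jitter, 10 * base_jitter, ...}`
#' (at most 8 escalations) for which the factorisation succeeds.
#'
#' @param G Symmetric numeric matrix, or a `genomic_relationship` object
#'   (in which case the updated object is returned with `chol_factor`
#'   and `jitter` filled in).
#' @param base_jitter First nonzero jitter tried (default `1e-8`).
#' @return For a matrix input, a list with `L` (lower triangular) and
#'   `jitter`; for a `genomic_relationship`, the object updated in place.
#' @export
#' @examples
#' stabilized_cholesky(diag(3))$jitter # 0: already positive definite
stabilized_cholesky <- function(G, base_jitter = 1e-8) {
  if (inherits(G, "genomic_relationship")) {
    res <- stabilized_cholesky(G$G, base_jitter)
    G$chol_factor <- res$L
    G$jitter <- res$jitter
    return(G)
  }
  if (!is.matrix(G) || nrow(G) != ncol(G)) abort("`G` must be square.")
  if (max(abs(G - t(G))) > 1e-8 * max(1, max(abs(G)))) {
    abort("`G` must be symmetric.")
  }
  n <- nrow(G)
  jitters <- c(0, base_jitter * 10^(0:7))
  for (j in jitters) {
    R <- tryCatch(chol(G + diag(j, n)), error = function(e) NULL)
    if (!is.null(R)) {
      L <- t(R)
      dimnames(L) <- dimnames(G)
      return(list(L = L, jitter = j))
    }
  }
  abort("Cholesky factorisation failed after 8 jitter escalations.")
}
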