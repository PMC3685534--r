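#' Sample-space principal component analysis
#'
#' Features are mean-centered (no unit-variance scaling by default: log2
#' ratios already share a scale); scores come from the SVD of the centered
#' sample-by-feature matrix. Variance-explained fractions are squared
#' singular values over the total variance. Sign convention: each loading
#' vector is flipped so its coordinate sum is nonnegative, making the
#' orientation deterministic across platforms.
#'
#' @param m [omics_matrix()] or matrix (features x samples); must be
#'   complete (impute first).
#' @param n_components number of components (default all).
#' @param scale. also scale features to unit variance.
#' @return list of class `pca_result`: `scores` (samples x components),
#'   `loadings` (features x components), `var_explained`, `center`.
#' @export
pca_samples <- function(m, n_components = NULL, scale. = FALSE) {
  vals <- if (inherits(m, "omics_matrix")) m$values else m
  if (anyNA(vals)) stop("matrix has missing values; impute before PCA")
  X <- t(vals)                      # samples x features
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  if (scale.) {
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0)) stop("zero-variance feature with scale. = TRUE")
    Xc <- sweep(Xc, 2L, sds, "/")
  }
  total <- sum(Xc^2)
  if (total == 0) stop("constant matrix: no variance to decompose")
  kmax <- min(dim(Xc))
  if (is.null(n_components)) n_components <- kmax
  if (n_components > kmax) stop("n_components exceeds min(features, samples)")
  sv <- svd(Xc, nu = kmax, nv = kmax)
  flip <- ifelse(colSums(sv$v) < 0, -1, 1)
  v <- sweep(sv$v, 2L, flip, "*")
  u <- sweep(sv$u, 2L, flip, "*")
  scores <- u %*% diag(sv$d, kmax, kmax)
  k <- seq_len(n_components)
  dimnames(scores) <- list(rownames(X), sprintf("PC%d", seq_len(kmax)))
  dimnames(v) <- list(colnames(X), sprintf("PC%d", seq_len(kmax)))
  structure(list(scores = scores[, k, drop = FALSE],
                 loadings = v[, k, drop = FALSE],
                 var_explained = (sv$d^2 / total)[k],
                 center = ctr),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples,",
      ncol(x$scores), "components\n")
  cat("variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$var_explained), collapse = " "), "\n")
  invisible(x)
}
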