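#' Principal component analysis of a spectral dataset
#'
#' Mean-centered singular value decomposition of the intensity matrix.
#' Explained-variance fractions are per-component variances divided by the
#' total variance. The sign of each loading is fixed so that its
#' largest-magnitude entry is positive, making results reproducible
#' bit-for-bit.
#'
#' @param d A [spectral_dataset()].
#' @param n_components Number of components to retain; defaults to the full
#'   rank bound min(n_scans - 1, n_points).
#' @return An object of class `pca_model`: mean_spectrum, loadings
#'   (n_components x n_points, orthonormal rows), explained_var_frac,
#'   scores (training scores, n_scans x n_components), grid, n_fit.
#' @export
fit_pca <- function(d, n_components = NULL) {
  X <- d$intensity
  n <- nrow(X)
  if (n < 2L) stop("PCA needs at least 2 scans")
  max_comp <- min(n - 1L, ncol(X))
  if (is.null(n_components)) n_components <- max_comp
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > max_comp)
    stop(sprintf("n_components must lie in [1, %d] for this dataset", max_comp))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0, nv = max_comp)
  total_var <- sum(sv$d^2)
  if (total_var == 0)
    stop("dataset has zero variance (all scans equal the mean spectrum)")
  evf <- (sv$d[seq_len(max_comp)]^2) / total_var
  loadings <- t(sv$v)[seq_len(n_components), , drop = FALSE]
  # deterministic sign: largest-magnitude entry of each loading positive
  for (i in seq_len(n_components)) {
    j <- which.max(abs(loadings[i, ]))
    if (loadings[i, j] < 0) loadings[i, ] <- -loadings[i, ]
  }
  scores <- Xc %*% t(loadings)
  structure(list(mean_spectrum = mu, loadings = loadings,
                 explained_var_frac = evf[seq_len(n_components)],
                 scores = scores, grid = d$grid, n_fit = n),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA model: %d components fit on %d scans (%d points)\n",
              nrow(x$loadings), x$n_fit, ncol(x$loadings)))
  cat(sprintf("  cumulative variance explained: %.2f%%\n",
              100 * sum(x$explained_var_frac)))
  invisible(x)
}

#' Project spectra into PC-score space
#'
#' Scores are the inner products of the first k loadings with the
#' mean-centered input.
#'
#' @param m A `pca_model`.
#' @param x Numeric vector on the model grid, or a matrix with one spectrum
#'   per row.
#' @param k Number of leading components to use (default: all retained).
#' @return A score vector of length k (or an n x k matrix for matrix input).
#' @export
pca_project <- function(m, x, k = nrow(m$loadings)) {
  k <- as.integer(k)
  if (k < 1L || k > nrow(m$loadings))
    stop("k must lie between 1 and the number of retained components")
  if (is.matrix(x)) {
    if (ncol(x) != length(m$mean_spectrum))
      stop("spectrum length does not match the model grid")
    return(sweep(x, 2L, m$mean_spectrum) %*% t(m$loadings[seq_len(k), , drop = FALSE]))
  }
  if (length(x) != length(m$mean_spectrum))
    stop("spectrum length does not match the model grid")
  drop(m$loadings[seq_len(k), , drop = FALSE] %*% (x - m$mean_spectrum))
}
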