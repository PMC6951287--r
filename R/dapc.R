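# Discriminant analysis of principal components: linear discriminant
# classification in the space of the first k PC scores, with a pooled
# (equal) within-class covariance, uniform class priors by default, and a
# tolerance-based pseudo-inverse so rank-deficient covariances (inevitable
# when k approaches the training-fold rank) degrade rather than error.

# symmetric pseudo-inverse; tolerance = dim * eps * largest eigenvalue
sym_pinv <- function(S) {
  ee <- eigen((S + t(S)) / 2, symmetric = TRUE)
  tol <- nrow(S) * .Machine$double.eps * max(ee$values, 0)
  inv_vals <- ifelse(ee$values > tol, 1 / ee$values, 0)
  ee$vectors %*% (inv_vals * t(ee$vectors))
}

#' Fit a DAPC model
#'
#' Fits a PCA to the dataset, retains the first k PC scores, and computes
#' the linear discriminant statistics in score space: per-class score
#' means, the pooled within-class covariance (pseudo-inverted with an
#' eigenvalue tolerance), and class priors (uniform by default). Classes
#' are ordered alphabetically; that order is also the tie-break rule at
#' classification time.
#'
#' @param d A [spectral_dataset()] with >= 2 classes, each with >= 2 scans.
#' @param k Number of retained principal components.
#' @param priors "uniform" (default) or "proportional" to class sizes.
#' @return An object of class `dapc_model`: pca, k, classes, class_means
#'   (g x k), pooled_cov, pooled_cov_inv, priors, plus training scores and
#'   labels.
#' @export
fit_dapc <- function(d, k, priors = c("uniform", "proportional")) {
  priors <- match.arg(priors)
  assert_classes_for_fit(d)
  labels <- d$meta$class_label
  classes <- sort(unique(labels))
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L))
    stop("every class needs >= 2 scans to fit DAPC; offending class(es): ",
         paste(classes[counts < 2L], collapse = ", "))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  max_comp <- min(nrow(d$intensity) - 1L, ncol(d$intensity))
  if (k > max_comp)
    stop(sprintf("k = %d exceeds the %d components available", k, max_comp))
  pca <- fit_pca(d, n_components = k)
  S <- pca$scores
  g <- length(classes)
  class_means <- matrix(0, g, k, dimnames = list(classes, NULL))
  Sw <- matrix(0, k, k)
  for (i in seq_len(g)) {
    rows <- which(labels == classes[i])
    class_means[i, ] <- colMeans(S[rows, , drop = FALSE])
    dev <- sweep(S[rows, , drop = FALSE], 2L, class_means[i, ])
    Sw <- Sw + crossprod(dev)
  }
  pooled_cov <- Sw / (nrow(S) - g)
  pr <- if (priors == "uniform") rep(1 / g, g) else as.numeric(counts) / nrow(S)
  names(pr) <- classes
  structure(list(pca = pca, k = k, classes = classes,
                 class_means = class_means, pooled_cov = pooled_cov,
                 pooled_cov_inv = sym_pinv(pooled_cov), priors = pr,
                 scores = S, labels = labels),
            class = "dapc_model")
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf("DAPC model: %d PCs, classes %s, %s priors\n", x$k,
              paste(x$classes, collapse = "/"),
              if (stats::var(x$priors) == 0) "uniform" else "proportional"))
  invisible(x)
}

# linear discriminant scores for one score vector s (length k)
discriminant_scores <- function(m, s) {
  W <- m$pooled_cov_inv
  delta <- vapply(seq_along(m$classes), function(i) {
    mu <- m$class_means[i, ]
    sum(s * (W %*% mu)) - 0.5 * sum(mu * (W %*% mu)) + log(m$priors[i])
  }, numeric(1))
  names(delta) <- m$classes
  delta
}

#' Classify a spectrum with a DAPC model
#'
#' Projects the spectrum onto the model's k retained PCs and evaluates the
#' linear discriminant score of each class,
#' delta_c = s' W mu_c - (1/2) mu_c' W mu_c + log prior_c,
#' where W is the pseudo-inverse of the pooled within-class covariance.
#' The predicted label is the argmax; exact ties go to the class earliest
#' in the model's (alphabetical) class order.
#'
#' @param m A `dapc_model`.
#' @param x Numeric spectrum vector on the model grid.
#' @return A list with `label` (predicted class) and `scores` (named
#'   per-class discriminant scores).
#' @export
dapc_classify <- function(m, x) {
  s <- pca_project(m$pca, x, m$k)
  delta <- discriminant_scores(m, s)
  list(label = m$classes[which.max(delta)], scores = delta)
}

#' Predict class labels for every scan in a dataset
#'
#' @param m A `dapc_model`.
#' @param d A [spectral_dataset()] on the model grid.
#' @return Character vector of predicted labels, one per scan.
#' @export
dapc_predict <- function(m, d) {
  if (length(d$grid) != length(m$pca$mean_spectrum))
    stop("dataset grid does not match the model grid")
  S <- pca_project(m$pca, d$intensity, m$k)
  unname(apply(S, 1L,
               function(s) m$classes[which.max(discriminant_scores(m, s))]))
}

#' Canonical discriminant coordinates and per-scan predictions
#'
#' Computes the canonical (linear discriminant) axes as eigenvectors of
#' W B, where W is the pseudo-inverse of the pooled within-class
#' covariance and B the between-class scatter of the class score means;
#' with g classes at most g - 1 axes are non-trivial, so a 2-class model
#' yields one axis and the second coordinate is zero. Each scan of the
#' dataset gets its first two canonical coordinates, its predicted label,
#' and a correctness flag — the quantities needed for DAPC cluster plots.
#'
#' @param m A `dapc_model`.
#' @param d A [spectral_dataset()] on the model grid.
#' @return An object of class `score_table` whose `table` element is a
#'   data.frame with one row per scan: specimen_id, true_label,
#'   predicted_label, correct, ld1, ld2.
#' @export
canonical_scores <- function(m, d) {
  if (length(d$grid) != length(m$pca$mean_spectrum))
    stop("dataset grid does not match the model grid")
  g <- length(m$classes)
  counts <- table(factor(m$labels, levels = m$classes))
  grand <- colSums(m$class_means * as.numeric(counts)) / sum(counts)
  B <- matrix(0, m$k, m$k)
  for (i in seq_len(g)) {
    dev <- m$class_means[i, ] - grand
    B <- B + as.numeric(counts[i]) * tcrossprod(dev)
  }
  ee <- eigen(m$pooled_cov_inv %*% B)
  ord <- order(Re(ee$values), decreasing = TRUE)
  n_axes <- min(g - 1L, m$k)
  axes <- Re(ee$vectors[, ord[seq_len(n_axes)], drop = FALSE])
  for (j in seq_len(n_axes)) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  S <- pca_project(m$pca, d$intensity, m$k)
  coords <- sweep(S, 2L, grand) %*% axes
  predicted <- dapc_predict(m, d)
  tab <- data.frame(specimen_id = d$meta$specimen_id,
                    true_label = d$meta$class_label,
                    predicted_label = predicted,
                    correct = predicted == d$meta$class_label,
                    ld1 = coords[, 1L],
                    ld2 = if (n_axes >= 2L) coords[, 2L] else 0,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, axes = axes, n_axes = n_axes),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("DAPC score table: %d spectra, %d canonical axis/axes, %.1f%% correct\n",
              nrow(x$table), x$n_axes, 100 * mean(x$table$correct)))
  invisible(x)
}
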