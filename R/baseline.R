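# Iterative asymmetric polynomial baseline estimation in the Goldindec
# family: a low-order polynomial is refit under a truncated asymmetric
# quadratic cost so that peaks (points far above the running fit) stop
# pulling the fit upward, while points at or below the fit always count in
# full. The truncation threshold is taken each iteration as the
# (1 - peak_ratio) quantile of the residuals (floored at zero), so roughly
# the configured fraction of points is treated as potential peak signal.

# orthogonal polynomial design matrix on a [-1, 1]-scaled grid
poly_design <- function(w, order) {
  t <- if (diff(range(w)) > 0) 2 * (w - min(w)) / diff(range(w)) - 1 else w * 0
  if (order == 0L) return(matrix(1, length(w), 1L))
  cbind(1, stats::poly(t, degree = order, raw = FALSE))
}

weighted_polyfit <- function(X, y, wt) {
  fit <- stats::lm.wfit(X, y, wt)
  drop(X %*% ifelse(is.na(fit$coefficients), 0, fit$coefficients))
}

#' Estimate and subtract a polynomial baseline (Goldindec-style)
#'
#' Fits a polynomial of degree `cfg$poly_order` to the spectrum by an
#' iterative asymmetric scheme: starting from the ordinary least-squares
#' fit, points whose residual exceeds the (1 - `peak_ratio`) residual
#' quantile are dropped from the next weighted refit (truncated cost),
#' while points below the fit always retain full weight. Iteration stops
#' when the baseline changes by less than `cfg$tol` (relative) or the
#' active point set reaches a fixed point or limit cycle; exceeding
#' `cfg$max_iter` is an error. On peak-free polynomial input the result
#' equals the least-squares fit. A copy smoothed with `cfg$smooth_window`
#' is used only to decide which points count as peak signal (it
#' stabilizes that decision under noise); the polynomial itself is always
#' fitted to, and subtracted from, the raw intensities.
#'
#' @param s A [raman_spectrum()], already truncated to the analysis window.
#' @param cfg A [preprocess_config()] supplying poly_order, peak_ratio,
#'   smooth_window, max_iter and tol.
#' @return A list with `baseline` (numeric vector over the grid),
#'   `corrected` (the baseline-subtracted `raman_spectrum`) and
#'   `iterations` (count used).
#' @export
goldindec_baseline <- function(s, cfg = preprocess_config()) {
  n <- length(s$wavenumbers)
  if (cfg$poly_order >= n)
    stop("poly_order must be smaller than the number of grid points")
  y <- s$intensities
  ysm <- moving_average(y, cfg$smooth_window)
  X <- poly_design(s$wavenumbers, cfg$poly_order)
  wt <- rep(1, n)
  b_prev <- NULL
  seen <- character(0)
  converged <- FALSE
  last_change <- NA_real_
  for (iter in seq_len(cfg$max_iter)) {
    b <- weighted_polyfit(X, y, wt)
    if (!is.null(b_prev)) {
      last_change <- max(abs(b - b_prev)) / max(max(abs(b)), 1e-300)
      if (last_change < cfg$tol) { converged <- TRUE; break }
    }
    r <- ysm - b
    thr <- max(stats::quantile(r, 1 - cfg$peak_ratio, names = FALSE), 0)
    active <- r <= thr
    key <- paste(which(active), collapse = ",")
    if (key %in% seen) { converged <- TRUE; break }  # fixed point or cycle
    seen <- c(seen, key)
    wt <- as.numeric(active)
    b_prev <- b
  }
  if (!converged)
    stop(sprintf(paste0("baseline fit did not converge in %d iterations ",
                        "(last relative change %.3g)"),
                 cfg$max_iter, last_change))
  corrected <- s
  corrected$intensities <- s$intensities - b
  list(baseline = b, corrected = corrected, iterations = iter)
}
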