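#' Preprocessing configuration
#'
#' Parameters of the four-step spectral processing chain: truncation to a
#' Raman shift window, polynomial baseline correction with an asymmetric
#' iterative fit, vector normalization, and replicate averaging. Defaults
#' follow common practice for liquid-sample Raman chemometrics: 400-1800
#' cm^-1 window, cubic baseline, estimated peak ratio 0.5, smoothing window
#' 5 (applied only to the working copy used for baseline estimation).
#'
#' @param trunc_low,trunc_high Truncation window in cm^-1 (closed interval).
#' @param poly_order Baseline polynomial order (>= 0).
#' @param peak_ratio Estimated fraction of grid points occupied by peaks,
#'   in (0, 1); sets the asymmetric-cost threshold of the baseline fit.
#' @param smooth_window Odd moving-average window used inside baseline
#'   estimation to decide which points count as peak signal (not applied
#'   to the corrected output).
#' @param normalize Whether to vector-normalize each corrected scan.
#' @param average_by Replicate averaging unit: "specimen", "individual" or
#'   "none".
#' @param renormalize_after_average Re-normalize averaged spectra to unit
#'   norm (default FALSE: averaging unit vectors yields norm <= 1, and the
#'   processing order normalize-then-average is kept as stated).
#' @param max_iter Baseline iteration cap.
#' @param tol Baseline convergence tolerance (relative change).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(trunc_low = 400, trunc_high = 1800,
                              poly_order = 3, peak_ratio = 0.5,
                              smooth_window = 5, normalize = TRUE,
                              average_by = c("specimen", "individual", "none"),
                              renormalize_after_average = FALSE,
                              max_iter = 200L, tol = 1e-6) {
  average_by <- match.arg(average_by)
  if (!(trunc_low < trunc_high)) stop("trunc_low must be < trunc_high")
  poly_order <- as.integer(poly_order)
  if (poly_order < 0L) stop("poly_order must be >= 0")
  if (!(peak_ratio > 0 && peak_ratio < 1))
    stop("peak_ratio must lie strictly between 0 and 1")
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L)
    stop("smooth_window must be an odd integer >= 1")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (tol <= 0) stop("tol must be positive")
  structure(list(trunc_low = trunc_low, trunc_high = trunc_high,
                 poly_order = poly_order, peak_ratio = peak_ratio,
                 smooth_window = smooth_window, normalize = isTRUE(normalize),
                 average_by = average_by,
                 renormalize_after_average = isTRUE(renormalize_after_average),
                 max_iter = max_iter, tol = tol),
            class = "preprocess_config")
}

#' Read a preprocessing configuration from a YAML or JSON file
#'
#' Keys mirror the [preprocess_config()] argument names exactly; absent
#' keys take their defaults.
#'
#' @param path Path to a YAML (or JSON) key-value file.
#' @return A `preprocess_config`.
#' @export
read_preprocess_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(preprocess_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown preprocess config key(s): ", paste(unknown, collapse = ", "))
  do.call(preprocess_config, vals)
}

#' Truncate a spectrum to a wavenumber window
#'
#' Keeps grid points w with low <= w <= high (closed interval); metadata is
#' preserved.
#'
#' @param s A [raman_spectrum()].
#' @param low,high Window bounds in cm^-1.
#' @return The truncated `raman_spectrum`.
#' @export
truncate_spectrum <- function(s, low = 400, high = 1800) {
  if (!(low < high)) stop("low must be < high")
  keep <- s$wavenumbers >= low & s$wavenumbers <= high
  if (sum(keep) < 2L)
    stop(sprintf("truncation window [%g, %g] contains fewer than 2 grid points",
                 low, high))
  s$wavenumbers <- s$wavenumbers[keep]
  s$intensities <- s$intensities[keep]
  s
}

# moving average with boundary-clipped windows; length preserved
moving_average <- function(y, window) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  n <- length(y)
  if (window > n) stop("smoothing window exceeds spectrum length")
  if (window == 1L) return(y)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth a spectrum with a moving average
#'
#' Windows are clipped at the spectrum edges, so output length equals input
#' length; `window = 1` is the identity.
#'
#' @param s A [raman_spectrum()].
#' @param window Odd integer window size, at most the grid length.
#' @return The smoothed `raman_spectrum`.
#' @export
smooth_spectrum <- function(s, window = 5) {
  s$intensities <- moving_average(s$intensities, window)
  s
}

#' Normalize a spectrum to unit Euclidean norm
#'
#' @param s A [raman_spectrum()].
#' @return The vector-normalized `raman_spectrum` (norm 1 within 1e-12).
#' @export
vector_normalize <- function(s) {
  nrm <- sqrt(sum(s$intensities^2))
  if (nrm == 0) stop("cannot vector-normalize an all-zero spectrum")
  s$intensities <- s$intensities / nrm
  s
}

#' Resample a spectrum onto a new wavenumber grid
#'
#' Linear interpolation; the target grid must lie within the source grid's
#' span (no extrapolation).
#'
#' @param s A [raman_spectrum()].
#' @param grid Target wavenumber vector, strictly increasing.
#' @return The resampled `raman_spectrum`.
#' @export
resample_to_grid <- function(s, grid) {
  grid <- as.numeric(grid)
  if (min(grid) < min(s$wavenumbers) || max(grid) > max(s$wavenumbers))
    stop("target grid extends outside the source grid span; refusing to extrapolate")
  s$intensities <- stats::approx(s$wavenumbers, s$intensities, xout = grid,
                                 method = "linear", ties = "ordered")$y
  s$wavenumbers <- grid
  s
}

#' Average replicate scans within specimens or individuals
#'
#' Each group of scans sharing a grouping key collapses to its pointwise
#' arithmetic mean. The class label must be unanimous within a group. In
#' the collapsed metadata, scan_id becomes the group key and
#' replicate_index the number of scans averaged.
#'
#' @param d A [spectral_dataset()].
#' @param by Grouping key: "specimen" (specimen_id) or "individual"
#'   (individual_id).
#' @return A `spectral_dataset` with one row per group, groups in order of
#'   first appearance.
#' @export
average_replicates <- function(d, by = c("specimen", "individual")) {
  by <- match.arg(by)
  key_col <- if (by == "specimen") "specimen_id" else "individual_id"
  keys <- d$meta[[key_col]]
  if (any(!nzchar(keys)) || anyNA(keys))
    stop("grouping key '", key_col, "' must be non-empty for all scans")
  groups <- unique(keys)
  mat <- matrix(0, length(groups), length(d$grid))
  meta <- data.frame(scan_id = groups, specimen_id = groups,
                     individual_id = groups, class_label = "",
                     replicate_index = 0L, stringsAsFactors = FALSE)
  for (g in seq_along(groups)) {
    rows <- which(keys == groups[g])
    labels <- unique(d$meta$class_label[rows])
    if (length(labels) > 1L)
      stop(sprintf("group '%s' has conflicting class labels: %s",
                   groups[g], paste(labels, collapse = ", ")))
    mat[g, ] <- colMeans(d$intensity[rows, , drop = FALSE])
    meta$class_label[g] <- labels
    meta$replicate_index[g] <- length(rows)
    meta$individual_id[g] <- d$meta$individual_id[rows[1]]
    if (by == "individual") meta$specimen_id[g] <- groups[g]
  }
  spectral_dataset(d$grid, mat, meta)
}

#' Run the full preprocessing chain on a dataset
#'
#' Applies, in order: truncation to the configured window, baseline
#' correction ([goldindec_baseline()]), vector normalization, and replicate
#' averaging. Smoothing per the config is used only inside baseline
#' estimation. Because normalization precedes averaging, averaged rows have
#' Euclidean norm <= 1 (exactly 1 only when a group's unit vectors agree);
#' set `renormalize_after_average` in the config to restore unit norm.
#'
#' @param d A [spectral_dataset()].
#' @param cfg A [preprocess_config()].
#' @return A list with `dataset` (the processed `spectral_dataset`) and
#'   `log` (data.frame of per-step scan and grid-point counts).
#' @export
run_preprocess <- function(d, cfg = preprocess_config()) {
  stopifnot(inherits(d, "spectral_dataset"), inherits(cfg, "preprocess_config"))
  log <- data.frame(step = "input", n_scans = n_scans(d),
                    n_points = length(d$grid), stringsAsFactors = FALSE)
  keep <- d$grid >= cfg$trunc_low & d$grid <= cfg$trunc_high
  if (sum(keep) < 2L)
    stop(sprintf("truncation window [%g, %g] contains fewer than 2 grid points",
                 cfg$trunc_low, cfg$trunc_high))
  d <- spectral_dataset(d$grid[keep], d$intensity[, keep, drop = FALSE], d$meta)
  log <- rbind(log, data.frame(step = "truncate", n_scans = n_scans(d),
                               n_points = length(d$grid)))
  for (i in seq_len(n_scans(d))) {
    s <- get_spectrum(d, i)
    s <- goldindec_baseline(s, cfg)$corrected
    if (cfg$normalize) s <- vector_normalize(s)
    d$intensity[i, ] <- s$intensities
  }
  log <- rbind(log, data.frame(step = "baseline_normalize",
                               n_scans = n_scans(d),
                               n_points = length(d$grid)))
  if (cfg$average_by != "none") {
    d <- average_replicates(d, cfg$average_by)
    if (cfg$renormalize_after_average)
      d$intensity <- d$intensity / sqrt(rowSums(d$intensity^2))
    log <- rbind(log, data.frame(step = "average", n_scans = n_scans(d),
                                 n_points = length(d$grid)))
  }
  list(dataset = d, log = log)
}
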