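# Synthetic liquid-sample Raman spectra with known ground truth. Each
# specimen gets a random low-order polynomial baseline (emulating broad
# fluorescence background) and per-peak amplitude perturbations; each
# replicate scan adds iid Gaussian detector noise on top of the shared
# specimen signal. Class membership acts multiplicatively on peak
# amplitudes (optionally as a peak shift), which is the kind of broad
# compositional difference chemometric models are meant to detect.

#' Synthetic dataset configuration
#'
#' Defaults emulate the acquisition conditions the pipeline targets: a
#' 400-1800 cm^-1 grid at 1 cm^-1 spacing, 10 replicate scans per
#' specimen, two classes ("healthy"/"unhealthy"), five Gaussian bands in
#' the fingerprint region (including the ~1003 cm^-1 band prominent in
#' urine), a multiplicative class effect on band amplitudes, moderate
#' specimen-to-specimen amplitude variability, and small replicate noise.
#'
#' @param grid_low,grid_high,grid_step Wavenumber grid in cm^-1.
#' @param n_specimens_per_class Specimens per class; scalar or one value
#'   per class.
#' @param n_replicates Replicate scans per specimen (>= 1).
#' @param classes Class labels.
#' @param peak_centers,peak_widths,base_amplitudes Per-peak Gaussian (or
#'   Lorentzian) band parameters; equal lengths, widths > 0.
#' @param class_effects Per-class multiplicative amplitude factor. Either
#'   a vector (one factor per class, applied to the marker bands in
#'   `effect_peaks`) or a full `length(classes)` x n_peaks matrix. Because
#'   the pipeline vector-normalizes each scan, a factor applied uniformly
#'   to every band cancels out; restricting it to a subset of bands
#'   changes relative band intensities, which is both what survives
#'   normalization and what a compositional difference between classes
#'   looks like.
#' @param effect_peaks Indices of the bands the per-class factors act on
#'   when `class_effects` is a vector (default: bands 2 and 4).
#' @param class_shifts Per-class additive shift of band centers (cm^-1),
#'   default 0 — an optional harder test mode.
#' @param baseline_coeffs_range 2-column matrix (lo, hi), one row per
#'   polynomial coefficient (constant first, order <= 3), sampled
#'   uniformly per specimen on a [0, 1]-scaled wavenumber axis.
#' @param specimen_sd SD of the per-specimen, per-peak amplitude factor
#'   (centered at 1).
#' @param clutter_n Number of minor per-specimen bands (random centers,
#'   widths and amplitudes), emulating individual compositional variation
#'   — the hundreds of low-abundance compounds whose levels differ from
#'   specimen to specimen. 0 disables clutter.
#' @param clutter_amp Maximum amplitude of a clutter band (uniform on
#'   [0, clutter_amp]).
#' @param clutter_width_range Range (lo, hi) of clutter band widths, cm^-1.
#' @param noise_sd SD of the iid additive replicate noise.
#' @param peak_shape "gaussian" (default) or "lorentzian".
#' @param seed Integer seed; generation is bit-reproducible for a fixed
#'   config.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(grid_low = 400, grid_high = 1800, grid_step = 1,
                         n_specimens_per_class = 20L, n_replicates = 10L,
                         classes = c("healthy", "unhealthy"),
                         peak_centers = c(680, 1003, 1160, 1450, 1650),
                         peak_widths = c(15, 10, 18, 22, 20),
                         base_amplitudes = c(0.6, 1.0, 0.5, 0.8, 0.7),
                         class_effects = c(1, 1.25),
                         effect_peaks = c(2L, 4L),
                         class_shifts = 0,
                         baseline_coeffs_range = cbind(lo = c(0.5, -0.3, -0.3, -0.2),
                                                       hi = c(1.5, 0.3, 0.3, 0.2)),
                         specimen_sd = 0.05, noise_sd = 0.02,
                         clutter_n = 30L, clutter_amp = 0.05,
                         clutter_width_range = c(8, 40),
                         peak_shape = c("gaussian", "lorentzian"),
                         seed = 1L) {
  peak_shape <- match.arg(peak_shape)
  if (!(grid_low < grid_high)) stop("grid_low must be < grid_high")
  if (grid_step <= 0) stop("grid_step must be positive")
  if (length(peak_centers) != length(peak_widths) ||
      length(peak_centers) != length(base_amplitudes))
    stop("peak_centers, peak_widths and base_amplitudes must have equal length")
  if (any(peak_widths <= 0)) stop("peak widths must be positive")
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (specimen_sd < 0) stop("specimen_sd must be >= 0")
  clutter_n <- as.integer(clutter_n)
  if (clutter_n < 0L || clutter_amp < 0) stop("clutter settings must be >= 0")
  if (length(clutter_width_range) != 2L ||
      any(clutter_width_range <= 0) ||
      clutter_width_range[2] < clutter_width_range[1])
    stop("clutter_width_range must be positive (lo, hi)")
  classes <- as.character(classes)
  if (length(classes) < 1L || anyDuplicated(classes))
    stop("classes must be distinct labels")
  n_specimens_per_class <- as.integer(rep_len(n_specimens_per_class,
                                              length(classes)))
  if (any(n_specimens_per_class < 1L))
    stop("n_specimens_per_class must be >= 1")
  n_peaks <- length(peak_centers)
  if (is.matrix(class_effects)) {
    if (nrow(class_effects) != length(classes) || ncol(class_effects) != n_peaks)
      stop("class_effects matrix must be length(classes) x n_peaks")
    effect_mat <- class_effects
  } else {
    effect_peaks <- as.integer(effect_peaks)
    if (any(effect_peaks < 1L) || any(effect_peaks > n_peaks))
      stop("effect_peaks indices must lie in 1..n_peaks")
    fac <- rep_len(as.numeric(class_effects), length(classes))
    effect_mat <- matrix(1, length(classes), n_peaks)
    effect_mat[, effect_peaks] <- fac
  }
  rownames(effect_mat) <- classes
  class_shifts <- rep_len(as.numeric(class_shifts), length(classes))
  baseline_coeffs_range <- as.matrix(baseline_coeffs_range)
  if (ncol(baseline_coeffs_range) != 2L || nrow(baseline_coeffs_range) > 4L)
    stop("baseline_coeffs_range must be a (lo, hi) matrix with <= 4 rows (order <= 3)")
  if (any(baseline_coeffs_range[, 2] < baseline_coeffs_range[, 1]))
    stop("baseline_coeffs_range rows must satisfy lo <= hi")
  structure(list(grid_low = grid_low, grid_high = grid_high,
                 grid_step = grid_step,
                 n_specimens_per_class = n_specimens_per_class,
                 n_replicates = n_replicates, classes = classes,
                 peak_centers = peak_centers, peak_widths = peak_widths,
                 base_amplitudes = base_amplitudes,
                 class_effects = effect_mat, class_shifts = class_shifts,
                 baseline_coeffs_range = baseline_coeffs_range,
                 specimen_sd = specimen_sd, noise_sd = noise_sd,
                 clutter_n = clutter_n, clutter_amp = clutter_amp,
                 clutter_width_range = clutter_width_range,
                 peak_shape = peak_shape, seed = as.integer(seed)),
            class = "synth_config")
}

peak_profile <- function(w, center, width, shape) {
  if (shape == "gaussian") exp(-(w - center)^2 / (2 * width^2))
  else 1 / (1 + ((w - center) / width)^2)
}

eval_poly_coeffs <- function(coeffs, grid, grid_low, grid_high) {
  t <- (grid - grid_low) / (grid_high - grid_low)
  drop(outer(t, seq_along(coeffs) - 1, `^`) %*% coeffs)
}

#' Generate a synthetic spectral dataset with known ground truth
#'
#' For each specimen a baseline polynomial and per-peak amplitude factors
#' are drawn once; each replicate scan is baseline + class-scaled peaks +
#' iid Gaussian noise. The ground-truth record keeps every baseline
#' coefficient and realized amplitude so recovery tests can compare
#' against the generative truth.
#'
#' @param cfg A [synth_config()].
#' @return A list with `dataset` (a [spectral_dataset()]) and `truth`
#'   (class `synth_truth`: grid span, per-specimen baseline coefficients,
#'   and realized per-peak amplitudes).
#' @export
generate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed)
  grid <- seq(cfg$grid_low, cfg$grid_high, by = cfg$grid_step)
  n_peaks <- length(cfg$peak_centers)
  n_spec_total <- sum(cfg$n_specimens_per_class)
  n_rows <- n_spec_total * cfg$n_replicates
  mat <- matrix(0, n_rows, length(grid))
  meta <- data.frame(scan_id = character(n_rows), specimen_id = "",
                     individual_id = "", class_label = "",
                     replicate_index = 0L, stringsAsFactors = FALSE)
  coeff_mat <- matrix(0, n_spec_total, nrow(cfg$baseline_coeffs_range))
  amp_mat <- matrix(0, n_spec_total, n_peaks)
  spec_ids <- character(n_spec_total)
  spec_class <- character(n_spec_total)
  row <- 0L; sp <- 0L
  for (ci in seq_along(cfg$classes)) {
    cls <- cfg$classes[ci]
    profiles <- vapply(seq_len(n_peaks), function(j)
      peak_profile(grid, cfg$peak_centers[j] + cfg$class_shifts[ci],
                   cfg$peak_widths[j], cfg$peak_shape),
      numeric(length(grid)))
    for (si in seq_len(cfg$n_specimens_per_class[ci])) {
      sp <- sp + 1L
      spec_ids[sp] <- sprintf("%s_s%02d", cls, si)
      spec_class[sp] <- cls
      coeffs <- stats::runif(nrow(cfg$baseline_coeffs_range),
                             cfg$baseline_coeffs_range[, 1],
                             cfg$baseline_coeffs_range[, 2])
      coeff_mat[sp, ] <- coeffs
      baseline <- eval_poly_coeffs(coeffs, grid, cfg$grid_low, cfg$grid_high)
      amps <- cfg$base_amplitudes * cfg$class_effects[ci, ] *
        stats::rnorm(n_peaks, 1, cfg$specimen_sd)
      amp_mat[sp, ] <- amps
      signal <- baseline + drop(profiles %*% amps)
      if (cfg$clutter_n > 0L) {
        cc <- stats::runif(cfg$clutter_n, cfg$grid_low, cfg$grid_high)
        cw <- stats::runif(cfg$clutter_n, cfg$clutter_width_range[1],
                           cfg$clutter_width_range[2])
        ca <- stats::runif(cfg$clutter_n, 0, cfg$clutter_amp)
        for (j in seq_len(cfg$clutter_n))
          signal <- signal + ca[j] * peak_profile(grid, cc[j], cw[j],
                                                  cfg$peak_shape)
      }
      for (ri in seq_len(cfg$n_replicates)) {
        row <- row + 1L
        mat[row, ] <- signal +
          if (cfg$noise_sd > 0) stats::rnorm(length(grid), 0, cfg$noise_sd) else 0
        meta$scan_id[row] <- sprintf("%s_r%02d", spec_ids[sp], ri)
        meta$specimen_id[row] <- spec_ids[sp]
        meta$individual_id[row] <- spec_ids[sp]
        meta$class_label[row] <- cls
        meta$replicate_index[row] <- ri
      }
    }
  }
  colnames(coeff_mat) <- paste0("coef", seq_len(ncol(coeff_mat)) - 1L)
  colnames(amp_mat) <- paste0("amp", seq_len(n_peaks))
  truth <- structure(list(
    grid_low = cfg$grid_low, grid_high = cfg$grid_high, grid = grid,
    specimens = cbind(data.frame(specimen_id = spec_ids,
                                 class_label = spec_class,
                                 stringsAsFactors = FALSE),
                      as.data.frame(coeff_mat), as.data.frame(amp_mat))),
    class = "synth_truth")
  list(dataset = spectral_dataset(grid, mat, meta), truth = truth)
}

#' Ground-truth baseline of a synthetic specimen
#'
#' Evaluates the generative baseline polynomial of one specimen on the
#' generation grid, for baseline-recovery tests.
#'
#' @param truth A `synth_truth` record from [generate_dataset()].
#' @param specimen_id Specimen identifier.
#' @return Numeric baseline vector over the generation grid.
#' @export
ground_truth_baseline <- function(truth, specimen_id) {
  stopifnot(inherits(truth, "synth_truth"))
  i <- match(specimen_id, truth$specimens$specimen_id)
  if (is.na(i)) stop("unknown specimen_id: ", specimen_id)
  coeffs <- as.numeric(truth$specimens[i, grep("^coef", names(truth$specimens))])
  eval_poly_coeffs(coeffs, truth$grid, truth$grid_low, truth$grid_high)
}

#' Write the ground-truth record as a sidecar CSV
#'
#' @param truth A `synth_truth` record.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synth_truth"))
  utils::write.table(truth$specimens, path, sep = infer_sep(path, NULL),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
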