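#' Construct a single Raman spectrum
#'
#' A `raman_spectrum` holds one scan: a strictly increasing wavenumber grid
#' (Raman shift, cm^-1), the measured intensities (arbitrary detector units),
#' and provenance labels tying the scan to a specimen, an individual and a
#' class.
#'
#' @param wavenumbers Numeric vector, strictly increasing, finite, length >= 2.
#' @param intensities Numeric vector, same length as `wavenumbers`, finite.
#' @param scan_id,specimen_id,individual_id Character identifiers.
#' @param class_label Character class label (e.g. "healthy"/"unhealthy").
#' @param replicate_index Integer >= 1, position of this scan among the
#'   specimen's replicate scans.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumbers, intensities,
                           scan_id = "scan1",
                           specimen_id = scan_id,
                           individual_id = specimen_id,
                           class_label = "",
                           replicate_index = 1L) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities must have equal length")
  if (length(wavenumbers) < 2L)
    stop("a spectrum needs at least 2 grid points")
  if (!all(is.finite(wavenumbers)) || !all(is.finite(intensities)))
    stop("wavenumbers and intensities must all be finite")
  if (any(diff(wavenumbers) <= 0))
    stop("wavenumbers must be strictly increasing")
  replicate_index <- as.integer(replicate_index)
  if (is.na(replicate_index) || replicate_index < 1L)
    stop("replicate_index must be an integer >= 1")
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         scan_id = as.character(scan_id),
         specimen_id = as.character(specimen_id),
         individual_id = as.character(individual_id),
         class_label = as.character(class_label),
         replicate_index = replicate_index),
    class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("Raman spectrum '%s' (%d points, %.1f-%.1f cm^-1)\n",
              x$scan_id, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  cat(sprintf("  specimen %s | individual %s | class '%s' | replicate %d\n",
              x$specimen_id, x$individual_id, x$class_label,
              x$replicate_index))
  invisible(x)
}

# required metadata columns, in canonical order
META_COLS <- c("scan_id", "specimen_id", "individual_id",
               "class_label", "replicate_index")

#' Construct a spectral dataset
#'
#' A `spectral_dataset` holds a set of scans aligned on a shared wavenumber
#' grid: an n_scans x n_points intensity matrix plus one metadata row per
#' scan (scan_id, specimen_id, individual_id, class_label, replicate_index).
#' Matrix row order always matches metadata row order.
#'
#' @param grid Shared wavenumber vector (cm^-1), strictly increasing.
#' @param intensity Numeric matrix, one row per scan, `length(grid)` columns.
#' @param meta data.frame with columns scan_id, specimen_id, individual_id,
#'   class_label, replicate_index; one row per scan, scan_ids unique.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(grid, intensity, meta) {
  grid <- as.numeric(grid)
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (!all(is.finite(grid))) stop("grid must be finite")
  if (ncol(intensity) != length(grid))
    stop("every intensity row must have length == length(grid)")
  if (!all(is.finite(intensity))) stop("intensities must all be finite")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  missing_cols <- setdiff(META_COLS, names(meta))
  if (length(missing_cols))
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  meta <- meta[META_COLS]
  for (col in META_COLS[1:4]) meta[[col]] <- as.character(meta[[col]])
  meta$replicate_index <- as.integer(meta$replicate_index)
  if (nrow(meta) != nrow(intensity))
    stop("metadata must have one row per scan")
  dup <- meta$scan_id[duplicated(meta$scan_id)]
  if (length(dup))
    stop("duplicate scan_id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(meta$class_label)) || anyNA(meta$class_label))
    stop("every scan must have a non-empty class_label")
  rownames(intensity) <- meta$scan_id
  rownames(meta) <- NULL
  structure(list(grid = grid, intensity = intensity, meta = meta),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cls <- table(x$meta$class_label)
  cat(sprintf("Spectral dataset: %d scans x %d points (%.1f-%.1f cm^-1)\n",
              nrow(x$intensity), length(x$grid), min(x$grid), max(x$grid)))
  cat("  classes:",
      paste(sprintf("%s (%d)", names(cls), as.integer(cls)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$intensity)

#' Number of scans in a dataset
#' @param d A `spectral_dataset`.
#' @return Integer scan count.
#' @export
n_scans <- function(d) nrow(d$intensity)

#' Extract one scan from a dataset as a spectrum
#' @param d A `spectral_dataset`.
#' @param i Row index or scan_id.
#' @return A `raman_spectrum`.
#' @export
get_spectrum <- function(d, i) {
  if (is.character(i)) {
    i <- match(i, d$meta$scan_id)
    if (is.na(i)) stop("unknown scan_id")
  }
  m <- d$meta[i, ]
  raman_spectrum(d$grid, d$intensity[i, ], scan_id = m$scan_id,
                 specimen_id = m$specimen_id, individual_id = m$individual_id,
                 class_label = m$class_label,
                 replicate_index = m$replicate_index)
}

#' Subset a dataset by scan rows
#' @param d A `spectral_dataset`.
#' @param rows Logical or integer row index.
#' @return A `spectral_dataset` with the selected scans.
#' @export
subset_scans <- function(d, rows) {
  spectral_dataset(d$grid, d$intensity[rows, , drop = FALSE], d$meta[rows, ])
}

# check a dataset is fit for model building (>= 2 classes)
assert_classes_for_fit <- function(d) {
  if (length(unique(d$meta$class_label)) < 2L)
    stop("at least 2 distinct class labels are required before model fitting")
  invisible(d)
}
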