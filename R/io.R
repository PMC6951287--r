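# Delimited-text interchange: a spectra table (column 1 = wavenumber, one
# column per scan) plus a companion metadata table (one row per scan).
# Comma is the default separator; tab is accepted (.tsv/.tab extension or
# sep = "\t").

infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
}

read_delim_checked <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE,
                    comment.char = "", quote = "\"")
}

# convert one character column to numeric, reporting the offending cell
as_numeric_checked <- function(x, colname, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' in file '%s', column '%s', data row %d",
                 x[bad[1]], path, colname, bad[1]))
  if (anyNA(out))
    stop(sprintf("missing value in file '%s', column '%s'", path, colname))
  out
}

#' Read a spectral dataset from a spectra/metadata file pair
#'
#' The spectra file is delimited text with a header row: column 1 holds the
#' wavenumber grid (cm^-1), columns 2..n hold one scan each, named by
#' scan_id. The metadata file has one row per scan_id with columns scan_id,
#' specimen_id, individual_id, class_label, replicate_index. Rows of the
#' returned intensity matrix follow metadata row order. A descending
#' wavenumber column is sorted ascending, uniformly across all scans.
#'
#' @param spectra_path Path to the spectra table (CSV default, TSV accepted).
#' @param meta_path Path to the metadata table.
#' @param sep Field separator; inferred from the file extension when NULL.
#' @return A [spectral_dataset()].
#' @export
read_dataset <- function(spectra_path, meta_path, sep = NULL) {
  sp <- read_delim_checked(spectra_path, infer_sep(spectra_path, sep))
  if (ncol(sp) < 2L) stop("spectra file must have a wavenumber column plus at least one scan column")
  scan_ids <- colnames(sp)[-1]
  dup <- scan_ids[duplicated(scan_ids)]
  if (length(dup)) stop("duplicate scan_id column(s) in spectra file: ",
                        paste(unique(dup), collapse = ", "))
  wn <- as_numeric_checked(sp[[1]], colnames(sp)[1], spectra_path)
  mat <- vapply(seq_along(scan_ids), function(j)
    as_numeric_checked(sp[[j + 1L]], scan_ids[j], spectra_path),
    numeric(length(wn)))
  mat <- matrix(mat, nrow = length(wn))
  ord <- order(wn)
  wn <- wn[ord]
  mat <- mat[ord, , drop = FALSE]
  if (any(diff(wn) <= 0)) stop("wavenumber column contains duplicates")

  meta <- read_delim_checked(meta_path, infer_sep(meta_path, sep))
  missing_cols <- setdiff(META_COLS, names(meta))
  if (length(missing_cols))
    stop("metadata file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  meta$replicate_index <- as.integer(
    as_numeric_checked(meta$replicate_index, "replicate_index", meta_path))
  dupm <- meta$scan_id[duplicated(meta$scan_id)]
  if (length(dupm)) stop("duplicate scan_id(s) in metadata: ",
                         paste(unique(dupm), collapse = ", "))
  no_meta <- setdiff(scan_ids, meta$scan_id)
  if (length(no_meta))
    stop("scan(s) present in spectra but missing from metadata: ",
         paste(no_meta, collapse = ", "))
  no_spec <- setdiff(meta$scan_id, scan_ids)
  if (length(no_spec))
    stop("scan(s) present in metadata but missing from spectra: ",
         paste(no_spec, collapse = ", "))
  # rows ordered as metadata rows
  mat <- t(mat[, match(meta$scan_id, scan_ids), drop = FALSE])
  spectral_dataset(wn, mat, meta)
}

# full-precision numeric formatting for round-trip-safe text output
fmt_full <- function(x) formatC(x, digits = 17, format = "g", width = -1)

#' Write a spectral dataset to a spectra/metadata file pair
#'
#' Inverse of [read_dataset()]: numeric values are written with 17
#' significant digits so a read/write round trip preserves doubles exactly.
#'
#' @param d A [spectral_dataset()].
#' @param spectra_path,meta_path Output paths.
#' @param sep Field separator; inferred from the file extension when NULL.
#' @return Invisibly, `c(spectra_path, meta_path)`.
#' @export
write_dataset <- function(d, spectra_path, meta_path, sep = NULL) {
  ssep <- infer_sep(spectra_path, sep)
  out <- data.frame(wavenumber = fmt_full(d$grid), stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (i in seq_len(nrow(d$intensity)))
    out[[d$meta$scan_id[i]]] <- fmt_full(d$intensity[i, ])
  utils::write.table(out, spectra_path, sep = ssep, quote = FALSE,
                     row.names = FALSE)
  utils::write.table(d$meta, meta_path, sep = infer_sep(meta_path, sep),
                     quote = FALSE, row.names = FALSE)
  invisible(c(spectra_path, meta_path))
}

#' Write a PC-sweep validation report to CSV
#'
#' One row per retained-PC count, ascending, with columns n_pcs,
#' variance_explained_pct, accuracy_pct, sensitivity_pct, specificity_pct.
#' Percentages are on the 0-100 scale and written with one decimal place;
#' full precision is retained in the in-memory report.
#'
#' @param report A `validation_report` from [pc_sweep()].
#' @param path Output path.
#' @param sep Field separator; inferred from the extension when NULL.
#' @return Invisibly, `path`.
#' @export
write_sweep_report <- function(report, path, sep = NULL) {
  rows <- if (inherits(report, "validation_report")) report$rows else report
  if (is.null(rows) || nrow(rows) == 0L)
    stop("cannot write an empty sweep report")
  rows <- rows[order(rows$n_pcs), , drop = FALSE]
  pct_cols <- c("variance_explained_pct", "accuracy_pct",
                "sensitivity_pct", "specificity_pct")
  out <- data.frame(n_pcs = as.integer(rows$n_pcs))
  for (col in pct_cols) out[[col]] <- sprintf("%.1f", rows[[col]])
  utils::write.table(out, path, sep = infer_sep(path, sep), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a discriminant score table to CSV
#'
#' Columns: specimen_id, true_label, predicted_label, correct, ld1, ld2 —
#' the quantities needed to recreate DAPC cluster plots (correct vs
#' incorrect markers on the first two canonical axes).
#'
#' @param scores A `score_table` from [canonical_scores()].
#' @param path Output path.
#' @param sep Field separator; inferred from the extension when NULL.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(scores, path, sep = NULL) {
  tab <- if (inherits(scores, "score_table")) scores$table else scores
  cols <- c("specimen_id", "true_label", "predicted_label", "correct",
            "ld1", "ld2")
  utils::write.table(tab[cols], path, sep = infer_sep(path, sep),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-fold leave-one-out predictions to CSV
#'
#' @param report A `validation_report` from [pc_sweep()] or the fold records
#'   from [loo_validate()].
#' @param path Output path.
#' @param sep Field separator; inferred from the extension when NULL.
#' @return Invisibly, `path`.
#' @export
write_fold_records <- function(report, path, sep = NULL) {
  folds <- if (inherits(report, "validation_report")) report$folds else report
  if (is.null(folds) || nrow(folds) == 0L) stop("no fold records to write")
  utils::write.table(folds, path, sep = infer_sep(path, sep), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
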