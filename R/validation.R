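#' Grouped leave-one-out validation of a DAPC model
#'
#' Each validation unit (specimen or individual) is held out in turn: all
#' of its scans are removed, PCA and the discriminant statistics are refit
#' from scratch on the remainder with the given k (no leakage of the
#' held-out unit into centering, loadings, or covariance), and the unit's
#' scan(s) are classified by the fold model.
#'
#' @param d A processed [spectral_dataset()].
#' @param k Number of retained principal components per fold model.
#' @param unit Validation unit: "specimen" (specimen_id) or "individual"
#'   (individual_id).
#' @param priors Passed to [fit_dapc()].
#' @return A list with `confusion` (true x predicted contingency table over
#'   the classes) and `folds` (data.frame: unit_id, scan_id, true_label,
#'   predicted_label).
#' @export
loo_validate <- function(d, k, unit = c("specimen", "individual"),
                         priors = "uniform") {
  unit <- match.arg(unit)
  key_col <- if (unit == "specimen") "specimen_id" else "individual_id"
  keys <- d$meta[[key_col]]
  classes <- sort(unique(d$meta$class_label))
  units <- unique(keys)
  for (u in units) {
    label_u <- unique(d$meta$class_label[keys == u])
    if (length(label_u) > 1L)
      stop(sprintf("validation unit '%s' has conflicting class labels", u))
  }
  folds <- vector("list", length(units))
  for (i in seq_along(units)) {
    held <- keys == units[i]
    train_classes <- unique(d$meta$class_label[!held])
    if (length(train_classes) < length(classes))
      stop(sprintf(
        "holding out unit '%s' removes class '%s' from the training fold",
        units[i], setdiff(classes, train_classes)[1]))
    model <- fit_dapc(subset_scans(d, !held), k, priors = priors)
    predicted <- dapc_predict(model, subset_scans(d, held))
    folds[[i]] <- data.frame(unit_id = units[i],
                             scan_id = d$meta$scan_id[held],
                             true_label = d$meta$class_label[held],
                             predicted_label = predicted,
                             stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, folds)
  confusion <- table(true = factor(folds$true_label, levels = classes),
                     predicted = factor(folds$predicted_label, levels = classes))
  list(confusion = confusion, folds = folds)
}

#' Accuracy, sensitivity and specificity from a confusion table
#'
#' Accuracy is the percentage of correctly classified spectra. Sensitivity
#' (true-positive rate) and specificity (true-negative rate) are computed
#' against the designated positive class; with more than two classes the
#' table is reduced one-vs-rest. A zero denominator yields NA with a
#' warning, never a silent 0.
#'
#' @param confusion A true x predicted contingency table (square, classes
#'   in the same order on both margins).
#' @param positive_class The label counted as "positive" (e.g. "unhealthy").
#' @return Named numeric vector: accuracy_pct, sensitivity_pct,
#'   specificity_pct (0-100 scale; NA where undefined).
#' @export
classification_metrics <- function(confusion, positive_class) {
  confusion <- as.table(confusion)
  n <- sum(confusion)
  if (n == 0L) stop("empty confusion table")
  classes <- rownames(confusion)
  if (!positive_class %in% classes)
    stop("positive_class '", positive_class, "' is not among the classes")
  tp <- confusion[positive_class, positive_class]
  fn <- sum(confusion[positive_class, ]) - tp
  fp <- sum(confusion[, positive_class]) - tp
  tn <- n - tp - fn - fp
  accuracy <- 100 * sum(diag(confusion)) / n
  sensitivity <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
    warning("sensitivity undefined: no spectra in the positive class")
    NA_real_
  }
  specificity <- if (tn + fp > 0) 100 * tn / (tn + fp) else {
    warning("specificity undefined: no spectra outside the positive class")
    NA_real_
  }
  c(accuracy_pct = accuracy, sensitivity_pct = sensitivity,
    specificity_pct = unname(specificity))
}

#' Leave-one-out sweep over retained-PC counts
#'
#' Repeats grouped leave-one-out validation for each k in `k_list` and
#' tabulates accuracy, sensitivity and specificity per k, together with
#' the cumulative variance explained by the first k components of a
#' full-data PCA (one value per k, not per fold). Duplicate k values are
#' deduplicated; rows are sorted ascending by k.
#'
#' @param d A processed [spectral_dataset()].
#' @param k_list Integer vector of retained-PC counts.
#' @param positive_class Label treated as positive for sensitivity and
#'   specificity.
#' @param unit Validation unit, as in [loo_validate()].
#' @param priors Passed to [fit_dapc()].
#' @return An object of class `validation_report` with `rows` (data.frame:
#'   n_pcs, variance_explained_pct, accuracy_pct, sensitivity_pct,
#'   specificity_pct; full precision) and `folds` (per-fold predictions
#'   with an n_pcs column).
#' @export
pc_sweep <- function(d, k_list, positive_class,
                     unit = c("specimen", "individual"), priors = "uniform") {
  unit <- match.arg(unit)
  k_list <- sort(unique(as.integer(k_list)))
  if (length(k_list) == 0L) stop("k_list is empty")
  if (any(k_list < 1L)) stop("all k must be >= 1")
  pca_full <- fit_pca(d)
  cum_var <- cumsum(pca_full$explained_var_frac)
  if (max(k_list) > length(cum_var))
    stop(sprintf("k = %d exceeds the %d components available from the full data",
                 max(k_list), length(cum_var)))
  rows <- data.frame(n_pcs = k_list,
                     variance_explained_pct = 100 * cum_var[k_list],
                     accuracy_pct = NA_real_, sensitivity_pct = NA_real_,
                     specificity_pct = NA_real_)
  fold_list <- vector("list", length(k_list))
  for (i in seq_along(k_list)) {
    res <- loo_validate(d, k_list[i], unit = unit, priors = priors)
    met <- classification_metrics(res$confusion, positive_class)
    rows$accuracy_pct[i] <- met[["accuracy_pct"]]
    rows$sensitivity_pct[i] <- met[["sensitivity_pct"]]
    rows$specificity_pct[i] <- met[["specificity_pct"]]
    res$folds$n_pcs <- k_list[i]
    fold_list[[i]] <- res$folds
  }
  structure(list(rows = rows, folds = do.call(rbind, fold_list),
                 positive_class = positive_class, unit = unit),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Leave-one-out sweep (%s-level, positive class '%s'):\n",
              x$unit, x$positive_class))
  rows <- x$rows
  for (col in c("variance_explained_pct", "accuracy_pct",
                "sensitivity_pct", "specificity_pct"))
    rows[[col]] <- sprintf("%.1f", rows[[col]])
  print(rows, row.names = FALSE)
  invisible(x)
}
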