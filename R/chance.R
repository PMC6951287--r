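#' Random-chance accuracy, sensitivity and specificity for a label set
#'
#' Computes the performance a label-agnostic random classifier would
#' achieve on a dataset with the given class labels — the floor against
#' which leave-one-out results should be judged. Two chance models:
#'
#' * `uniform-guess`: the classifier assigns each spectrum a label drawn
#'   uniformly over the g classes. Closed form, independent of class
#'   representation: accuracy = sensitivity = 100/g and
#'   specificity = 100 (g - 1)/g for every class; with two classes all
#'   three are 50%.
#' * `permutation`: predicted labels are a random permutation of the true
#'   labels (the classifier reproduces the class proportions but carries
#'   no information). Monte-Carlo over `n_mc` shuffles; expected accuracy
#'   is sum(p_c^2) over class proportions p_c. Means and standard errors
#'   are reported; deterministic for a fixed seed.
#'
#' @param labels Character vector of true class labels (>= 2 classes).
#' @param model "uniform-guess" (default) or "permutation".
#' @param n_mc Number of Monte-Carlo shuffles for the permutation model.
#' @param seed Integer seed for the permutation model.
#' @return An object of class `chance_report`: model tag, accuracy_pct
#'   (+ accuracy_se for permutation), and per_class data.frame with
#'   sensitivity_pct and specificity_pct (+ standard errors).
#' @export
random_chance <- function(labels, model = c("uniform-guess", "permutation"),
                          n_mc = 1000L, seed = 1L) {
  model <- match.arg(model)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  g <- length(classes)
  if (g < 2L) stop("random chance values need at least 2 classes")
  if (model == "uniform-guess") {
    per_class <- data.frame(class = classes,
                            sensitivity_pct = 100 / g,
                            specificity_pct = 100 * (g - 1) / g,
                            stringsAsFactors = FALSE)
    out <- list(model = model, accuracy_pct = 100 / g, accuracy_se = 0,
                per_class = per_class, n_mc = 0L)
    return(structure(out, class = "chance_report"))
  }
  n_mc <- as.integer(n_mc)
  if (n_mc < 2L) stop("n_mc must be >= 2")
  truth <- factor(labels, levels = classes)
  acc <- numeric(n_mc)
  sens <- matrix(0, n_mc, g)
  spec <- matrix(0, n_mc, g)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed))
  for (r in seq_len(n_mc)) {
    pred <- sample(truth)
    tab <- table(truth, pred)
    acc[r] <- 100 * sum(diag(tab)) / length(labels)
    for (i in seq_len(g)) {
      tp <- tab[i, i]
      fn <- sum(tab[i, ]) - tp
      fp <- sum(tab[, i]) - tp
      tn <- length(labels) - tp - fn - fp
      sens[r, i] <- 100 * tp / (tp + fn)
      spec[r, i] <- 100 * tn / (tn + fp)
    }
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  per_class <- data.frame(class = classes,
                          sensitivity_pct = colMeans(sens),
                          sensitivity_se = apply(sens, 2L, se),
                          specificity_pct = colMeans(spec),
                          specificity_se = apply(spec, 2L, se),
                          stringsAsFactors = FALSE)
  structure(list(model = model, accuracy_pct = mean(acc),
                 accuracy_se = se(acc), per_class = per_class, n_mc = n_mc),
            class = "chance_report")
}

#' @export
print.chance_report <- function(x, ...) {
  cat(sprintf("Random chance (%s model%s):\n", x$model,
              if (x$n_mc > 0) sprintf(", %d shuffles", x$n_mc) else ""))
  if (x$model == "uniform-guess")
    cat(sprintf("  accuracy %.1f%%\n", x$accuracy_pct))
  else
    cat(sprintf("  accuracy %.2f%% (SE %.3f)\n", x$accuracy_pct, x$accuracy_se))
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}
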