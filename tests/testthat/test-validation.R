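test_that("confusion-count metrics match direct arithmetic", {
  # counts consistent with a 118-vs-20 two-class validation
  conf <- as.table(matrix(c(16, 0, 4, 118), 2, 2,
                          dimnames = list(true = c("healthy", "unhealthy"),
                                          predicted = c("healthy", "unhealthy"))))
  met <- classification_metrics(conf, "unhealthy")
  expect_equal(met[["accuracy_pct"]], 100 * 134 / 138)
  expect_equal(round(met[["accuracy_pct"]], 1), 97.1)
  expect_equal(met[["sensitivity_pct"]], 100)
  expect_equal(met[["specificity_pct"]], 80)
  # identity: accuracy * N == 100 * (TP + TN), exactly
  expect_identical(met[["accuracy_pct"]] * 138, 100 * (118 + 16))
  # identity: accuracy == (sens * P + spec * Neg) / N
  expect_equal(met[["accuracy_pct"]],
               (met[["sensitivity_pct"]] * 118 + met[["specificity_pct"]] * 20) / 138)
})

test_that("undefined ratios are NA with a warning, never coerced", {
  all_pos <- as.table(matrix(c(0, 0, 0, 7), 2, 2,
                             dimnames = list(true = c("n", "p"),
                                             predicted = c("n", "p"))))
  expect_warning(met <- classification_metrics(all_pos, "p"), "specificity")
  expect_equal(met[["accuracy_pct"]], 100)
  expect_equal(met[["sensitivity_pct"]], 100)
  expect_true(is.na(met[["specificity_pct"]]))

  anti <- as.table(matrix(c(0, 5, 3, 0), 2, 2,
                          dimnames = list(true = c("n", "p"),
                                          predicted = c("n", "p"))))
  met2 <- classification_metrics(anti, "p")
  expect_equal(unname(met2), c(0, 0, 0))

  expect_error(classification_metrics(all_pos * 0, "p"), "empty")
  expect_error(classification_metrics(all_pos, "q"), "not among")
})

test_that("grouped LOO predicts every unit once, without leakage artifacts", {
  d <- processed_synth(n_per_class = 5, effect = 1.6, noise_sd = 0.002)
  res <- loo_validate(d, 2)
  expect_equal(nrow(res$folds), 10L)
  expect_equal(sort(res$folds$unit_id), sort(d$meta$specimen_id))
  expect_equal(sum(res$confusion), 10)
  # huge class separation: every unit predicted correctly
  expect_equal(res$folds$predicted_label, res$folds$true_label)

  # permuting row order leaves the confusion counts unchanged
  set.seed(31)
  d_perm <- subset_scans(d, sample(n_scans(d)))
  res_perm <- loo_validate(d_perm, 2)
  expect_equal(as.matrix(res$confusion), as.matrix(res_perm$confusion))
})

test_that("a mislabeled unit is predicted as its generative class", {
  d <- processed_synth(n_per_class = 5, effect = 1.6, noise_sd = 0.002)
  flip <- which(d$meta$specimen_id == "healthy_s01")
  d$meta$class_label[flip] <- "unhealthy"
  res <- loo_validate(d, 2)
  rec <- res$folds[res$folds$unit_id == "healthy_s01", ]
  expect_identical(rec$true_label, "unhealthy")   # the (wrong) recorded label
  expect_identical(rec$predicted_label, "healthy")  # the generative class
})

test_that("LOO refuses folds that lose a class", {
  d <- processed_synth(n_per_class = 5, effect = 1.6, noise_sd = 0.002)
  keep <- d$meta$class_label == "unhealthy" | d$meta$specimen_id == "healthy_s01"
  d1 <- subset_scans(d, keep)
  expect_error(loo_validate(d1, 2), "healthy_s01")
})

test_that("individual-level LOO holds out all specimens of an individual", {
  d <- processed_synth(n_per_class = 6, effect = 1.6, noise_sd = 0.002)
  # pair specimens into individuals (two specimens each)
  d$meta$individual_id <- paste0(substr(d$meta$class_label, 1, 1), "_ind",
                                 rep(rep(1:3, each = 2), 2))
  res <- loo_validate(d, 2, unit = "individual")
  expect_equal(length(unique(res$folds$unit_id)), 6L)
  expect_equal(nrow(res$folds), 12L)  # every specimen still predicted once
})

test_that("pc_sweep tabulates one deduplicated ascending row per k", {
  d <- processed_synth(n_per_class = 5, effect = 1.6, noise_sd = 0.002)
  rep <- pc_sweep(d, c(3, 2, 3, 2), positive_class = "unhealthy")
  expect_equal(rep$rows$n_pcs, c(2L, 3L))
  expect_true(all(diff(rep$rows$variance_explained_pct) >= 0))
  expect_true(all(rep$rows$accuracy_pct == 100))
  expect_true(all(rep$rows$sensitivity_pct == 100))
  expect_true(all(rep$rows$specificity_pct == 100))
  expect_equal(unique(rep$folds$n_pcs), c(2L, 3L))
  # variance column comes from the full-data PCA
  full <- fit_pca(d)
  expect_equal(rep$rows$variance_explained_pct,
               100 * cumsum(full$explained_var_frac)[2:3], tolerance = 1e-10)
  expect_error(pc_sweep(d, integer(0), "unhealthy"), "empty")
  expect_error(pc_sweep(d, 50, "unhealthy"), "exceeds")
})

test_that("LOO accuracy rises with class separation (parameter recovery)", {
  effects <- c(1.02, 1.12, 1.6)
  mean_acc <- vapply(effects, function(eff) {
    accs <- vapply(1:10, function(s) {
      d <- processed_synth(n_per_class = 4, effect = eff, noise_sd = 0.01,
                           seed = s, n_replicates = 2)
      classification_metrics(loo_validate(d, 2)$confusion,
                             "unhealthy")[["accuracy_pct"]]
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_true(all(diff(mean_acc) >= 0))
  expect_gt(mean_acc[3], mean_acc[1])
})
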