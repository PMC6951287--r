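test_that("truncation keeps the closed interval and is idempotent", {
  s <- raman_spectrum(c(300, 400, 1000, 1800, 1900), c(1, 2, 3, 4, 5))
  t1 <- truncate_spectrum(s, 400, 1800)
  expect_equal(t1$wavenumbers, c(400, 1000, 1800))
  expect_equal(t1$intensities, c(2, 3, 4))
  expect_equal(truncate_spectrum(t1, 400, 1800), t1)
  # full-range truncation is the identity
  expect_equal(truncate_spectrum(s, 300, 1900), s)
  # a window catching fewer than 2 points errors
  expect_error(truncate_spectrum(s, 999, 1001), "fewer than 2")
})

test_that("moving-average smoothing matches the hand-computed oracle", {
  s <- raman_spectrum(1:3, c(0, 3, 0))
  expect_equal(smooth_spectrum(s, 3)$intensities, c(1.5, 1, 1.5))
  expect_equal(smooth_spectrum(s, 1), s)
  const <- raman_spectrum(1:9, rep(2.5, 9))
  expect_equal(smooth_spectrum(const, 5), const)
  expect_error(smooth_spectrum(s, 2), "odd")
  # interior value is the plain window mean
  s2 <- raman_spectrum(1:7, c(1, 4, 2, 8, 5, 7, 3))
  expect_equal(smooth_spectrum(s2, 3)$intensities[4], mean(c(2, 8, 5)))
})

test_that("vector normalization is idempotent and scale-invariant", {
  s <- raman_spectrum(1:2, c(3, 4))
  n1 <- vector_normalize(s)
  expect_equal(n1$intensities, c(0.6, 0.8))
  expect_equal(vector_normalize(n1)$intensities, n1$intensities,
               tolerance = 1e-12)
  for (c_scale in c(0.001, 7, 1e6)) {
    scaled <- s
    scaled$intensities <- scaled$intensities * c_scale
    expect_equal(vector_normalize(scaled)$intensities, n1$intensities,
                 tolerance = 1e-12)
  }
  expect_error(vector_normalize(raman_spectrum(1:3, c(0, 0, 0))), "zero")
})

test_that("replicate averaging is the pointwise group mean with unanimous labels", {
  meta <- data.frame(scan_id = paste0("s", 1:4),
                     specimen_id = c("A", "A", "B", "B"),
                     individual_id = c("i1", "i1", "i2", "i2"),
                     class_label = c("x", "x", "y", "y"),
                     replicate_index = c(1L, 2L, 1L, 2L))
  d <- spectral_dataset(c(1, 2), rbind(c(0, 2), c(2, 0), c(1, 1), c(3, 3)),
                        meta)
  avg <- average_replicates(d, "specimen")
  expect_equal(unname(avg$intensity), rbind(c(1, 1), c(2, 2)))
  expect_equal(avg$meta$scan_id, c("A", "B"))
  expect_equal(avg$meta$replicate_index, c(2L, 2L))
  # sum conservation: n_group * mean == sum of member rows
  expect_equal(2 * avg$intensity["A", ], colSums(d$intensity[1:2, ]),
               tolerance = 1e-10)

  meta$class_label[2] <- "y"
  d_bad <- spectral_dataset(c(1, 2), d$intensity, meta)
  expect_error(average_replicates(d_bad, "specimen"), "'A'")

  # ten identical rows collapse to that row with count 10
  meta10 <- data.frame(scan_id = paste0("r", 1:10), specimen_id = "P",
                       individual_id = "i", class_label = "x",
                       replicate_index = 1:10)
  d10 <- spectral_dataset(c(1, 2), matrix(c(5, 9), 10, 2, byrow = TRUE),
                          meta10)
  avg10 <- average_replicates(d10, "specimen")
  expect_equal(unname(avg10$intensity), rbind(c(5, 9)))
  expect_equal(avg10$meta$replicate_index, 10L)
})

test_that("resampling interpolates linearly and refuses to extrapolate", {
  s <- raman_spectrum(c(0, 10, 20), c(0, 10, 20))  # linear ramp
  expect_equal(resample_to_grid(s, c(0, 10, 20)), s)
  r <- resample_to_grid(s, c(2.5, 7.5, 15))
  expect_equal(r$intensities, c(2.5, 7.5, 15))
  expect_error(resample_to_grid(s, c(-1, 5)), "extrapolat")
})

test_that("the pipeline applies steps in order and logs counts", {
  gen <- generate_dataset(synth_config(n_specimens_per_class = 3,
                                       n_replicates = 4, seed = 3))
  res <- run_preprocess(gen$dataset, preprocess_config())
  d <- res$dataset
  # one row per specimen after averaging
  expect_equal(n_scans(d), 6L)
  expect_equal(res$log$step,
               c("input", "truncate", "baseline_normalize", "average"))
  expect_equal(res$log$n_scans, c(24L, 24L, 24L, 6L))
  # normalize-then-average: averaged rows have Euclidean norm <= 1
  norms <- sqrt(rowSums(d$intensity^2))
  expect_true(all(norms <= 1 + 1e-12))
  expect_true(all(norms > 0.9))  # replicates of one specimen are near-parallel

  # average_by = "none" preserves the row count
  res_none <- run_preprocess(gen$dataset,
                             preprocess_config(average_by = "none"))
  expect_equal(n_scans(res_none$dataset), 24L)
  # rows then have unit norm exactly (normalization is the last step)
  expect_equal(unname(sqrt(rowSums(res_none$dataset$intensity^2))),
               rep(1, 24L), tolerance = 1e-12)

  # pipeline-with-averaging equals external averaging of the unaveraged run
  avg_after <- average_replicates(res_none$dataset, "specimen")
  expect_equal(unname(avg_after$intensity), unname(d$intensity),
               tolerance = 1e-12)

  # a truncation window with no points errors
  expect_error(run_preprocess(gen$dataset,
                              preprocess_config(trunc_low = 2000,
                                                trunc_high = 3000)),
               "fewer than 2")
})

test_that("preprocess config files mirror the constructor arguments", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("trunc_low: 500", "poly_order: 2", "average_by: none"), path)
  cfg <- read_preprocess_config(path)
  expect_equal(cfg$trunc_low, 500)
  expect_equal(cfg$poly_order, 2L)
  expect_equal(cfg$average_by, "none")
  expect_equal(cfg$peak_ratio, 0.5)  # untouched default

  writeLines("bogus_key: 1", path)
  expect_error(read_preprocess_config(path), "bogus_key")
  expect_error(preprocess_config(smooth_window = 4), "odd")
  expect_error(preprocess_config(peak_ratio = 1), "peak_ratio")
  expect_error(preprocess_config(trunc_low = 1800, trunc_high = 400),
               "trunc_low")
})
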