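# Small in-code fixtures shared across test files.

# a tiny dataset built by hand: `grid` points, one row per scan
tiny_dataset <- function(grid = c(400, 500, 600),
                         rows = rbind(c(1, 2, 3), c(4, 5, 6)),
                         classes = c("a", "b")) {
  n <- nrow(rows)
  meta <- data.frame(scan_id = paste0("scan", seq_len(n)),
                     specimen_id = paste0("spec", seq_len(n)),
                     individual_id = paste0("ind", seq_len(n)),
                     class_label = rep_len(classes, n),
                     replicate_index = 1L, stringsAsFactors = FALSE)
  spectral_dataset(grid, rows, meta)
}

# two well-separated Gaussian classes in spectrum space: class means differ
# along a fixed direction, spherical within-class noise
blob_dataset <- function(n_per_class = 6, n_points = 20, sep = 10,
                         sd = 0.5, seed = 42) {
  set.seed(seed)
  dir1 <- sin(seq_len(n_points))
  dir1 <- dir1 / sqrt(sum(dir1^2))
  n <- 2 * n_per_class
  mat <- matrix(rnorm(n * n_points, sd = sd), n, n_points)
  mat[seq_len(n_per_class), ] <-
    mat[seq_len(n_per_class), ] + matrix(sep * dir1, n_per_class, n_points,
                                         byrow = TRUE)
  meta <- data.frame(scan_id = paste0("s", seq_len(n)),
                     specimen_id = paste0("s", seq_len(n)),
                     individual_id = paste0("s", seq_len(n)),
                     class_label = rep(c("pos", "neg"), each = n_per_class),
                     replicate_index = 1L, stringsAsFactors = FALSE)
  spectral_dataset(seq_len(n_points), mat, meta)
}

# small processed synthetic dataset for model-level tests
processed_synth <- function(n_per_class = 5, effect = 1.5, noise_sd = 0.005,
                            seed = 7, n_replicates = 3, ...) {
  cfg <- synth_config(n_specimens_per_class = n_per_class,
                      n_replicates = n_replicates,
                      class_effects = c(1, effect), noise_sd = noise_sd,
                      seed = seed, ...)
  run_preprocess(generate_dataset(cfg)$dataset, preprocess_config())$dataset
}

expect_dataset_equal <- function(a, b, tolerance = 0) {
  expect_equal(a$grid, b$grid, tolerance = tolerance)
  expect_equal(unname(a$intensity), unname(b$intensity), tolerance = tolerance)
  expect_equal(a$meta, b$meta)
}
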