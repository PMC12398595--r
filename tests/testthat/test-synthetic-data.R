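test_that("degenerate single-mode spec yields identical rows of its class", {
  spec <- mixture_spec(matrix(0, 1, 3), sds = 0, classes = 1L, noise_sd = 0)
  sim <- simulate_features(spec, n = 3, seed = 1)
  expect_equal(unname(as.matrix(sim[paste0("f", 1:3)])), matrix(0, 3, 3))
  expect_equal(sim$label, rep(1L, 3))
})

test_that("mixture sampling respects class weights and the seed", {
  spec <- ring_mixture_spec(prevalence = 0.3)
  sim <- simulate_features(spec, n = 4000, seed = 7)
  # class counts within binomial 99% bounds of the class-weight sums
  bounds <- qbinom(c(0.005, 0.995), 4000, 0.3)
  expect_gte(sum(sim$label == 1L), bounds[1])
  expect_lte(sum(sim$label == 1L), bounds[2])
  expect_identical(sim, simulate_features(spec, n = 4000, seed = 7))
  expect_false(identical(sim, simulate_features(spec, n = 4000, seed = 8)))
})

test_that("per-mode empirical means converge to the spec means", {
  spec <- ring_mixture_spec(mode_sd = 0.5, noise_sd = 0.1)
  sim <- simulate_features(spec, n = 8000, seed = 3)
  X <- as.matrix(sim[paste0("f", 1:16)])
  sd_tot <- sqrt(0.5^2 + 0.1^2)
  for (m in unique(sim$.mode)) {
    rows <- sim$.mode == m
    dev <- colMeans(X[rows, ]) - spec$means[m, ]
    expect_lt(max(abs(dev)), 3 * sd_tot / sqrt(sum(rows)) * 3)
  }
})

test_that("semi-supervised masking is stratified with fixed rounding", {
  # 90/10 class split, 30% labeled -> 27/3 labeled by largest remainder
  spec <- mixture_spec(rbind(c(0, 0), c(4, 0)), sds = 0.1,
                       classes = c(0L, 1L), weights = c(0.9, 0.1))
  base <- simulate_features(spec, 400, seed = 5)
  data <- base[c(which(base$label == 0)[1:90], which(base$label == 1)[1:10]), ]
  out <- split_semisupervised(data, 0.3, seed = 1)
  expect_equal(sum(out$label != -1L), 30)
  expect_equal(sum(out$label == 0L), 27)
  expect_equal(sum(out$label == 1L), 3)
  expect_equal(out$label_true, data$label)          # shadow labels intact
  expect_equal(out[paste0("f", 1:2)], data[paste0("f", 1:2)]) # rows untouched

  # fraction 1 is the identity; invalid fractions and empty input error
  all_lab <- split_semisupervised(data, 1, seed = 1)
  expect_equal(all_lab$label, data$label)
  expect_error(split_semisupervised(data, 0), "labeled_fraction")
  expect_error(split_semisupervised(data[0, ], 0.3), "empty")
})

test_that("masking applies to the train split only", {
  data <- tiny_dataset(200) |> assign_splits(seed = 2)
  out <- split_semisupervised(data, 0.3, seed = 3)
  expect_true(all(out$label[out$split != "train"] != -1L))
  expect_true(any(out$label[out$split == "train"] == -1L))
})

test_that("stratified k-fold partitions indices and balances classes", {
  data <- tiny_dataset(110, seed = 2)
  folds <- stratified_kfold(data, k = 5, seed = 1)
  tests <- lapply(folds, `[[`, "test")
  expect_setequal(unlist(tests), seq_len(nrow(data)))
  expect_equal(sum(lengths(tests)), nrow(data)) # pairwise disjoint
  expect_lte(diff(range(lengths(tests))), 1)
  prev <- mean(data$label)
  for (f in folds) {
    expect_lte(abs(sum(data$label[f$test]) - prev * length(f$test)), 1)
    expect_setequal(c(f$train, f$test), seq_len(nrow(data)))
  }
  # 10 samples 5/5, k = 5: exactly one of each class per fold
  ten <- data[c(which(data$label == 0)[1:5], which(data$label == 1)[1:5]), ]
  for (f in stratified_kfold(ten, k = 5, seed = 1)) {
    expect_equal(sort(ten$label[f$test]), c(0L, 1L))
  }
  expect_error(stratified_kfold(ten, k = 6, seed = 1), "fewer than k")
})

test_that("oversampling equalizes labeled classes and only duplicates", {
  spec <- mixture_spec(rbind(c(0, 0), c(4, 0)), sds = 0.1,
                       classes = c(0L, 1L), weights = c(0.9, 0.1))
  data <- simulate_features(spec, 300, seed = 9) |>
    split_semisupervised(0.5, seed = 1)
  n_unl <- sum(data$label == -1L)
  out <- oversample_minority(data, seed = 4)
  counts <- table(out$label[out$label != -1L])
  expect_equal(unname(counts[["0"]]), unname(counts[["1"]]))
  expect_equal(sum(out$label == -1L), n_unl)
  # every appended row is a copy of an existing minority row
  extra <- out[-seq_len(nrow(data)), ]
  expect_true(all(extra$label == 1L))
  orig_keys <- do.call(paste, data[data$label == 1L, paste0("f", 1:2)])
  expect_true(all(do.call(paste, extra[paste0("f", 1:2)]) %in% orig_keys))
  # balanced input is a fixed point; single-class labeled set errors
  expect_identical(oversample_minority(out, seed = 1), out)
  single <- data[data$label != 0L, ]
  expect_error(oversample_minority(single), "both classes")
})

test_that("Gaussian feature augmentation has the stated scale and determinism", {
  X <- matrix(rnorm(1e4), 100)
  expect_identical(augment_features(X, 0), X)
  d1 <- augment_features(X, 1, seed = 3) - X
  expect_gt(sd(d1), 0.95)
  expect_lt(sd(d1), 1.05)
  expect_identical(augment_features(X, 1, seed = 3),
                   augment_features(X, 1, seed = 3))
  expect_error(augment_features(X, -0.1), "sigma")
})

test_that("dataset TSV round-trips losslessly at 9 significant digits", {
  data <- tiny_dataset(50) |> assign_splits(seed = 1) |>
    split_semisupervised(0.4, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(data, path)
  back <- read_feature_tsv(path)
  expect_equal(back$label, data$label)
  expect_equal(back$split, data$split)
  expect_equal(as.matrix(back[paste0("f", 1:4)]),
               as.matrix(data[paste0("f", 1:4)]), tolerance = 1e-8)
})

test_that("invalid mixture specs name the offending field", {
  expect_error(mixture_spec(matrix(0, 1, 2), sds = -1, classes = 0L), "sds")
  expect_error(mixture_spec(matrix(0, 1, 2), sds = 1, classes = 2L),
               "classes")
  expect_error(mixture_spec(matrix(0, 1, 2), 1, 0L, weights = 0), "weights")
  expect_error(mixture_spec(matrix(0, 1, 2), 1, 0L, noise_sd = -1),
               "noise_sd")
})
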