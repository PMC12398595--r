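small_ssl_data <- function(n = 120, d = 4, seed = 1) {
  spec <- ring_mixture_spec(n_modes = 4, d = d, mode_sd = 0.4,
                            noise_sd = 0.05)
  simulate_features(spec, n, seed = seed) |>
    assign_splits(seed = seed) |>
    split_semisupervised(0.4, seed = seed + 1)
}

fast_config <- function(...) {
  defaults <- list(
    batch_size = 16, epochs = 1, noise_size = 4,
    g_spec = mlp_spec(n_layers = 2, hidden_width = 8),
    d_spec = mlp_spec(n_layers = 2, hidden_width = 8)
  )
  do.call(training_config, utils::modifyList(defaults, list(...)))
}

test_that("one-epoch training returns finite history and valid nets", {
  data <- small_ssl_data(40)
  fit <- train_ssgan(data, fast_config(seed = 1))
  expect_s3_class(fit, "ssgan_fit")
  expect_equal(nrow(fit$history), 1)
  num <- vapply(fit$history, is.numeric, TRUE)
  expect_true(all(vapply(fit$history[num], function(x) all(is.finite(x)),
                         TRUE)))
  p <- discriminator_forward(fit$discriminator,
                             melanogan:::feature_matrix(data)[1:5, ])
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)
})

test_that("training is reproducible: same config and seed, same checkpoints", {
  data <- small_ssl_data(60)
  cfg <- fast_config(epochs = 2, seed = 7,
                     g_spec = mlp_spec(n_layers = 2, hidden_width = 8,
                                       dropout_rate = 0.3),
                     d_spec = mlp_spec(n_layers = 2, hidden_width = 8,
                                       dropout_rate = 0.3))
  f1 <- train_ssgan(data, cfg)
  f2 <- train_ssgan(data, cfg)
  expect_identical(melanogan:::net_params(f1$generator),
                   melanogan:::net_params(f2$generator))
  expect_identical(melanogan:::net_params(f1$discriminator),
                   melanogan:::net_params(f2$discriminator))
  expect_identical(f1$history, f2$history)
  f3 <- train_ssgan(data, fast_config(epochs = 2, seed = 8))
  expect_false(identical(melanogan:::net_params(f1$generator),
                         melanogan:::net_params(f3$generator)))
})

test_that("training requires a labeled example of each class", {
  data <- small_ssl_data(50)
  one_class <- data
  one_class$label[one_class$label == 1L] <- -1L
  expect_error(train_ssgan(one_class, fast_config()), "labeled row per class")
})

test_that("prediction renormalizes away the fake class", {
  # row [0.7, 0.2, 0.1] -> melanoma with score 7/9; [0.1, 0.7, 0.2] -> 0
  dsc <- discriminator_net(2, 2, mlp_spec(n_layers = 1, hidden_width = 2,
                                          activation = "linear"), seed = 1)
  probs <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.7, 0.2))
  # drive the head to produce those rows exactly via log-prob logits
  dsc$attn <- init_attention(2, zero = TRUE)
  dsc$layers[[1]]$W <- diag(2); dsc$layers[[1]]$b <- c(0, 0)
  dsc$proj$W <- diag(2); dsc$proj$b <- c(0, 0)
  dsc$head$W <- matrix(0, 2, 3)
  dsc$head$W[1, ] <- log(probs[1, ])
  dsc$head$W[2, ] <- log(probs[2, ])
  X <- rbind(c(1, 0), c(0, 1))
  pred <- discriminator_predict(dsc, X)
  expect_equal(pred$.pred_class, c(1L, 0L))
  expect_equal(pred$.pred_melanoma[1], 0.7 / 0.9, tolerance = 1e-9)
  # batch agreement with a per-row oracle on a trained model
  data <- small_ssl_data(60)
  fit <- train_ssgan(data, fast_config(seed = 3))
  Xd <- melanogan:::feature_matrix(data)
  p <- discriminator_forward(fit$discriminator, Xd)
  pred <- predict(fit, data)
  for (i in seq_len(nrow(Xd))) {
    expect_equal(pred$.pred_class[i], as.integer(p[i, 1] >= p[i, 2]))
    expect_equal(pred$.pred_melanoma[i],
                 unname(p[i, 1] / (p[i, 1] + p[i, 2])))
  }
})

test_that("ablation switches are pure configuration", {
  data <- small_ssl_data(60)
  # zeroed attention stays exactly zero through training
  fit <- train_ssgan(data, fast_config(use_attention = FALSE, seed = 2))
  expect_equal(fit$generator$attn$W_q, matrix(0, 4, 4))
  expect_equal(fit$discriminator$attn$W_v, matrix(0, 4, 4))
  # lambda_r = 0 skips reconstruction entirely
  fit0 <- train_ssgan(data, fast_config(
    seed = 2, weights = loss_weights(lambda_r = 0)))
  expect_equal(unique(fit0$history$rec), 0)
  # vanilla SS-GAN: no consistency, no pseudo contribution
  fitv <- train_ssgan(data, fast_config(
    seed = 2, weights = loss_weights(0, 0, 0, 0.9)))
  expect_equal(unique(fitv$history$cons), 0)
  expect_equal(unique(fitv$history$pseudo), 0)
})

test_that("history tracks validation metrics and tidiers expose them", {
  data <- small_ssl_data(150)
  fit <- train_ssgan(data, fast_config(epochs = 3, seed = 5))
  expect_true(all(c("val_f_measure", "val_accuracy", "val_auc") %in%
                    names(fit$history)))
  expect_true(all(fit$history$val_f_measure >= 0 &
                    fit$history$val_f_measure <= 1))
  td <- tidy(fit)
  expect_setequal(unique(td$epoch), 1:3)
  gl <- glance(fit)
  expect_equal(gl$epochs, 3)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("table-2 range checking flags out-of-range confs for the pipeline", {
  cfg <- training_config(batch_size = 64, epochs = 128, noise_size = 32)
  expect_invisible(check_table2(cfg))
  expect_error(check_table2(training_config(batch_size = 8, epochs = 128)),
               "batch_size")
  expect_error(check_table2(training_config(epochs = 4)), "epochs")
})

test_that("a short tuner run returns a usable configuration", {
  data <- small_ssl_data(80)
  fit <- tune_ssgan(
    data,
    space = search_space(
      param_continuous("learning_rate", 1e-3, 1e-2),
      param_integer("n_layers", 1, 2)
    ),
    config = colony_config(num_bees = 2, max_cycles = 1, limit = 3,
                           seed = 1),
    budget_epochs = 1,
    base_config = fast_config()
  )
  expect_s3_class(fit, "abc_fit")
  expect_gte(fit$best$fitness, 0)
  tc <- fit$best_training_config
  expect_true(tc$lr_d >= 1e-3 && tc$lr_d <= 1e-2)
  expect_equal(tc$epochs, 1)
})
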