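test_that("a 1-layer linear generator with zero attention is an affine map", {
  g <- generator_net(3, 2, mlp_spec(n_layers = 1, activation = "linear"),
                     seed = 2)
  g$attn <- init_attention(3, zero = TRUE)
  z <- matrix(rnorm(12), 4, 3)
  W <- g$layers[[1]]$W; b <- g$layers[[1]]$b
  expect_equal(generator_forward(g, z),
               z %*% W + matrix(b, 4, 2, byrow = TRUE), tolerance = 1e-12)
})

test_that("all-zero weights with linear activation give the zero map", {
  g <- generator_net(3, 2, mlp_spec(n_layers = 2, hidden_width = 4,
                                    activation = "linear"), seed = 1)
  p <- melanogan:::net_params(g)
  p <- lapply(p, function(x) x * 0)
  g <- melanogan:::net_set_params(g, p)
  z <- matrix(rnorm(9), 3)
  expect_equal(generator_forward(g, z), matrix(0, 3, 2))
})

test_that("eval-mode forwards are pure functions; z width is checked", {
  g <- generator_net(4, 3, mlp_spec(dropout_rate = 0.5), seed = 3)
  z <- matrix(rnorm(20), 5, 4)
  expect_identical(generator_forward(g, z), generator_forward(g, z))
  expect_error(generator_forward(g, z[, 1:3]), "noise_size")
  dsc <- discriminator_net(3, 4, mlp_spec(dropout_rate = 0.5), seed = 4)
  f <- matrix(rnorm(15), 5, 3)
  expect_identical(discriminator_forward(dsc, f),
                   discriminator_forward(dsc, f))
  expect_error(discriminator_forward(dsc, z), "in_dim")
})

test_that("discriminator probabilities are proper and the zero head uniform", {
  dsc <- discriminator_net(4, 4, mlp_spec(), seed = 5)
  f <- matrix(rnorm(40), 10, 4)
  p <- discriminator_forward(dsc, f)
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-12)
  expect_true(all(p > 0 & p < 1))
  dsc$head$W[] <- 0; dsc$head$b[] <- 0
  p0 <- discriminator_forward(dsc, f)
  expect_equal(unname(p0), matrix(1 / 3, 10, 3), tolerance = 1e-12)
})

test_that("forward pass agrees with a layer-by-layer manual unroll", {
  spec <- mlp_spec(n_layers = 2, hidden_width = 6, activation = "leaky_relu")
  dsc <- discriminator_net(5, 4, spec, seed = 6)
  f <- matrix(rnorm(35), 7, 5)
  # manual: attention residual, two hidden layers, projection, head
  H <- f + self_attention(f, dsc$attn)
  act <- function(z) ifelse(z > 0, z, 0.01 * z)
  for (l in 1:2) {
    H <- act(H %*% dsc$layers[[l]]$W +
               matrix(dsc$layers[[l]]$b, nrow(H), 6, byrow = TRUE))
  }
  Fz <- H %*% dsc$proj$W + matrix(dsc$proj$b, nrow(H), 4, byrow = TRUE)
  logits <- Fz %*% dsc$head$W + matrix(dsc$head$b, nrow(H), 3, byrow = TRUE)
  probs <- t(apply(logits, 1, softmax))
  expect_equal(discriminator_features(dsc, f), Fz, tolerance = 1e-10)
  expect_equal(unname(discriminator_forward(dsc, f)), probs,
               tolerance = 1e-10)
  # composition contract: features then head reproduces the forward pass
  expect_equal(nrow(discriminator_features(dsc, f)), 7)
  expect_equal(ncol(discriminator_features(dsc, f)), 4) # = noise_size
})

test_that("D_F output feeds the generator without shape error", {
  g <- generator_net(4, 5, mlp_spec(), seed = 7)
  dsc <- discriminator_net(5, 4, mlp_spec(), seed = 8)
  x <- matrix(rnorm(30), 6, 5)
  rec <- generator_forward(g, discriminator_features(dsc, x))
  expect_equal(dim(rec), dim(x)) # G(D_F(x)) is a reconstruction of x
})

test_that("identity-configured discriminator returns its attention output", {
  spec <- mlp_spec(n_layers = 1, hidden_width = 4, activation = "linear")
  dsc <- discriminator_net(4, 4, spec, seed = 9)
  dsc$layers[[1]]$W <- diag(4); dsc$layers[[1]]$b <- rep(0, 4)
  dsc$proj$W <- diag(4); dsc$proj$b <- rep(0, 4)
  f <- matrix(rnorm(20), 5, 4)
  expect_equal(discriminator_features(dsc, f),
               f + self_attention(f, dsc$attn), tolerance = 1e-12)
})

test_that("train-mode dropout zeroes the expected activation fraction", {
  rate <- 0.4
  g <- generator_net(6, 4, mlp_spec(n_layers = 3, hidden_width = 50,
                                    dropout_rate = rate), seed = 10)
  z <- matrix(rnorm(600), 100, 6)
  withr::with_seed(11, {
    cache <- melanogan:::generator_forward_cache(g, z, train = TRUE)
  })
  m <- c(cache$layers[[1]]$M, cache$layers[[2]]$M)
  n <- length(m)
  frac <- mean(m == 0)
  expect_lt(abs(frac - rate), 3 * sqrt(rate * (1 - rate) / n))
})

test_that("every catalogued activation is constructible and differentiable", {
  z <- matrix(seq(-2, 2, length.out = 12), 3)
  for (a in c("relu", "leaky_relu", "linear", "tanh", "sigmoid")) {
    g <- generator_net(4, 2, mlp_spec(activation = a), seed = 12)
    expect_true(all(is.finite(generator_forward(g, matrix(rnorm(8), 2)))))
    act <- melanogan:::ACTIVATIONS[[a]]
    grad <- act$grad(z, act$f(z))
    expect_true(all(is.finite(grad)))
    # central finite difference where the activation is smooth (avoid 0
    # for the kinked rectifiers)
    zs <- z + 0.123
    num <- (act$f(zs + 1e-6) - act$f(zs - 1e-6)) / 2e-6
    expect_equal(act$grad(zs, act$f(zs)) + zs * 0, num, tolerance = 1e-5)
  }
  expect_error(mlp_spec(n_layers = 11), "n_layers")
  expect_error(mlp_spec(dropout_rate = 1), "dropout_rate")
})

test_that("backpropagation matches central finite differences", {
  # the training loop relies entirely on these hand-derived gradients
  d <- 4; ns <- 3; eps <- 1e-6
  dsc <- discriminator_net(d, ns, mlp_spec(n_layers = 2, hidden_width = 5,
                                           activation = "tanh"), seed = 13)
  X <- matrix(rnorm(6 * d), 6)
  y <- c(1L, 0L, 1L, 0L, 0L, 1L)
  loss_d <- function(net) {
    d_supervised_loss(discriminator_forward(net, X), y)
  }
  cache <- melanogan:::discriminator_forward_cache(dsc, X, train = FALSE)
  dL <- melanogan:::grad_ce(cache$probs, melanogan:::label_col(y)) / nrow(X)
  gr <- melanogan:::grads_as_params(
    melanogan:::discriminator_backward(dsc, cache, dL))
  p0 <- melanogan:::net_params(dsc)
  for (nm in names(p0)) {
    for (i in seq_len(min(3, length(p0[[nm]])))) {
      pp <- p0; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- p0; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_d(melanogan:::net_set_params(dsc, pp)) -
                loss_d(melanogan:::net_set_params(dsc, pm))) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-5)
    }
  }
  g <- generator_net(ns, d, mlp_spec(n_layers = 2, hidden_width = 5,
                                     activation = "sigmoid"), seed = 14)
  Z <- matrix(rnorm(5 * ns), 5)
  target <- matrix(rnorm(5 * d), 5)
  loss_g <- function(net) reconstruction_loss(target,
                                              generator_forward(net, Z))
  gc1 <- melanogan:::generator_forward_cache(g, Z, train = FALSE)
  diff <- gc1$out - target
  norms <- pmax(sqrt(rowSums(diff^2)), 1e-12)
  grg <- melanogan:::grads_as_params(
    melanogan:::generator_backward(g, gc1, diff / (norms * nrow(Z))))
  p0 <- melanogan:::net_params(g)
  for (nm in names(p0)) {
    for (i in seq_len(min(3, length(p0[[nm]])))) {
      pp <- p0; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- p0; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_g(melanogan:::net_set_params(g, pp)) -
                loss_g(melanogan:::net_set_params(g, pm))) / (2 * eps)
      expect_equal(grg[[nm]][i], num, tolerance = 1e-5)
    }
  }
})

test_that("checkpoints round-trip bit-exactly", {
  g <- generator_net(4, 3, mlp_spec(n_layers = 3, activation = "tanh",
                                    dropout_rate = 0.2), seed = 15)
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(g, path)
  g2 <- read_checkpoint(path)
  expect_identical(melanogan:::net_params(g), melanogan:::net_params(g2))
  expect_identical(g$spec, g2$spec)
  z <- matrix(rnorm(8), 2)
  expect_identical(generator_forward(g, z), generator_forward(g2, z))
  dsc <- discriminator_net(3, 4, mlp_spec(), seed = 16)
  write_checkpoint(dsc, path)
  d2 <- read_checkpoint(path)
  f <- matrix(rnorm(9), 3)
  expect_identical(discriminator_forward(dsc, f),
                   discriminator_forward(d2, f))
})
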