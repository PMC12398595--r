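#' MLP architecture specification
#'
#' Shared hyperparameters of the generator/discriminator multilayer
#' perceptrons. `n_layers` counts linear layers in the search range
#' \[1, 10\]; all hidden layers use one configurable `hidden_width`
#' (the search tunes depth only, so width is a single logged knob).
#'
#' @param n_layers number of linear layers, 1-10.
#' @param hidden_width width of hidden layers (default 64 at desk scale).
#' @param activation one of `"relu"`, `"leaky_relu"`, `"linear"`, `"tanh"`,
#'   `"sigmoid"`.
#' @param dropout_rate dropout probability in \[0, 1) applied to hidden
#'   activations in train mode (inverted dropout).
#' @return An object of class `mlp_spec`.
#' @export
mlp_spec <- function(n_layers = 2, hidden_width = 64,
                     activation = c("relu", "leaky_relu", "linear",
                                    "tanh", "sigmoid"),
                     dropout_rate = 0) {
  activation <- match.arg(activation)
  structure(
    list(
      n_layers = check_number(n_layers, "n_layers", 1, 10, integer = TRUE),
      hidden_width = check_number(hidden_width, "hidden_width", 1,
                                  integer = TRUE),
      activation = activation,
      dropout_rate = check_number(dropout_rate, "dropout_rate", 0, 1,
                                  open_hi = TRUE)
    ),
    class = "mlp_spec"
  )
}

ACTIVATIONS <- list(
  relu = list(
    f = function(z) pmax(z, 0),
    grad = function(z, a) (z > 0) * 1
  ),
  leaky_relu = list(
    f = function(z) ifelse(z > 0, z, 0.01 * z),
    grad = function(z, a) ifelse(z > 0, 1, 0.01)
  ),
  linear = list(
    f = function(z) z,
    grad = function(z, a) 1
  ),
  tanh = list(
    f = function(z) tanh(z),
    grad = function(z, a) 1 - a^2
  ),
  sigmoid = list(
    f = function(z) 1 / (1 + exp(-z)),
    grad = function(z, a) a * (1 - a)
  )
)

# fan-in scaled uniform init, drawn from the ambient RNG stream
init_linear <- function(d_in, d_out) {
  list(
    W = matrix(stats::runif(d_in * d_out, -1, 1) / sqrt(d_in), d_in, d_out),
    b = rep(0, d_out)
  )
}

init_mlp <- function(dims) {
  lapply(seq_len(length(dims) - 1L),
         function(l) init_linear(dims[l], dims[l + 1L]))
}

#' Construct the generator network
#'
#' An attention-prefixed MLP mapping Gaussian noise vectors to synthetic
#' feature vectors. Self-attention (residual, `d_k = noise_size`) is applied
#' to the raw noise input, then `n_layers` linear layers: hidden layers with
#' the configured activation/dropout, and a linear output layer of width
#' `out_dim` (the dataset feature dimension).
#'
#' @param noise_size width of the noise input.
#' @param out_dim feature dimension `d` of the data.
#' @param spec an [mlp_spec()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `generator_net`.
#' @export
generator_net <- function(noise_size, out_dim, spec = mlp_spec(), seed = 1) {
  noise_size <- check_number(noise_size, "noise_size", 1, integer = TRUE)
  out_dim <- check_number(out_dim, "out_dim", 1, integer = TRUE)
  withr::local_seed(seed)
  dims <- c(noise_size,
            rep(spec$hidden_width, spec$n_layers - 1L),
            out_dim)
  structure(
    list(
      noise_size = noise_size, out_dim = out_dim, spec = spec,
      attn = init_attention(noise_size),
      layers = init_mlp(dims)
    ),
    class = "generator_net"
  )
}

#' Construct the discriminator network
#'
#' An attention-prefixed MLP over `in_dim`-dimensional feature vectors with
#' three heads' worth of structure: `n_layers` hidden layers, a linear
#' projection to `noise_size` units (the penultimate feature map `D_F`,
#' sized so the generator can consume it for reconstruction), and a linear
#' head emitting 3 logits over \{melanoma, non-melanoma, fake\}.
#'
#' @param in_dim feature dimension `d`.
#' @param noise_size width of the `D_F` projection; must equal the paired
#'   generator's `noise_size`.
#' @param spec an [mlp_spec()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `discriminator_net`.
#' @export
discriminator_net <- function(in_dim, noise_size, spec = mlp_spec(),
                              seed = 1) {
  in_dim <- check_number(in_dim, "in_dim", 1, integer = TRUE)
  noise_size <- check_number(noise_size, "noise_size", 1, integer = TRUE)
  withr::local_seed(seed)
  dims <- c(in_dim, rep(spec$hidden_width, spec$n_layers))
  structure(
    list(
      in_dim = in_dim, noise_size = noise_size, spec = spec,
      attn = init_attention(in_dim),
      layers = init_mlp(dims),              # hidden layers (act + dropout)
      proj = init_linear(spec$hidden_width, noise_size), # D_F projection
      head = init_linear(noise_size, 3L)    # 3-class logits
    ),
    class = "discriminator_net"
  )
}

# ---- forward passes -------------------------------------------------------

# attention residual block; cache carries everything backprop needs
attn_block_forward <- function(X, attn) {
  f <- attention_forward(X, attn)
  f$out <- X + f$H
  f
}

mlp_layer_forward <- function(H, layer, act, dropout, train) {
  Z <- H %*% layer$W + rep(layer$b, each = nrow(H))
  A_pre <- act$f(Z)
  A <- A_pre
  M <- NULL
  if (train && dropout > 0) {
    M <- matrix(stats::rbinom(length(A), 1L, 1 - dropout), nrow(A)) /
      (1 - dropout)
    A <- A * M
  }
  list(Z = Z, A_pre = A_pre, A = A, M = M)
}

generator_forward_cache <- function(g, z, train = FALSE) {
  z <- check_matrix(z, "z")
  if (ncol(z) != g$noise_size) {
    abort_field("z", sprintf("has width %d, expected noise_size %d",
                             ncol(z), g$noise_size))
  }
  act <- ACTIVATIONS[[g$spec$activation]]
  ab <- attn_block_forward(z, g$attn)
  L <- length(g$layers)
  hs <- vector("list", L)
  H <- ab$out
  for (l in seq_len(L)) {
    if (l < L) {
      hs[[l]] <- mlp_layer_forward(H, g$layers[[l]], act,
                                   g$spec$dropout_rate, train)
      H <- hs[[l]]$A
    } else { # linear output layer
      hs[[l]] <- list(Z = H %*% g$layers[[l]]$W +
                        rep(g$layers[[l]]$b, each = nrow(H)))
      H <- hs[[l]]$Z
    }
  }
  list(attn = ab, layers = hs, out = H)
}

#' Generator forward pass
#'
#' @param g a [generator_net()].
#' @param z `m x noise_size` matrix of noise draws.
#' @param train_mode apply dropout (train) or not (eval; deterministic).
#' @return `m x out_dim` matrix of synthetic feature vectors.
#' @export
generator_forward <- function(g, z, train_mode = FALSE) {
  generator_forward_cache(g, z, train_mode)$out
}

discriminator_forward_cache <- function(dsc, f, train = FALSE) {
  f <- check_matrix(f, "f")
  if (ncol(f) != dsc$in_dim) {
    abort_field("f", sprintf("has width %d, expected in_dim %d",
                             ncol(f), dsc$in_dim))
  }
  act <- ACTIVATIONS[[dsc$spec$activation]]
  ab <- attn_block_forward(f, dsc$attn)
  hs <- vector("list", length(dsc$layers))
  H <- ab$out
  for (l in seq_along(dsc$layers)) {
    hs[[l]] <- mlp_layer_forward(H, dsc$layers[[l]], act,
                                 dsc$spec$dropout_rate, train)
    H <- hs[[l]]$A
  }
  Fz <- H %*% dsc$proj$W + rep(dsc$proj$b, each = nrow(H)) # D_F features
  logits <- Fz %*% dsc$head$W + rep(dsc$head$b, each = nrow(Fz))
  list(attn = ab, layers = hs, H_last = H, Fz = Fz,
       logits = logits, probs = row_softmax(logits))
}

#' Discriminator forward pass
#'
#' @param dsc a [discriminator_net()].
#' @param f `m x d` feature matrix (real or generated).
#' @param train_mode apply dropout (train) or not (eval; deterministic).
#' @return `m x 3` matrix of class probabilities, columns
#'   `(melanoma, non_melanoma, fake)`; rows sum to 1.
#' @export
discriminator_forward <- function(dsc, f, train_mode = FALSE) {
  p <- discriminator_forward_cache(dsc, f, train_mode)$probs
  colnames(p) <- c("melanoma", "non_melanoma", "fake")
  p
}

#' Penultimate discriminator features D_F
#'
#' The discriminator without its final classification layer: attention
#' block, hidden layers, and the linear projection to `noise_size` units,
#' sized so `generator_forward(g, discriminator_features(dsc, x))` is
#' well-typed for the reconstruction loss.
#'
#' @inheritParams discriminator_forward
#' @return `m x noise_size` feature matrix.
#' @export
discriminator_features <- function(dsc, f, train_mode = FALSE) {
  discriminator_forward_cache(dsc, f, train_mode)$Fz
}

# ---- backward passes ------------------------------------------------------

mlp_layer_backward <- function(dA, cache, layer, act, H_in) {
  if (!is.null(cache$M)) dA <- dA * cache$M
  dZ <- dA * act$grad(cache$Z, cache$A_pre)
  list(W = crossprod(H_in, dZ), b = colSums(dZ),
       dH = tcrossprod(dZ, layer$W))
}

# gradient of generator parameters (and optionally input) given dOut
generator_backward <- function(g, cache, dOut) {
  act <- ACTIVATIONS[[g$spec$activation]]
  L <- length(g$layers)
  grads <- list(layers = vector("list", L))
  dH <- dOut
  for (l in rev(seq_len(L))) {
    H_in <- if (l == 1L) cache$attn$out else cache$layers[[l - 1L]]$A
    if (l == L) {
      grads$layers[[l]] <- list(W = crossprod(H_in, dH), b = colSums(dH))
      dH <- tcrossprod(dH, g$layers[[l]]$W)
    } else {
      bk <- mlp_layer_backward(dH, cache$layers[[l]], g$layers[[l]], act, H_in)
      grads$layers[[l]] <- bk[c("W", "b")]
      dH <- bk$dH
    }
  }
  ab <- attention_backward(cache$attn, g$attn, dH)
  grads$attn <- ab[c("W_q", "W_k", "W_v")]
  grads$dX <- dH + ab$X # residual: input feeds both branches
  grads
}

# gradient of discriminator parameters (and input) given dLogits
discriminator_backward <- function(dsc, cache, dLogits) {
  act <- ACTIVATIONS[[dsc$spec$activation]]
  grads <- list()
  grads$head <- list(W = crossprod(cache$Fz, dLogits), b = colSums(dLogits))
  dFz <- tcrossprod(dLogits, dsc$head$W)
  grads$proj <- list(W = crossprod(cache$H_last, dFz), b = colSums(dFz))
  dH <- tcrossprod(dFz, dsc$proj$W)
  L <- length(dsc$layers)
  grads$layers <- vector("list", L)
  for (l in rev(seq_len(L))) {
    H_in <- if (l == 1L) cache$attn$out else cache$layers[[l - 1L]]$A
    bk <- mlp_layer_backward(dH, cache$layers[[l]], dsc$layers[[l]], act, H_in)
    grads$layers[[l]] <- bk[c("W", "b")]
    dH <- bk$dH
  }
  ab <- attention_backward(cache$attn, dsc$attn, dH)
  grads$attn <- ab[c("W_q", "W_k", "W_v")]
  grads$dX <- dH + ab$X
  grads
}

# like discriminator_backward but the loss attaches to Fz (D_F output),
# used when reconstruction flows through the encoder in diagnostics
discriminator_features_backward <- function(dsc, cache, dFz) {
  dLogits <- matrix(0, nrow(dFz), 3L)
  grads <- discriminator_backward(dsc, cache, dLogits)
  # redo from the projection downwards with the feature gradient added
  act <- ACTIVATIONS[[dsc$spec$activation]]
  grads$proj <- list(W = crossprod(cache$H_last, dFz), b = colSums(dFz))
  dH <- tcrossprod(dFz, dsc$proj$W)
  L <- length(dsc$layers)
  for (l in rev(seq_len(L))) {
    H_in <- if (l == 1L) cache$attn$out else cache$layers[[l - 1L]]$A
    bk <- mlp_layer_backward(dH, cache$layers[[l]], dsc$layers[[l]], act, H_in)
    grads$layers[[l]] <- bk[c("W", "b")]
    dH <- bk$dH
  }
  ab <- attention_backward(cache$attn, dsc$attn, dH)
  grads$attn <- ab[c("W_q", "W_k", "W_v")]
  grads$dX <- dH + ab$X
  grads
}

# ---- parameter flattening + Adam ------------------------------------------

net_params <- function(net) {
  p <- list(attn.W_q = net$attn$W_q, attn.W_k = net$attn$W_k,
            attn.W_v = net$attn$W_v)
  for (l in seq_along(net$layers)) {
    p[[paste0("layers.", l, ".W")]] <- net$layers[[l]]$W
    p[[paste0("layers.", l, ".b")]] <- net$layers[[l]]$b
  }
  if (!is.null(net$proj)) {
    p$proj.W <- net$proj$W; p$proj.b <- net$proj$b
    p$head.W <- net$head$W; p$head.b <- net$head$b
  }
  p
}

net_set_params <- function(net, p) {
  net$attn$W_q[] <- p$attn.W_q; net$attn$W_k[] <- p$attn.W_k
  net$attn$W_v[] <- p$attn.W_v
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W[] <- p[[paste0("layers.", l, ".W")]]
    net$layers[[l]]$b[] <- p[[paste0("layers.", l, ".b")]]
  }
  if (!is.null(net$proj)) {
    net$proj$W[] <- p$proj.W; net$proj$b[] <- p$proj.b
    net$head$W[] <- p$head.W; net$head$b[] <- p$head.b
  }
  net
}

grads_as_params <- function(grads) {
  p <- list(attn.W_q = grads$attn$W_q, attn.W_k = grads$attn$W_k,
            attn.W_v = grads$attn$W_v)
  for (l in seq_along(grads$layers)) {
    p[[paste0("layers.", l, ".W")]] <- grads$layers[[l]]$W
    p[[paste0("layers.", l, ".b")]] <- grads$layers[[l]]$b
  }
  if (!is.null(grads$proj)) {
    p$proj.W <- grads$proj$W; p$proj.b <- grads$proj$b
    p$head.W <- grads$head$W; p$head.b <- grads$head$b
  }
  p
}

adam_init <- function(params) {
  list(t = 0,
       m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0))
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    if (is.null(gmat)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- checkpoints -----------------------------------------------------------

#' Save and load network checkpoints
#'
#' A self-describing JSON archive of all named weight arrays plus the
#' architecture specs; `read_checkpoint(write_checkpoint(net, path))`
#' round-trips bit-exactly (doubles are serialized at full precision).
#'
#' @param net a [generator_net()] or [discriminator_net()].
#' @param path file path (`.json`).
#' @return `write_checkpoint()` returns `path` invisibly;
#'   `read_checkpoint()` the reconstructed network.
#' @export
write_checkpoint <- function(net, path) {
  ser <- list(
    class = class(net)[1],
    meta = net[setdiff(names(net), c("attn", "layers", "proj", "head",
                                     "spec"))],
    spec = unclass(net$spec),
    params = lapply(net_params(net), function(x) {
      list(dim = dim(x) %||% length(x), data = as.numeric(x))
    })
  )
  # I(17) significant digits round-trips IEEE doubles exactly
  writeLines(jsonlite::serializeJSON(ser, digits = I(17)), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  ser <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  spec <- do.call(mlp_spec, ser$spec)
  net <- if (ser$class == "generator_net") {
    generator_net(ser$meta$noise_size, ser$meta$out_dim, spec, seed = 0)
  } else {
    discriminator_net(ser$meta$in_dim, ser$meta$noise_size, spec, seed = 0)
  }
  params <- lapply(ser$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2]) else p$data
  })
  net_set_params(net, params)
}
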