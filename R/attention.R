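#' Numerically stable softmax
#'
#' Converts a real vector into a probability distribution,
#' `exp(z_i) / sum_j exp(z_j)`, computed with max-subtraction so large
#' logits do not overflow. Shift-invariant: `softmax(z + c) == softmax(z)`.
#'
#' @param z finite numeric vector of length >= 1.
#' @return A probability vector summing to 1.
#' @export
softmax <- function(z) {
  if (length(z) == 0L) abort_field("z", "must be non-empty")
  if (any(!is.finite(z))) abort_field("z", "must be finite")
  e <- exp(z - max(z))
  e / sum(e)
}

# row-wise softmax of a matrix, stable
row_softmax <- function(S) {
  e <- exp(S - apply(S, 1L, max))
  e / rowSums(e)
}

#' Attention weight matrices
#'
#' The learned projections producing query, key and value matrices. All
#' three share shape `d x d_k`; by default `d_k = d` so attention keeps the
#' feature dimension unchanged, letting it sit in a residual block in front
#' of the MLP.
#'
#' @param W_q,W_k,W_v numeric `d x d_k` matrices.
#' @return An object of class `attention_weights`.
#' @export
attention_weights <- function(W_q, W_k, W_v) {
  W_q <- check_matrix(W_q, "W_q")
  W_k <- check_matrix(W_k, "W_k")
  W_v <- check_matrix(W_v, "W_v")
  if (!all(dim(W_q) == dim(W_k)) || !all(dim(W_q) == dim(W_v))) {
    abort_field("W_q/W_k/W_v", "must share the same d x d_k shape")
  }
  structure(list(W_q = W_q, W_k = W_k, W_v = W_v,
                 d = nrow(W_q), d_k = ncol(W_q)),
            class = "attention_weights")
}

#' @rdname attention_weights
#' @param d input feature dimension.
#' @param d_k key dimension (default `d`).
#' @param scale init scale; entries are drawn `U(-scale, scale) / sqrt(d)`.
#' @param zero if `TRUE`, all-zero weights (the exact attention ablation:
#'   with zero weights the residual block is the identity map).
#' @export
init_attention <- function(d, d_k = d, scale = 0.1, zero = FALSE) {
  draw <- function() {
    if (zero) matrix(0, d, d_k)
    else matrix(stats::runif(d * d_k, -scale, scale) / sqrt(d), d, d_k)
  }
  attention_weights(draw(), draw(), draw())
}

#' Single-head scaled dot-product self-attention
#'
#' Treats the `n` rows of `X` (a minibatch of feature vectors) as tokens:
#' `Q = X W_q`, `K = X W_k`, `V = X W_v`, and the output is
#' `softmax(Q K' / sqrt(d_k)) V`. Each row of the attention matrix is a
#' probability distribution over the batch.
#'
#' @param X numeric `n x d` matrix.
#' @param w an [attention_weights()] object with `d` rows.
#' @param return_weights if `TRUE`, attach the `n x n` attention matrix as
#'   attribute `"attention"`.
#' @return `n x d_k` matrix of attended values.
#' @export
self_attention <- function(X, w, return_weights = FALSE) {
  X <- check_matrix(X, "X")
  if (!inherits(w, "attention_weights")) abort_field("w", "not attention_weights")
  if (ncol(X) != w$d) {
    abort_field("X", sprintf("has %d columns but weights expect d = %d",
                             ncol(X), w$d))
  }
  f <- attention_forward(X, w)
  if (return_weights) attr(f$H, "attention") <- f$P
  f$H
}

# forward returning the cache needed for backprop; H is attention output
# WITHOUT the residual term (callers add X where a residual block is wanted)
attention_forward <- function(X, w) {
  Q <- X %*% w$W_q
  K <- X %*% w$W_k
  V <- X %*% w$W_v
  S <- tcrossprod(Q, K) / sqrt(w$d_k)
  P <- row_softmax(S)
  list(X = X, Q = Q, K = K, V = V, P = P, H = P %*% V)
}

# reverse-mode through scaled dot-product attention.
# dH: gradient wrt the attention output. Returns gradients for the three
# weight matrices and the input.
attention_backward <- function(cache, w, dH) {
  P <- cache$P
  dV <- crossprod(P, dH)
  dP <- tcrossprod(dH, cache$V)
  # softmax Jacobian rowwise: dS = P * (dP - rowSums(dP * P))
  dS <- P * (dP - rowSums(dP * P))
  dS <- dS / sqrt(w$d_k)
  dQ <- dS %*% cache$K
  dK <- crossprod(dS, cache$Q)
  list(
    W_q = crossprod(cache$X, dQ),
    W_k = crossprod(cache$X, dK),
    W_v = crossprod(cache$X, dV),
    X = tcrossprod(dQ, w$W_q) + tcrossprod(dK, w$W_k) + tcrossprod(dV, w$W_v)
  )
}
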