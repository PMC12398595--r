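# Shared fixtures and independent oracles used across the suite.
# Oracles are deliberately naive (scalar loops, exhaustive pair counting)
# and never call the vectorized implementation paths they check.

tiny_dataset <- function(n = 60, d = 4, seed = 1) {
  spec <- ring_mixture_spec(n_modes = 4, d = d, mode_sd = 0.4,
                            noise_sd = 0.05)
  simulate_features(spec, n, seed = seed)
}

# brute-force attention per the scaled dot-product definition,
# one output element at a time
naive_attention <- function(X, w) {
  n <- nrow(X); d_k <- ncol(w$W_q)
  Q <- X %*% w$W_q; K <- X %*% w$W_k; V <- X %*% w$W_v
  out <- matrix(0, n, d_k)
  for (i in seq_len(n)) {
    logits <- numeric(n)
    for (j in seq_len(n)) logits[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d_k)
    a <- exp(logits - max(logits)); a <- a / sum(a)
    for (c in seq_len(d_k)) out[i, c] <- sum(a * V[, c])
  }
  out
}

# scalar-loop loss oracles ---------------------------------------------------

eps_clamp <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)

oracle_sup <- function(probs, labels) {
  tot <- 0
  for (i in seq_len(nrow(probs))) {
    col <- if (labels[i] == 1) 1 else 2
    tot <- tot - log(eps_clamp(probs[i, col]))
  }
  tot / nrow(probs)
}

oracle_usup <- function(pr, pf) {
  a <- 0
  if (!is.null(pr)) {
    for (i in seq_len(nrow(pr))) a <- a - log(eps_clamp(1 - pr[i, 3]))
    a <- a / nrow(pr)
  }
  b <- 0
  if (!is.null(pf)) {
    for (i in seq_len(nrow(pf))) b <- b - log(eps_clamp(pf[i, 3]))
    b <- b / nrow(pf)
  }
  a + b
}

oracle_gadv <- function(pf) {
  tot <- 0
  for (i in seq_len(nrow(pf))) tot <- tot - log(eps_clamp(1 - pf[i, 3]))
  tot / nrow(pf)
}

oracle_rec <- function(x, xr) {
  tot <- 0
  for (i in seq_len(nrow(x))) tot <- tot + sqrt(sum((xr[i, ] - x[i, ])^2))
  tot / nrow(x)
}

oracle_cons <- function(p, pa) {
  tot <- 0
  for (i in seq_len(nrow(p))) tot <- tot + sum((p[i, ] - pa[i, ])^2)
  tot / nrow(p)
}

oracle_pseudo <- function(p, tau) {
  losses <- c()
  for (i in seq_len(nrow(p))) {
    conf <- max(p[i, 1], p[i, 2])
    if (conf >= tau) losses <- c(losses, -log(eps_clamp(conf)))
  }
  if (length(losses) == 0) list(loss = 0, n = 0L)
  else list(loss = mean(losses), n = length(losses))
}

# random probability rows over 3 classes
random_probs <- function(m, seed) {
  withr::with_seed(seed, {
    p <- matrix(stats::rexp(m * 3), m)
    p / rowSums(p)
  })
}

# exhaustive O(n^2) AUC: fraction of (pos, neg) pairs ranked correctly,
# ties counted half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}
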