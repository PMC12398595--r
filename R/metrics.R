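#' Confusion counts for binary melanoma classification
#'
#' Melanoma (label 1) is the positive class.
#'
#' @param truth integer vector of true labels in \{0, 1\}.
#' @param estimate integer vector of predicted labels in \{0, 1\}.
#' @return A `confusion_counts` object with TP, TN, FP, FN.
#' @export
confusion_counts <- function(truth, estimate) {
  if (length(truth) != length(estimate)) abort_field("estimate", "length mismatch")
  if (!all(truth %in% c(0L, 1L)) || !all(estimate %in% c(0L, 1L))) {
    abort_field("truth/estimate", "labels must be 0 or 1")
  }
  structure(
    list(TP = sum(truth == 1 & estimate == 1),
         TN = sum(truth == 0 & estimate == 0),
         FP = sum(truth == 0 & estimate == 1),
         FN = sum(truth == 1 & estimate == 0)),
    class = "confusion_counts"
  )
}

safe_ratio <- function(num, den) {
  if (den == 0) structure(0, degenerate = TRUE) else num / den
}

#' Classification metrics for imbalanced screening
#'
#' Accuracy, precision, recall (TPR), specificity, F-measure (harmonic mean
#' of precision and recall), G-means (geometric mean of TPR and
#' specificity) and FNR = 1 - TPR, the clinically critical missed-malignancy
#' rate. Ratios with zero denominators are reported as 0 with a warning and
#' a `degenerate` flag. All values are fractions in \[0, 1\]; multiply by
#' 100 for the percent scale used in reporting.
#'
#' @param c a [confusion_counts()] object.
#' @return A one-row tibble of metrics.
#' @examples
#' classification_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1)))
#' @export
classification_metrics <- function(c) {
  if (!inherits(c, "confusion_counts")) abort_field("c", "not confusion_counts")
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0) abort_field("c", "all counts are zero")
  vals <- list(
    accuracy = (c$TP + c$TN) / total,
    precision = safe_ratio(c$TP, c$TP + c$FP),
    recall_tpr = safe_ratio(c$TP, c$TP + c$FN),
    specificity = safe_ratio(c$TN, c$TN + c$FP)
  )
  degenerate <- any(vapply(vals, function(v) isTRUE(attr(v, "degenerate")),
                           TRUE))
  vals <- lapply(vals, as.numeric)
  pr_sum <- vals$precision + vals$recall_tpr
  vals$f_measure <- if (pr_sum == 0) {
    degenerate <- TRUE
    0
  } else 2 * vals$precision * vals$recall_tpr / pr_sum
  vals$g_means <- sqrt(vals$recall_tpr * vals$specificity)
  vals$fnr <- 1 - vals$recall_tpr
  if (degenerate) {
    warning("zero-denominator metric reported as 0", call. = FALSE)
  }
  out <- tibble::as_tibble(vals)
  out$degenerate <- degenerate
  out
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Area under the ROC curve computed from rank statistics with ties counted
#' half, equal to the trapezoidal integral of the empirical ROC curve.
#'
#' @param scores numeric scores (higher = more melanoma-like).
#' @param labels integer labels in \{0, 1\}; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) abort_field("labels", "length mismatch")
  if (!all(labels %in% c(0L, 1L))) abort_field("labels", "must be 0 or 1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort_field("labels", "both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Convolutional layer stacks and their receptive field
#'
#' `layer_stack(kernel, stride)` records an ordered conv/pool stack;
#' `receptive_field()` evaluates the standard recursion
#' `R_1 = k_1`, `R_l = R_(l-1) + (k_l - 1) * prod(s_1 .. s_(l-1))`.
#' `vgg16_stack()` is the canonical 13-conv (k=3, s=1) / 5-pool (k=2, s=2)
#' feature extractor, whose final receptive field of 212 x 212 pixels
#' nearly covers a 224 x 224 input — the rationale for using its embeddings
#' as globally informed feature vectors.
#'
#' @param kernel,stride positive integer vectors (recycled to equal length).
#' @return `layer_stack()` a tibble with class `layer_stack`;
#'   `receptive_field()` an integer.
#' @examples
#' receptive_field(layer_stack(c(3, 3), c(1, 1))) # two stacked 3x3 convs: 5
#' receptive_field(vgg16_stack()) # 212
#' @export
layer_stack <- function(kernel, stride = 1) {
  if (length(kernel) == 0L) abort_field("kernel", "stack must be non-empty")
  n <- max(length(kernel), length(stride))
  kernel <- rep_len(as.integer(kernel), n)
  stride <- rep_len(as.integer(stride), n)
  if (any(kernel < 1L) || any(stride < 1L)) {
    abort_field("kernel/stride", "must be >= 1")
  }
  structure(tibble::tibble(kernel = kernel, stride = stride),
            class = c("layer_stack", class(tibble::tibble())))
}

#' @rdname layer_stack
#' @export
vgg16_stack <- function() {
  blocks <- c(2, 2, 3, 3, 3) # convs per block, each followed by a pool
  kernel <- unlist(lapply(blocks, function(b) c(rep(3L, b), 2L)))
  stride <- unlist(lapply(blocks, function(b) c(rep(1L, b), 2L)))
  layer_stack(kernel, stride)
}

#' @rdname layer_stack
#' @param stack a `layer_stack`.
#' @export
receptive_field <- function(stack) {
  if (!inherits(stack, "layer_stack")) stack <- layer_stack(stack$kernel,
                                                            stack$stride)
  R <- stack$kernel[1]
  jump <- stack$stride[1]
  for (l in seq_along(stack$kernel)[-1]) {
    R <- R + (stack$kernel[l] - 1L) * jump
    jump <- jump * stack$stride[l]
  }
  as.integer(R)
}

# ---- distribution metrics --------------------------------------------------

sq_dists <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

# unbiased RBF MMD^2 (diagonal terms removed), median-heuristic bandwidth
mmd_rbf <- function(X, Y, bandwidth = NULL) {
  n <- nrow(X); m <- nrow(Y)
  dxx <- sq_dists(X, X); dyy <- sq_dists(Y, Y); dxy <- sq_dists(X, Y)
  if (is.null(bandwidth)) {
    pooled <- c(dxx[upper.tri(dxx)], dyy[upper.tri(dyy)], as.vector(dxy))
    bandwidth <- sqrt(stats::median(pooled[pooled > 0]) / 2)
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  k <- function(d2) exp(-d2 / (2 * bandwidth^2))
  kxx <- k(dxx); kyy <- k(dyy)
  mmd2 <- (sum(kxx) - sum(diag(kxx))) / (n * (n - 1)) +
    (sum(kyy) - sum(diag(kyy))) / (m * (m - 1)) -
    2 * mean(k(dxy))
  sqrt(max(mmd2, 0))
}

knn_kth_dist <- function(query, ref, k, drop_self = FALSE) {
  if (requireNamespace("FNN", quietly = TRUE)) {
    kk <- if (drop_self) k + 1L else k
    d <- FNN::knnx.dist(ref, query, k = kk)
    d[, kk]
  } else {
    d <- sqrt(sq_dists(query, ref))
    apply(d, 1L, function(r) {
      r <- sort(r)
      if (drop_self) r[k + 1L] else r[k]
    })
  }
}

# Kozachenko-Leonenko style k-NN estimator of KL(P || Q) from samples
kl_knn <- function(X, Y, k = 5) {
  n <- nrow(X); m <- nrow(Y); d <- ncol(X)
  rho <- pmax(knn_kth_dist(X, X, k, drop_self = TRUE), 1e-12)
  nu <- pmax(knn_kth_dist(X, Y, k), 1e-12)
  max(0, d * mean(log(nu / rho)) + log(m / (n - 1)))
}

# exact 1-D Wasserstein-1 via the CDF-difference integral
w1_1d <- function(x, y) {
  all_v <- sort(c(x, y))
  n <- length(all_v)
  Fx <- stats::ecdf(x)(all_v[-n])
  Fy <- stats::ecdf(y)(all_v[-n])
  sum(abs(Fx - Fy) * diff(all_v))
}

sliced_wasserstein <- function(X, Y, slices = 64) {
  d <- ncol(X)
  mean(vapply(seq_len(slices), function(s) {
    u <- stats::rnorm(d)
    u <- u / sqrt(sum(u^2))
    w1_1d(X %*% u, Y %*% u)
  }, 1))
}

# soft posterior over mixture modes (Gaussian responsibilities)
mode_posterior <- function(X, spec) {
  k <- nrow(spec$means)
  var_k <- spec$sds^2 + spec$noise_sd^2
  ll <- vapply(seq_len(k), function(j) {
    d2 <- rowSums(sweep(X, 2L, spec$means[j, ])^2)
    -d2 / (2 * var_k[j]) - ncol(X) / 2 * log(var_k[j]) + log(spec$weights[j])
  }, numeric(nrow(X)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1L)
  t(apply(ll, 1L, softmax))
}

kl_discrete <- function(p, q, eps = 1e-12) {
  p <- pmax(p, eps); q <- pmax(q, eps)
  sum(p * log(p / q))
}

#' Distribution metrics for generator quality
#'
#' Quantifies mode coverage (diversity) and fidelity of generated features
#' against real ones: `mmd` is the square root of the unbiased RBF-kernel
#' two-sample statistic (median-heuristic bandwidth); `kld` a k-nearest
#' neighbour estimate of KL(real || fake); `wd` the sliced Wasserstein-1
#' distance (random unit projections, exact 1-D transport per slice); and
#' `mode_score` combines per-sample sharpness of the oracle's mode
#' posterior with marginal mode coverage relative to real data, normalized
#' by the mode count so 1 is ideal and collapse onto few modes scores low.
#' All four are near their ideal for identical samples; mode collapse
#' raises mmd/kld/wd and lowers the mode score.
#'
#' @param real_X,fake_X numeric matrices with equal column counts.
#' @param spec optional [mixture_spec()]; the known mixture acts as the
#'   mode-assignment oracle for the mode score (omitted when `NULL`).
#' @param slices number of random projections for `wd`.
#' @param k neighbour count for `kld`.
#' @param seed integer seed for the random projections.
#' @return A one-row tibble: `mmd`, `kld`, `wd`, and `mode_score` (NA
#'   without an oracle).
#' @export
distribution_metrics <- function(real_X, fake_X, spec = NULL,
                                 slices = 64, k = 5, seed = 1) {
  real_X <- check_matrix(real_X, "real_X")
  fake_X <- check_matrix(fake_X, "fake_X")
  if (ncol(real_X) != ncol(fake_X)) {
    abort_field("fake_X", sprintf("has %d columns, real has %d",
                                  ncol(fake_X), ncol(real_X)))
  }
  if (nrow(real_X) == 0L || nrow(fake_X) == 0L) {
    abort_field("real_X/fake_X", "must be non-empty")
  }
  withr::local_seed(seed)
  ms <- NA_real_
  if (!is.null(spec)) {
    if (!inherits(spec, "mixture_spec")) abort_field("spec", "not a mixture_spec")
    post_real <- mode_posterior(real_X, spec)
    post_fake <- mode_posterior(fake_X, spec)
    marg_real <- colMeans(post_real)
    marg_fake <- colMeans(post_fake)
    mean_kl <- mean(vapply(seq_len(nrow(post_fake)), function(i) {
      kl_discrete(post_fake[i, ], marg_real)
    }, 1))
    ms <- exp(mean_kl - kl_discrete(marg_fake, marg_real)) /
      nrow(spec$means)
  }
  tibble::tibble(
    mmd = mmd_rbf(real_X, fake_X),
    kld = kl_knn(real_X, fake_X, k = k),
    wd = sliced_wasserstein(real_X, fake_X, slices = slices),
    mode_score = ms
  )
}

#' Percent change between two reported values
#'
#' `relative` mode returns `100 * (after - before) / before` (sign
#' preserved, so a reduction is negative); `absolute` returns
#' `after - before`.
#'
#' @param before,after scalar values on the same scale.
#' @param mode `"relative"` (percent of `before`) or `"absolute"`.
#' @return Scalar change (percent for `relative`).
#' @examples
#' relative_change(11.22, 7.17) # -36.1% missed-malignancy reduction
#' @export
relative_change <- function(before, after, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  before <- check_number(before, "before")
  after <- check_number(after, "after")
  if (mode == "relative") {
    if (before == 0) abort_field("before", "must be nonzero in relative mode")
    100 * (after - before) / before
  } else {
    after - before
  }
}
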