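#' Specify a Gaussian mixture over feature space
#'
#' A mixture of isotropic Gaussian modes, each carrying a class label,
#' stands in for the heterogeneous lesion-subtype structure of image-derived
#' feature vectors: melanoma and non-melanoma populations are each
#' multi-modal (many subtypes differing in shape, colour gradation and size),
#' and observations carry additive noise.
#'
#' @param means numeric matrix, one row per mode (columns = feature
#'   dimension `d`).
#' @param sds positive numeric vector of per-mode isotropic standard
#'   deviations (recycled).
#' @param classes integer vector of per-mode classes, `0` = non-melanoma,
#'   `1` = melanoma.
#' @param weights positive per-mode sampling weights; normalized to sum to 1.
#' @param noise_sd non-negative standard deviation of additive observation
#'   noise applied on top of the mode draw.
#' @return An object of class `mixture_spec`.
#' @seealso [ring_mixture_spec()] for the default 8-mode benchmark,
#'   [simulate_features()] to draw a dataset.
#' @export
mixture_spec <- function(means, sds, classes, weights = NULL, noise_sd = 0) {
  means <- check_matrix(means, "means")
  k <- nrow(means)
  if (k < 1L) abort_field("means", "needs at least one mode")
  sds <- rep_len(as.numeric(sds), k)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    abort_field("sds", "must be finite and >= 0")
  }
  classes <- rep_len(as.integer(classes), k)
  if (!all(classes %in% c(0L, 1L))) abort_field("classes", "must be 0 or 1")
  if (length(unique(classes)) < 2L && k > 1L) {
    # single-mode degenerate specs are allowed; multi-mode specs must cover
    # both classes to be a usable two-class world
    if (!all(classes == classes[1L])) abort_field("classes", "inconsistent")
  }
  weights <- if (is.null(weights)) rep(1, k) else rep_len(as.numeric(weights), k)
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    abort_field("weights", "must be finite and > 0")
  }
  noise_sd <- check_number(noise_sd, "noise_sd", lo = 0)
  structure(
    list(
      means = means, sds = sds, classes = classes,
      weights = weights / sum(weights), noise_sd = noise_sd,
      d = ncol(means)
    ),
    class = "mixture_spec"
  )
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf(
    "<mixture_spec> %d modes in d=%d (classes %s), noise_sd=%g\n",
    nrow(x$means), x$d, paste(table(x$classes), collapse = "/"), x$noise_sd
  ))
  invisible(x)
}

#' Default multi-modal two-class benchmark: modes on a ring
#'
#' Eight isotropic Gaussian modes (four per class, interleaved) placed on a
#' ring of radius 4 in the first two coordinates of a `d = 16` dimensional
#' space. Rich enough to exhibit generator mode collapse at desk scale while
#' remaining cheap on one CPU. Class imbalance is introduced through the
#' per-class mode weights (default 70% non-melanoma / 30% melanoma).
#'
#' @param n_modes even number of modes (default 8).
#' @param d feature dimension (default 16).
#' @param radius ring radius (default 4).
#' @param mode_sd within-mode standard deviation (default 0.5).
#' @param noise_sd additive observation noise (default 0.1).
#' @param prevalence fraction of mass on the melanoma class (default 0.3).
#' @return A [mixture_spec()].
#' @export
ring_mixture_spec <- function(n_modes = 8, d = 16, radius = 4,
                              mode_sd = 0.5, noise_sd = 0.1,
                              prevalence = 0.3) {
  n_modes <- check_number(n_modes, "n_modes", lo = 2, integer = TRUE)
  if (n_modes %% 2L != 0L) abort_field("n_modes", "must be even")
  d <- check_number(d, "d", lo = 2, integer = TRUE)
  prevalence <- check_number(prevalence, "prevalence", lo = 0, hi = 1,
                             open_lo = TRUE, open_hi = TRUE)
  ang <- 2 * pi * (seq_len(n_modes) - 1) / n_modes
  means <- matrix(0, n_modes, d)
  means[, 1] <- radius * cos(ang)
  means[, 2] <- radius * sin(ang)
  classes <- rep_len(c(0L, 1L), n_modes) # interleave classes around the ring
  # class mass split equally across that class's modes
  w <- ifelse(classes == 1L, prevalence, 1 - prevalence)
  w <- w / stats::ave(w, classes, FUN = length)
  mixture_spec(means, mode_sd, classes, weights = w, noise_sd = noise_sd)
}

#' Draw a feature dataset from a mixture specification
#'
#' Each row picks a mode by weight, draws an isotropic Gaussian around the
#' mode mean, adds observation noise of sd `noise_sd`, and inherits the
#' mode's class label. The hidden mode index is kept in `.mode` for
#' distribution-metric oracles.
#'
#' @param spec a [mixture_spec()].
#' @param n number of rows to draw.
#' @param seed integer seed; draws are deterministic given `seed`.
#' @return A tibble with columns `f1..fd`, `label` (0/1) and `.mode`.
#' @examples
#' sim <- simulate_features(ring_mixture_spec(), n = 200, seed = 1)
#' dplyr::count(sim, label)
#' @export
simulate_features <- function(spec, n, seed = 1) {
  if (!inherits(spec, "mixture_spec")) abort_field("spec", "not a mixture_spec")
  n <- check_number(n, "n", lo = 1, integer = TRUE)
  withr::local_seed(seed)
  k <- nrow(spec$means)
  mode <- sample.int(k, n, replace = TRUE, prob = spec$weights)
  x <- spec$means[mode, , drop = FALSE] +
    matrix(stats::rnorm(n * spec$d), n, spec$d) * spec$sds[mode]
  if (spec$noise_sd > 0) {
    x <- x + matrix(stats::rnorm(n * spec$d, sd = spec$noise_sd), n, spec$d)
  }
  colnames(x) <- paste0("f", seq_len(spec$d))
  out <- tibble::as_tibble(x)
  out$label <- spec$classes[mode]
  out$.mode <- mode
  out
}

#' Stratified train/validation/test split tags
#'
#' Adds a `split` column with per-class stratified assignment. Default
#' proportions follow the common 70/15/15 protocol.
#'
#' @param data feature tibble with a `label` column.
#' @param train,val,test nonnegative proportions (normalized to sum to 1).
#' @param seed integer seed.
#' @return `data` with a `split` factor column.
#' @export
assign_splits <- function(data, train = 0.7, val = 0.15, test = 0.15,
                          seed = 1) {
  p <- c(train = train, val = val, test = test)
  if (any(p < 0) || sum(p) <= 0) abort_field("train/val/test", "invalid")
  p <- p / sum(p)
  withr::local_seed(seed)
  split <- character(nrow(data))
  for (cl in unique(data$label)) {
    idx <- which(data$label == cl)
    idx <- sample(idx)
    n_cl <- length(idx)
    n_tr <- round(p[["train"]] * n_cl)
    n_va <- round(p[["val"]] * n_cl)
    split[idx[seq_len(n_tr)]] <- "train"
    split[idx[seq_len(n_va) + n_tr]] <- "val"
    split[idx[seq(n_tr + n_va + 1, length.out = n_cl - n_tr - n_va)]] <- "test"
  }
  data$split <- split
  data
}

# per-class labeled quotas: floor(fraction * n_class) plus largest-remainder
# top-up so the total matches round(fraction * n)
stratified_quota <- function(n_class, fraction) {
  raw <- fraction * n_class
  quota <- floor(raw)
  total <- round(fraction * sum(n_class))
  short <- total - sum(quota)
  if (short > 0) {
    order_rem <- order(raw - quota, decreasing = TRUE)
    quota[order_rem[seq_len(short)]] <- quota[order_rem[seq_len(short)]] + 1
  }
  quota
}

#' Mask labels for semi-supervised training
#'
#' Keeps the labels of a stratified `labeled_fraction` of rows (default 30%,
#' the labeled/unlabeled protocol used for training) and sets the rest to
#' `-1` (unlabeled). Ground truth is retained in a `label_true` column for
#' evaluation oracles only; training never reads it. If a `split` column is
#' present, masking is applied to `train` rows only (validation and test
#' rows keep their labels).
#'
#' @param data feature tibble with `label` in \{0, 1\}.
#' @param labeled_fraction fraction in (0, 1] of rows keeping their label.
#' @param seed integer seed.
#' @return `data` with masked `label` and added `label_true`.
#' @export
split_semisupervised <- function(data, labeled_fraction = 0.3, seed = 1) {
  labeled_fraction <- check_number(labeled_fraction, "labeled_fraction",
                                   lo = 0, hi = 1, open_lo = TRUE)
  if (nrow(data) == 0L) abort_field("data", "is empty")
  if (any(data$label == -1L)) abort_field("data", "already has unlabeled rows")
  withr::local_seed(seed)
  data$label_true <- as.integer(data$label)
  pool <- if ("split" %in% names(data)) which(data$split == "train")
          else seq_len(nrow(data))
  classes <- sort(unique(data$label_true[pool]))
  n_class <- vapply(classes, function(cl) sum(data$label_true[pool] == cl), 1L)
  quota <- stratified_quota(n_class, labeled_fraction)
  keep <- integer(0)
  for (i in seq_along(classes)) {
    idx <- pool[data$label_true[pool] == classes[i]]
    keep <- c(keep, sample(idx)[seq_len(quota[i])])
  }
  mask <- setdiff(pool, keep)
  data$label[mask] <- -1L
  data$label <- as.integer(data$label)
  data
}

#' Stratified k-fold partitions
#'
#' Partitions row indices into `k` folds preserving class proportions to
#' within one sample per fold, the protocol used for cross-validated
#' evaluation on imbalanced melanoma data.
#'
#' @param data feature tibble with `label` column (no unlabeled rows).
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return A list of `k` elements, each `list(train =, test =)` index
#'   vectors; the test sets partition `seq_len(nrow(data))`.
#' @export
stratified_kfold <- function(data, k = 5, seed = 1) {
  k <- check_number(k, "k", lo = 2, integer = TRUE)
  withr::local_seed(seed)
  fold <- integer(nrow(data))
  offset <- 0L # stagger per-class remainders so fold sizes differ by <= 1
  for (cl in unique(data$label)) {
    idx <- which(data$label == cl)
    if (length(idx) < k) {
      abort_field("data", sprintf(
        "class %s has %d members, fewer than k = %d", cl, length(idx), k
      ))
    }
    fold[sample(idx)] <- (seq_along(idx) - 1L + offset) %% k + 1L
    offset <- (offset + length(idx)) %% k
  }
  lapply(seq_len(k), function(f) {
    list(train = which(fold != f), test = which(fold == f))
  })
}

#' Equalize labeled class counts by random oversampling
#'
#' Duplicates labeled minority-class rows (sampled with replacement) until
#' both labeled classes have equal counts; unlabeled rows are untouched.
#' This is the class-imbalance handling applied before training.
#'
#' @param data feature tibble with `label` in \{-1, 0, 1\}.
#' @param seed integer seed.
#' @return `data` with appended duplicated minority rows.
#' @export
oversample_minority <- function(data, seed = 1) {
  lab <- data$label[data$label != -1L]
  counts <- table(factor(lab, levels = c(0L, 1L)))
  if (any(counts == 0L)) {
    abort_field("data", "both classes must be present among labeled rows")
  }
  if (counts[[1]] == counts[[2]]) return(data)
  withr::local_seed(seed)
  minority <- as.integer(names(which.min(counts)))
  extra_n <- abs(counts[[1]] - counts[[2]])
  idx <- which(data$label == minority)
  dplyr::bind_rows(data, data[sample(idx, extra_n, replace = TRUE), ])
}

#' Additive Gaussian feature-space augmentation
#'
#' The augmentation used by consistency regularization: flips/rotations are
#' image-space operations with no meaning on feature vectors, so the
#' admissible "adding Gaussian noise" transformation is used, elementwise
#' with sd `sigma`.
#'
#' @param X numeric matrix (or feature tibble).
#' @param sigma noise standard deviation (>= 0); `0` returns `X` unchanged.
#' @param seed optional integer seed; `NULL` uses the ambient RNG stream.
#' @return A matrix of the same shape as `X`.
#' @export
augment_features <- function(X, sigma = 0.1, seed = NULL) {
  if (is.data.frame(X)) X <- feature_matrix(X)
  X <- check_matrix(X, "X")
  sigma <- check_number(sigma, "sigma", lo = 0)
  if (sigma == 0) return(X)
  if (!is.null(seed)) withr::local_seed(seed)
  X + matrix(stats::rnorm(length(X), sd = sigma), nrow(X), ncol(X))
}

#' Read and write feature datasets as TSV
#'
#' Tab-separated text with header `f1..fd`, `label` and any extra columns
#' (`split`, `label_true`, `.mode`). Numeric values round-trip at 9
#' significant digits.
#'
#' @param data feature tibble.
#' @param path file path.
#' @return `read_feature_tsv()` returns a tibble; `write_feature_tsv()`
#'   returns `path` invisibly.
#' @export
write_feature_tsv <- function(data, path) {
  out <- data
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(x) signif(x, 9))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in intersect(c("label", "label_true", ".mode"), names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  if (!all(out$label %in% c(-1L, 0L, 1L))) {
    abort_field("label", "must be -1, 0 or 1")
  }
  if (any(!is.finite(feature_matrix(out)))) {
    abort_field("features", "contain non-finite values")
  }
  out
}
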