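#' Loss-term weights for the hybrid SS-GAN objective
#'
#' Defaults are the best tuned values reported for the largest dermoscopy
#' benchmark: `lambda_r = 0.42` (generator reconstruction),
#' `lambda_consistency = 0.28`, `lambda_pseudo = 0.41`. The confidence
#' threshold `tau` for pseudo-labeling is not reported; the default 0.9 is
#' the conventional high-confidence cut in the pseudo-labeling literature.
#' Setting all three lambdas to 0 recovers the vanilla SS-GAN objective;
#' the published ablations ("w/o RL/CR/PL") are pure configuration.
#'
#' @param lambda_r reconstruction-loss weight (>= 0).
#' @param lambda_consistency consistency-regularization weight (>= 0).
#' @param lambda_pseudo pseudo-label-loss weight (>= 0).
#' @param tau confidence threshold in (0, 1] for pseudo-label selection.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_r = 0.42, lambda_consistency = 0.28,
                         lambda_pseudo = 0.41, tau = 0.9) {
  structure(
    list(
      lambda_r = check_number(lambda_r, "lambda_r", 0),
      lambda_consistency = check_number(lambda_consistency,
                                        "lambda_consistency", 0),
      lambda_pseudo = check_number(lambda_pseudo, "lambda_pseudo", 0),
      tau = check_number(tau, "tau", 0, 1, open_lo = TRUE)
    ),
    class = "loss_weights"
  )
}

check_probs <- function(probs, field = "probs") {
  probs <- check_matrix(probs, field)
  if (ncol(probs) != 3L) abort_field(field, "must have 3 columns")
  if (any(abs(rowSums(probs) - 1) > 1e-6) || any(probs < -1e-12)) {
    abort_field(field, "rows must be probability vectors")
  }
  probs
}

# column index of the fake class
FAKE <- 3L

# labels in {0 = non-melanoma, 1 = melanoma} map to probability columns
# (1 = melanoma, 2 = non-melanoma)
label_col <- function(labels) ifelse(labels == 1L, 1L, 2L)

#' Supervised discriminator loss on labeled rows
#'
#' Mean negative log-probability the discriminator assigns to the true real
#' class. Probabilities are clamped to `[1e-7, 1 - 1e-7]` before logs.
#'
#' @param probs `m x 3` probability matrix `(melanoma, non_melanoma, fake)`.
#' @param labels integer vector in \{0, 1\}; unlabeled (-1) rows are a
#'   contract violation here.
#' @return Scalar loss >= 0.
#' @export
d_supervised_loss <- function(probs, labels) {
  probs <- check_probs(probs)
  if (any(labels == -1L)) abort_field("labels", "contain unlabeled (-1) rows")
  if (!all(labels %in% c(0L, 1L))) abort_field("labels", "must be 0 or 1")
  if (length(labels) != nrow(probs)) abort_field("labels", "length mismatch")
  p_true <- probs[cbind(seq_len(nrow(probs)), label_col(labels))]
  -mean(log(clamp_prob(p_true)))
}

#' Unsupervised adversarial discriminator loss
#'
#' `-mean log(1 - p_fake)` over real rows plus `-mean log(p_fake)` over
#' generated rows: the discriminator should not assign real samples to the
#' fake class and should assign generated ones to it. The training loop
#' applies the masking rule (only unlabeled rows currently classified as
#' fake enter the first term) upstream of this function. Either argument
#' may be `NULL`/empty, but not both.
#'
#' @param probs_real `m x 3` probabilities on (masked) real rows, or `NULL`.
#' @param probs_fake `k x 3` probabilities on generated rows, or `NULL`.
#' @return Scalar loss (sum of both expectation terms).
#' @export
d_unsupervised_loss <- function(probs_real, probs_fake) {
  n_r <- if (is.null(probs_real)) 0L else nrow(check_probs(probs_real))
  n_f <- if (is.null(probs_fake)) 0L else nrow(check_probs(probs_fake))
  if (n_r + n_f == 0L) abort_field("probs_real/probs_fake", "both empty")
  loss <- 0
  if (n_r > 0L) loss <- loss - mean(log(clamp_prob(1 - probs_real[, FAKE])))
  if (n_f > 0L) loss <- loss - mean(log(clamp_prob(probs_fake[, FAKE])))
  loss
}

#' Generator adversarial loss
#'
#' `-mean log(1 - p_fake)` over generated rows: the generator is rewarded
#' when its samples escape the fake class.
#'
#' @param probs_fake `k x 3` probabilities on generated rows.
#' @return Scalar loss.
#' @export
g_adversarial_loss <- function(probs_fake) {
  probs_fake <- check_probs(probs_fake)
  if (nrow(probs_fake) == 0L) abort_field("probs_fake", "is empty")
  -mean(log(clamp_prob(1 - probs_fake[, FAKE])))
}

#' Generator reconstruction loss
#'
#' Mean over rows of the Euclidean norm `||x_rec - x||_2`, where `x_rec` is
#' the generator's reconstruction `G(D_F(x))` of a real sample from its
#' discriminator-extracted features. Anchoring the generator to real
#' samples in this way counteracts mode collapse.
#'
#' @param x `m x d` real features.
#' @param x_rec `m x d` reconstructions.
#' @return Scalar loss >= 0; zero iff `x_rec == x`.
#' @export
reconstruction_loss <- function(x, x_rec) {
  x <- check_matrix(x, "x")
  x_rec <- check_matrix(x_rec, "x_rec")
  if (!all(dim(x) == dim(x_rec))) {
    abort_field("x_rec", sprintf("shape %dx%d does not match x %dx%d",
                                 nrow(x_rec), ncol(x_rec), nrow(x), ncol(x)))
  }
  mean(sqrt(rowSums((x_rec - x)^2)))
}

#' Total generator loss
#'
#' `adv + lambda_r * rec`. With `lambda_r = 0` this is the conventional
#' SS-GAN generator objective (the "w/o RL" ablation).
#'
#' @param adv adversarial term ([g_adversarial_loss()]).
#' @param rec reconstruction term ([reconstruction_loss()]).
#' @param w a [loss_weights()].
#' @return Scalar loss.
#' @export
g_total_loss <- function(adv, rec, w) {
  adv + w$lambda_r * rec
}

#' Consistency-regularization loss
#'
#' Mean squared Euclidean distance between the discriminator's probability
#' outputs on a sample and on its augmented copy; zero iff predictions are
#' identical, so minimizing it stabilizes predictions under input
#' perturbation.
#'
#' @param probs `m x 3` probabilities on original rows.
#' @param probs_aug `m x 3` probabilities on augmented rows (paired).
#' @return Scalar loss >= 0.
#' @export
consistency_loss <- function(probs, probs_aug) {
  probs <- check_probs(probs)
  probs_aug <- check_probs(probs_aug, "probs_aug")
  if (!all(dim(probs) == dim(probs_aug))) {
    abort_field("probs_aug", "shape does not match probs")
  }
  mean(rowSums((probs - probs_aug)^2))
}

#' Confidence-thresholded pseudo-label loss
#'
#' For unlabeled rows, the pseudo-label is the argmax over the two real
#' classes (a "fake" pseudo-label for a real image is meaningless). A row is
#' selected iff its maximum real-class probability is at least `tau`; the
#' loss is the mean negative log-probability of the pseudo-label over
#' selected rows, and `(0, 0)` when nothing passes the threshold.
#'
#' @param probs `m x 3` probabilities on unlabeled rows.
#' @param tau confidence threshold in (0, 1].
#' @return `list(loss =, n_selected =)`.
#' @export
pseudo_label_loss <- function(probs, tau) {
  probs <- check_probs(probs)
  tau <- check_number(tau, "tau", 0, 1, open_lo = TRUE)
  real <- probs[, 1:2, drop = FALSE]
  conf <- pmax(real[, 1], real[, 2])
  sel <- which(conf >= tau)
  if (length(sel) == 0L) return(list(loss = 0, n_selected = 0L))
  p_pseudo <- conf[sel]
  list(loss = -mean(log(clamp_prob(p_pseudo))), n_selected = length(sel))
}

#' Total discriminator loss
#'
#' `sup + usup + lambda_consistency * cons + lambda_pseudo * pseudo`.
#' Zeroing both lambdas recovers the conventional SS-GAN discriminator.
#'
#' @param sup,usup,cons,pseudo the four component losses.
#' @param w a [loss_weights()].
#' @return Scalar loss.
#' @export
d_total_loss <- function(sup, usup, cons, pseudo, w) {
  sup + usup + w$lambda_consistency * cons + w$lambda_pseudo * pseudo
}
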