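#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of an SS-GAN fit
#'
#' One row per epoch and loss component (long format), ready for faceted
#' plotting.
#'
#' @param x an `ssgan_fit`.
#' @param ... unused.
#' @return A tibble with `epoch`, `term`, `value`.
#' @export
tidy.ssgan_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch",
                      names_to = "term", values_to = "value")
}

#' @rdname tidy.ssgan_fit
#' @export
glance.ssgan_fit <- function(x, ...) {
  last <- dplyr::slice_tail(x$history, n = 1)
  out <- tibble::tibble(
    epochs = nrow(x$history),
    loss_d = last$loss_d, loss_g = last$loss_g
  )
  for (col in intersect(c("val_f_measure", "val_accuracy", "val_auc"),
                        names(last))) {
    out[[col]] <- last[[col]]
  }
  out
}

#' Tidy an ABC optimization trace
#'
#' @param x an `abc_fit`.
#' @param ... unused.
#' @return A tibble with `cycle`, `best_fitness`, `mean_fitness`.
#' @export
tidy.abc_fit <- function(x, ...) x$history

#' @rdname tidy.abc_fit
#' @export
glance.abc_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    cycles = nrow(x$history),
    n_evaluations = x$n_evaluations,
    best_fitness = x$best$fitness
  )
}

#' Plot training loss curves and validation metrics
#'
#' @param object an `ssgan_fit`.
#' @param terms history columns to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ssgan_fit <- function(object,
                               terms = c("loss_d", "loss_g",
                                         "val_f_measure"), ...) {
  df <- tidy(object)
  df <- df[df$term %in% terms & is.finite(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "SS-GAN training history")
}

#' Plot the colony's convergence trace
#'
#' @param object an `abc_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.abc_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"cycle",
                            names_to = "series", values_to = "fitness")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$fitness,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle", y = "fitness",
                  title = "Bee-colony convergence")
}

#' Plot a two-class feature dataset in its first two dimensions
#'
#' @param object a feature tibble (as from [simulate_features()]).
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_features <- function(object, ...) {
  df <- tibble::tibble(
    f1 = object$f1, f2 = object$f2,
    label = factor(object$label, c(-1, 0, 1),
                   c("unlabeled", "non-melanoma", "melanoma"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f1, y = .data$f2,
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(title = "Feature dataset (first two dimensions)")
}
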