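# broom-style tidiers and autoplot methods for fitted objects.

#' Tidy a trained model fit
#'
#' @param x A `catsite_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `lambda`,
#'   `contrastive_loss`, `supervised_loss`).
#' @export
tidy.catsite_fit <- function(x, ...) x$history

#' @rdname tidy.catsite_fit
#' @export
glance.catsite_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    epochs = nrow(x$history),
    final_supervised_loss = last$supervised_loss,
    final_contrastive_loss = last$contrastive_loss,
    pos_weight = x$pos_weight,
    prevalence = x$prevalence,
    n_parameters = sum(vapply(x$model$params, length, numeric(1))))
}

#' Loss curves of a training run
#'
#' Both loss components per epoch, with the contrastive-to-supervised
#' phase boundary visible where `lambda` reaches zero.
#'
#' @param object A `catsite_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.catsite_fit <- function(object, ...) {
  h <- object$history |>
    tidyr::pivot_longer(c("contrastive_loss", "supervised_loss"),
                        names_to = "component", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean loss", color = NULL)
}

#' Tidy a triage-tree fit
#'
#' @param x A `triage_fit`.
#' @param ... Unused.
#' @return Per-fold cross-validation tibble.
#' @export
tidy.triage_fit <- function(x, ...) x$cv

#' @rdname tidy.triage_fit
#' @export
glance.triage_fit <- function(x, ...) {
  tibble::tibble(cv_accuracy = x$cv_accuracy,
                 cv_precision = x$cv_precision,
                 train_accuracy = x$train_accuracy,
                 train_precision = x$train_precision,
                 depth = x$depth, folds = x$folds)
}

#' Decision regions of the triage tree
#'
#' Scatter of the two triage features colored by predicted class.
#'
#' @param object A `triage_fit`.
#' @param features Feature tibble used for the fit (with `distance`,
#'   `accessibility`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.triage_fit <- function(object, features, ...) {
  features <- tibble::as_tibble(features)
  features$predicted <- predict(object$tree, features, type = "class")
  ggplot2::ggplot(features,
                  ggplot2::aes(x = .data$distance, y = .data$accessibility,
                               color = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "distance to nearest predicted catalytic residue (Å)",
                  y = "relative accessibility", color = "call")
}

#' Propensity profile along the chain
#'
#' Per-residue catalytic propensity for one or more enzymes, with native
#' catalytic residues marked.
#'
#' @param preds Prediction tibble from [predict.catsite_model()].
#' @return A ggplot object.
#' @export
plot_propensity <- function(preds) {
  preds <- dplyr::mutate(preds,
                         position = as.integer(factor(
                           .data$residue_number,
                           levels = unique(.data$residue_number))))
  ggplot2::ggplot(preds, ggplot2::aes(x = .data$position,
                                      y = .data$propensity)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(data = dplyr::filter(preds, .data$label == 1),
                        color = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$enzyme)) +
    ggplot2::labs(x = "residue", y = "catalytic propensity")
}
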