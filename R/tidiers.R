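#' Tidy a trained model's training history
#'
#' @param x An `ionm_model`.
#' @param ... Unused.
#' @return The per-epoch history in long form: `epoch`, `metric`, `value`.
#' @export
tidy.ionm_model <- function(x, ...) {
  if (is.null(x$history)) abort("model has no training history")
  x$history |>
    tidyr::pivot_longer(-"epoch", names_to = "metric", values_to = "value")
}

#' One-row summary of a trained model
#'
#' @param x An `ionm_model`.
#' @param ... Unused.
#' @return A one-row tibble with the best epoch and its metrics.
#' @export
glance.ionm_model <- function(x, ...) {
  if (!x$trained) {
    return(tibble::tibble(trained = FALSE, n_features = nrow(x$layout)))
  }
  hb <- x$history[x$best_epoch, ]
  tibble::tibble(
    trained = TRUE, n_features = nrow(x$layout),
    epochs = nrow(x$history), best_epoch = x$best_epoch,
    val_loss = hb$val_loss,
    val_acc_nerve = hb$val_acc_nerve, val_acc_side = hb$val_acc_side,
    val_acc_position = hb$val_acc_position
  )
}

#' Tidy a calibration table
#'
#' @param x An `ionm_calibration`.
#' @param ... Unused.
#' @return The per-cell tibble (head, class, n, mu, sigma, flags).
#' @export
tidy.ionm_calibration <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' Tidy a confusion matrix
#'
#' @param x An `ionm_confusion`.
#' @param ... Unused.
#' @return Long tibble with `reference`, `predicted`, `n`.
#' @export
tidy.ionm_confusion <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' Heatmap of a confusion matrix
#'
#' @param object An `ionm_confusion`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ionm_confusion <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$reference,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "predicted", y = "reference", fill = "records") +
    ggplot2::theme_minimal()
}

#' Density plot of calibrated uncertainty by outcome category
#'
#' @param object An `ionm_outcomes`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ionm_outcomes <- function(object, ...) {
  df <- dplyr::filter(object$records, !is.na(.data$calibrated))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$calibrated,
                                   colour = .data$category)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "calibrated uncertainty", y = "density",
                  colour = "category") +
    ggplot2::theme_minimal()
}

#' Training-history curves
#'
#' @param model A trained `ionm_model`.
#' @return A ggplot of losses and head accuracies over epochs.
#' @export
plot_training_history <- function(model) {
  df <- tidy(model)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ grepl("loss", .data$metric), scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(`TRUE` = "loss", `FALSE` = "accuracy / lr"))) +
    ggplot2::theme_minimal()
}
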