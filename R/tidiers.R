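# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained node model: per-epoch loss history
#'
#' @param x A `gait_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `val_loss`.
#' @method tidy gait_model
#' @export
tidy.gait_model <- function(x, ...) x$history

#' One-row summary of a trained node model
#'
#' @param x A `gait_model`.
#' @param ... Unused.
#' @return Tibble with node, architecture counts, data sizes, epochs and
#'   validation AUC.
#' @method glance gait_model
#' @export
glance.gait_model <- function(x, ...) {
  n_par <- sum(vapply(x$net$layers, function(l)
    sum(vapply(l$params, length, numeric(1))), numeric(1)))
  tibble::tibble(
    node = x$node,
    window_length = x$config$window_length,
    n_channels = length(x$config$channels),
    n_dense_layers = x$config$n_dense_layers,
    use_conv = x$config$use_conv,
    use_lstm = x$config$use_lstm,
    n_parameters = n_par,
    n_train = x$n_train %||% NA_integer_,
    epochs = nrow(x$history),
    validation_auc = x$validation_auc
  )
}

#' Tidy cascade metrics: per-event one-vs-rest AUCs
#' @param x A `gait_cascade_metrics`.
#' @param ... Unused.
#' @return Tibble with `event`, `auc`, `n_positive`.
#' @method tidy gait_cascade_metrics
#' @export
tidy.gait_cascade_metrics <- function(x, ...) x$per_event

#' One-row summary of cascade performance
#' @param x A `gait_cascade_metrics`.
#' @param ... Unused.
#' @return Tibble with `accuracy`, `macro_auc`, `n`.
#' @method glance gait_cascade_metrics
#' @export
glance.gait_cascade_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_auc = x$macro_auc, n = x$n)
}

#' Training-history curve for a node model
#'
#' @param object A `gait_model`.
#' @param ... Unused.
#' @return A ggplot of train and validation loss by epoch.
#' @method autoplot gait_model
#' @export
autoplot.gait_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = paste0("Training history: ", object$node),
                  x = "epoch", y = "cross-entropy") +
    ggplot2::theme_minimal()
}

#' Confusion heat map for cascade metrics
#'
#' @param object A `gait_cascade_metrics`.
#' @param ... Unused.
#' @return A ggplot of the 6 x 6 confusion matrix (truth in rows).
#' @method autoplot gait_cascade_metrics
#' @export
autoplot.gait_cascade_metrics <- function(object, ...) {
  df <- tibble::as_tibble(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(gait_events())) +
    ggplot2::labs(title = "Cascade confusion (truth in rows)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Channel traces of one recording
#'
#' @param recordings Nested recordings tibble.
#' @param recording_id Recording to plot (default: first).
#' @param channels Channels to show (default: four pressure sensors and the
#'   vertical acceleration).
#' @return A ggplot with one facet per channel.
#' @export
plot_recording <- function(recordings, recording_id = NULL,
                           channels = c("p0", "p5", "p10", "p15", "az")) {
  recording_id <- recording_id %||% recordings$recording_id[[1]]
  row <- recordings[recordings$recording_id == recording_id, ]
  stopifnot(nrow(row) == 1)
  channels <- normalize_channels(channels)
  df <- row$frames[[1]][, c("timestamp", channels)] |>
    tidyr::pivot_longer(-"timestamp", names_to = "channel",
                        values_to = "value")
  df$channel <- factor(df$channel, levels = gait_channels())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timestamp, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(title = paste0(recording_id, " (", row$event, ")"),
                  x = NULL, y = "device units") +
    ggplot2::theme_minimal()
}
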