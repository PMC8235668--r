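# Model configuration, network assembly, cross-entropy training.

#' Binary classifier configuration
#'
#' One point in the architecture/optimizer search space: a stack of 1-11
#' hidden dense (or time-distributed dense) layers of 1-64 units with tanh
#' or selu activations, optionally preceded by a 1-D convolution (1-50
#' filters, kernel 2-32, selu or sigmoid, optional max pooling) or an LSTM
#' (1-50 units); learning rate in \{0.1, 0.01, 0.001\}; optimizer sgd, adam
#' or rmsprop; batch size 1-50; window length 4-32; and a channel subset.
#' The output head is always a single sigmoid unit.
#'
#' @param n_dense_layers Number of hidden dense layers, 1-11.
#' @param units Integer vector of layer widths (length `n_dense_layers`),
#'   each 1-64.
#' @param activations Character vector (`"tanh"`/`"selu"`), recycled to
#'   `n_dense_layers` if length 1.
#' @param use_conv,conv_filters,conv_window,conv_activation,use_pooling
#'   Convolutional front end (see above).
#' @param use_lstm,lstm_units Recurrent front end.
#' @param learning_rate One of 0.1, 0.01, 0.001.
#' @param optimizer `"sgd"`, `"adam"` or `"rmsprop"`.
#' @param batch_size Minibatch size, 1-50.
#' @param window_length Input window length `w`, 4-32.
#' @param channels Input channel subset (device-style `P0`/`A0` names
#'   accepted).
#' @param dropout Dropout rate after each hidden dense layer (default 0.2).
#' @return A `gait_model_config` list.
#' @export
model_config <- function(n_dense_layers = 1, units = 32,
                         activations = "selu",
                         use_conv = FALSE, conv_filters = NULL,
                         conv_window = NULL, conv_activation = NULL,
                         use_pooling = FALSE,
                         use_lstm = FALSE, lstm_units = NULL,
                         learning_rate = 0.01, optimizer = "adam",
                         batch_size = 32, window_length = 16,
                         channels = gait_channels(), dropout = 0.2) {
  bad <- function(msg) rlang::abort(msg, class = "gait_config_error")
  if (length(units) == 1 && n_dense_layers > 1)
    units <- rep(units, n_dense_layers)
  if (length(activations) == 1)
    activations <- rep(activations, n_dense_layers)
  if (n_dense_layers < 1 || n_dense_layers > 11)
    bad("n_dense_layers must lie in [1, 11]")
  if (length(units) != n_dense_layers)
    bad(paste0("units has length ", length(units), " but n_dense_layers is ",
               n_dense_layers))
  if (length(activations) != n_dense_layers)
    bad("activations must have one entry per dense layer")
  if (any(units < 1 | units > 64)) bad("units must lie in [1, 64]")
  if (!all(activations %in% c("tanh", "selu")))
    bad("activations must be 'tanh' or 'selu'")
  if (use_conv) {
    if (is.null(conv_filters) || conv_filters < 1 || conv_filters > 50)
      bad("conv_filters must lie in [1, 50]")
    if (is.null(conv_window) || conv_window < 2 || conv_window > 32)
      bad("conv_window must lie in [2, 32]")
    if (!conv_activation %in% c("selu", "sigmoid"))
      bad("conv_activation must be 'selu' or 'sigmoid'")
  }
  if (use_lstm && (is.null(lstm_units) || lstm_units < 1 || lstm_units > 50))
    bad("lstm_units must lie in [1, 50]")
  if (!learning_rate %in% c(0.1, 0.01, 0.001))
    bad("learning_rate must be one of 0.1, 0.01, 0.001")
  if (!optimizer %in% c("sgd", "adam", "rmsprop"))
    bad("optimizer must be 'sgd', 'adam' or 'rmsprop'")
  if (batch_size < 1 || batch_size > 50) bad("batch_size must lie in [1, 50]")
  if (window_length < 4 || window_length > 32)
    bad("window_length must lie in [4, 32]")
  channels <- normalize_channels(channels)
  if (length(channels) == 0) bad("channels must be non-empty")
  channels <- gait_channels()[gait_channels() %in% channels]
  cfg <- list(
    n_dense_layers = as.integer(n_dense_layers),
    units = as.integer(units), activations = activations,
    use_conv = isTRUE(use_conv),
    conv_filters = if (use_conv) as.integer(conv_filters),
    conv_window = if (use_conv) as.integer(conv_window),
    conv_activation = if (use_conv) conv_activation,
    use_pooling = isTRUE(use_pooling),
    use_lstm = isTRUE(use_lstm),
    lstm_units = if (use_lstm) as.integer(lstm_units),
    learning_rate = learning_rate, optimizer = optimizer,
    batch_size = as.integer(batch_size),
    window_length = as.integer(window_length),
    channels = channels, dropout = dropout
  )
  class(cfg) <- "gait_model_config"
  cfg
}

#' Assemble an untrained network from a configuration
#'
#' Layer order is: optional 1-D convolution over time (plus optional max
#' pooling, size 2), then optional LSTM, then the dense stack, then the
#' single sigmoid output unit. When neither a convolutional nor an LSTM
#' front end is used, the hidden dense layers are time-distributed over the
#' window and the result flattened before the output unit.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialisation.
#' @param clamp_conv If `TRUE`, a convolution window longer than the input
#'   window is clamped to the input window (with a `conv_clamped` attribute)
#'   instead of raising an error.
#' @return A `gait_network` (untrained) with an `input_shape` of
#'   `c(window_length, n_channels)`.
#' @export
build_network <- function(config, seed = 1, clamp_conv = FALSE) {
  stopifnot(inherits(config, "gait_model_config"))
  w <- config$window_length
  nc <- length(config$channels)
  clamped <- FALSE
  kernel <- config$conv_window
  if (config$use_conv && kernel > w) {
    if (!clamp_conv) {
      rlang::abort(paste0("conv_window (", kernel,
                          ") exceeds window_length (", w, ")"),
                   class = "gait_config_error")
    }
    kernel <- w
    clamped <- TRUE
  }
  layers <- list()
  net <- with_seed(seed, {
    t_dim <- w; c_dim <- nc
    if (config$use_conv) {
      layers[[length(layers) + 1]] <-
        layer_conv(c_dim, config$conv_filters, kernel,
                   config$conv_activation)
      t_dim <- t_dim - kernel + 1
      c_dim <- config$conv_filters
      if (config$use_pooling) {
        if (t_dim >= 2) {
          layers[[length(layers) + 1]] <- layer_pool()
          t_dim <- t_dim %/% 2
        }
      }
    }
    if (config$use_lstm) {
      layers[[length(layers) + 1]] <- layer_lstm(c_dim, config$lstm_units)
      d_in <- config$lstm_units
      for (i in seq_len(config$n_dense_layers)) {
        layers[[length(layers) + 1]] <-
          layer_dense(d_in, config$units[i], config$activations[i],
                      config$dropout)
        d_in <- config$units[i]
      }
    } else if (config$use_conv) {
      layers[[length(layers) + 1]] <- layer_flatten()
      d_in <- t_dim * c_dim
      for (i in seq_len(config$n_dense_layers)) {
        layers[[length(layers) + 1]] <-
          layer_dense(d_in, config$units[i], config$activations[i],
                      config$dropout)
        d_in <- config$units[i]
      }
    } else {
      for (i in seq_len(config$n_dense_layers)) {
        layers[[length(layers) + 1]] <-
          layer_td_dense(c_dim, config$units[i], config$activations[i],
                         config$dropout)
        c_dim <- config$units[i]
      }
      layers[[length(layers) + 1]] <- layer_flatten()
      d_in <- t_dim * c_dim
    }
    layers[[length(layers) + 1]] <- layer_dense(d_in, 1L, "linear", 0)
    list(layers = layers, config = config, input_shape = c(w, nc))
  })
  class(net) <- "gait_network"
  attr(net, "conv_clamped") <- clamped
  net
}

#' Binary cross-entropy
#'
#' Mean negative log-likelihood of binary labels under predicted
#' probabilities, with natural logarithms and probabilities clipped to
#' `[eps, 1 - eps]`:
#' \deqn{E = -\frac{1}{N}\sum_i y_i \log p_i + (1-y_i)\log(1-p_i).}
#'
#' @param labels 0/1 vector.
#' @param probabilities Vector of predicted probabilities of class 1.
#' @param eps Clipping constant (default `1e-7`).
#' @return Non-negative scalar.
#' @export
#' @examples
#' cross_entropy(c(1, 0), c(0.5, 0.5))  # log(2)
cross_entropy <- function(labels, probabilities, eps = 1e-7) {
  if (length(labels) != length(probabilities)) {
    rlang::abort("labels and probabilities must have equal length",
                 class = "gait_schema_error")
  }
  stopifnot(length(labels) >= 1)
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Extract model-ready arrays from a windows tibble for a given config:
# subset/reorder channels, check the window length.
windows_model_array <- function(windows, config) {
  if (nrow(windows) == 0) {
    rlang::abort("No windows supplied", class = "gait_schema_error")
  }
  w <- nrow(windows$values[[1]])
  if (w != config$window_length) {
    rlang::abort(paste0("Windows have length ", w,
                        " but the model expects ", config$window_length),
                 class = "gait_config_error")
  }
  have <- colnames(windows$values[[1]])
  missing <- setdiff(config$channels, have)
  if (length(missing) > 0) {
    rlang::abort(paste0("Windows lack model channel(s): ",
                        paste(missing, collapse = ", ")),
                 class = "gait_config_error")
  }
  x <- windows_to_array(windows)
  x[, , config$channels, drop = FALSE]
}

scale_array <- function(x, scaler) {
  for (j in seq_len(dim(x)[3])) {
    x[, , j] <- (x[, , j] - scaler$mean[j]) / scaler$sd[j]
  }
  x
}

#' Train a binary node classifier
#'
#' Optimises the cross-entropy loss with the configured optimizer, learning
#' rate and batch size; applies dropout after hidden dense layers; stops
#' early when the validation loss has not improved for `patience` epochs and
#' restores the best-epoch weights; records the validation AUC of the
#' restored model. Channels are z-scored with statistics fitted on the
#' training partition (stored in the model and reapplied at prediction).
#'
#' @param windows Relabelled, split windows tibble (`label` and `split`
#'   columns; see [relabel_binary()] and [stratified_split()]) whose window
#'   length matches `config$window_length`.
#' @param config A [model_config()].
#' @param patience Early-stopping patience in epochs (default 10).
#' @param max_epochs Maximum epochs (default 100).
#' @param seed Integer seed (weight init, shuffling, dropout).
#' @param clamp_conv Passed to [build_network()].
#' @param class_weights Optional length-2 vector weighting classes 0 and 1
#'   in the loss (default unweighted).
#' @return A `gait_model`: config, learned weights, per-epoch loss history,
#'   `validation_auc`.
#' @export
train_node <- function(windows, config, patience = 10, max_epochs = 100,
                       seed = 1, clamp_conv = FALSE, class_weights = NULL) {
  stopifnot(inherits(config, "gait_model_config"))
  if (!all(c("label", "split") %in% names(windows))) {
    rlang::abort("windows must carry 'label' and 'split' columns",
                 class = "gait_schema_error")
  }
  node <- attr(windows, "node") %||% "binary"
  tr <- windows[windows$split == "train", ]
  va <- windows[windows$split == "validation", ]
  if (nrow(tr) == 0 || nrow(va) == 0) {
    rlang::abort(paste0("Node '", node,
                        "': empty training or validation partition"),
                 class = "gait_schema_error")
  }
  if (length(unique(tr$label)) < 2) {
    rlang::abort(paste0("Node '", node,
                        "': training partition contains a single class"),
                 class = "gait_schema_error")
  }
  x_tr <- windows_model_array(tr, config)
  x_va <- windows_model_array(va, config)
  y_tr <- tr$label
  y_va <- va$label
  scaler <- list(
    mean = apply(x_tr, 3, mean),
    sd = pmax(apply(x_tr, 3, stats::sd), 1e-6)
  )
  x_tr <- scale_array(x_tr, scaler)
  x_va <- scale_array(x_va, scaler)
  wts <- if (is.null(class_weights)) c(1, 1) else class_weights
  net <- build_network(config, seed = seed, clamp_conv = clamp_conv)
  opt <- opt_init(net, config$optimizer, config$learning_rate)
  n <- length(y_tr)
  best_val <- Inf; best_w <- net_weights(net); wait <- 0L
  history <- vector("list", max_epochs)
  with_seed(derive_seed(seed, 13), {
    for (epoch in seq_len(max_epochs)) {
      idx <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        bi <- idx[start:min(n, start + config$batch_size - 1L)]
        xb <- x_tr[bi, , , drop = FALSE]
        yb <- y_tr[bi]
        fw <- nn_forward(net, xb, training = TRUE)
        p <- sigmoid(fw$logit)
        wvec <- wts[yb + 1]
        batch_losses <- c(batch_losses,
                          cross_entropy(yb, p))
        dlogit <- wvec * (p - yb) / length(yb)
        grads <- nn_backward(net, fw$caches, dlogit)
        step <- opt_step(net, grads, opt)
        net <- step$net; opt <- step$state
      }
      p_va <- sigmoid(nn_forward(net, x_va)$logit)
      val_loss <- cross_entropy(y_va, p_va)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = mean(batch_losses), val_loss = val_loss)
      if (val_loss < best_val - 1e-8) {
        best_val <- val_loss
        best_w <- net_weights(net)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })
  net <- set_net_weights(net, best_w)
  p_va <- sigmoid(nn_forward(net, x_va)$logit)
  val_auc <- if (length(unique(y_va)) < 2) NA_real_ else auc_score(y_va, p_va)
  model <- list(
    config = config, net = net, scaler = scaler, node = node,
    history = dplyr::bind_rows(history),
    validation_auc = val_auc,
    n_train = n, n_validation = length(y_va), seed = seed
  )
  class(model) <- "gait_model"
  model
}

#' Predict class-1 probabilities from a trained node model
#'
#' @param object A `gait_model`.
#' @param newdata A windows tibble, an `N x w x c` array (channels named in
#'   canonical order), or a single `w x c` matrix.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.gait_model <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) {
    windows_model_array(newdata, object$config)
  } else if (is.matrix(newdata)) {
    a <- array(newdata, dim = c(1, nrow(newdata), ncol(newdata)))
    dimnames(a) <- list(NULL, NULL, colnames(newdata))
    a[, , object$config$channels, drop = FALSE]
  } else {
    newdata[, , object$config$channels, drop = FALSE]
  }
  x <- scale_array(x, object$scaler)
  sigmoid(nn_forward(object$net, x)$logit)
}

#' @export
print.gait_model <- function(x, ...) {
  cat("<gait_model> node:", x$node, "\n")
  cat("  window", x$config$window_length, "x",
      length(x$config$channels), "channels;",
      x$config$n_dense_layers, "dense layer(s)",
      if (x$config$use_conv) "+ conv" else "",
      if (x$config$use_lstm) "+ lstm" else "", "\n")
  cat("  epochs trained:", nrow(x$history),
      " validation AUC:", round(x$validation_auc, 4), "\n")
  invisible(x)
}
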