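# Hyperparameter search over the architecture space, ranked model registry,
# sensor-failure fallback selection.

#' The architecture search space
#'
#' Ranges for every searchable parameter: hidden layer count and widths,
#' activations, convolutional and LSTM front ends, learning rate, optimizer,
#' batch size, window length and the per-channel input mask. Individual
#' ranges can be narrowed (e.g. for quick searches) by passing replacement
#' entries.
#'
#' @param ... Named replacements for individual space entries.
#' @return A `gait_search_space` list.
#' @export
search_space <- function(...) {
  space <- list(
    n_dense_layers = c(1L, 11L),
    units = c(1L, 64L),
    activations = c("tanh", "selu"),
    use_conv = c(FALSE, TRUE),
    conv_filters = c(1L, 50L),
    conv_window = c(2L, 32L),
    conv_activation = c("selu", "sigmoid"),
    use_pooling = c(FALSE, TRUE),
    use_lstm = c(FALSE, TRUE),
    lstm_units = c(1L, 50L),
    learning_rate = c(0.1, 0.01, 0.001),
    optimizer = c("sgd", "adam", "rmsprop"),
    batch_size = c(1L, 50L),
    window_length = c(4L, 32L),
    channel_prob = 0.5
  )
  override <- list(...)
  for (nm in names(override)) {
    if (!nm %in% names(space)) {
      rlang::abort(paste0("Unknown search-space entry: ", nm),
                   class = "gait_config_error")
    }
    space[[nm]] <- override[[nm]]
  }
  class(space) <- "gait_search_space"
  space
}

rint <- function(lo_hi) {
  if (lo_hi[1] == lo_hi[2]) return(lo_hi[1])
  sample(seq.int(lo_hi[1], lo_hi[2]), 1)
}
rchoice <- function(v) if (length(v) == 1) v else v[sample.int(length(v), 1)]

# Draw one configuration uniformly from the space (current RNG stream).
sample_config <- function(space) {
  w <- rint(space$window_length)
  nd <- rint(space$n_dense_layers)
  use_conv <- rchoice(space$use_conv)
  use_lstm <- rchoice(space$use_lstm)
  ch_mask <- stats::runif(20) < space$channel_prob
  if (!any(ch_mask)) ch_mask[sample.int(20, 1)] <- TRUE
  model_config(
    n_dense_layers = nd,
    units = vapply(seq_len(nd), function(i) rint(space$units), integer(1)),
    activations = vapply(seq_len(nd), function(i)
      rchoice(space$activations), character(1)),
    use_conv = use_conv,
    conv_filters = if (use_conv) rint(space$conv_filters),
    conv_window = if (use_conv)
      rint(c(space$conv_window[1], min(space$conv_window[2], w))),
    conv_activation = if (use_conv) rchoice(space$conv_activation),
    use_pooling = if (use_conv) rchoice(space$use_pooling) else FALSE,
    use_lstm = use_lstm,
    lstm_units = if (use_lstm) rint(space$lstm_units),
    learning_rate = rchoice(space$learning_rate),
    optimizer = rchoice(space$optimizer),
    batch_size = rint(space$batch_size),
    window_length = w,
    channels = gait_channels()[ch_mask]
  )
}

# ---- tree-structured Parzen estimator (independent per-parameter) ----

config_features <- function(config) {
  ch <- as.integer(gait_channels() %in% config$channels)
  c(list(
    n_dense_layers = config$n_dense_layers,
    mean_units = mean(config$units),
    use_conv = as.integer(config$use_conv),
    use_lstm = as.integer(config$use_lstm),
    learning_rate = config$learning_rate,
    optimizer = config$optimizer,
    batch_size = config$batch_size,
    window_length = config$window_length
  ), stats::setNames(as.list(ch), paste0("ch_", gait_channels())))
}

tpe_numeric <- function(good, bad, lo, hi, n_candidates = 24) {
  if (length(good) == 0) return(stats::runif(1, lo, hi))
  bw <- max((hi - lo) / 6, 1e-6)
  dens <- function(x, centers) {
    if (length(centers) == 0) return(rep(1 / (hi - lo), length(x)))
    rowMeans(outer(x, centers, function(a, b) stats::dnorm(a, b, bw))) +
      1e-12
  }
  cand <- stats::rnorm(n_candidates, sample(good, n_candidates, replace = TRUE),
                       bw)
  cand <- pmin(pmax(cand, lo), hi)
  cand[which.max(dens(cand, good) / dens(cand, bad))]
}

tpe_categorical <- function(good, bad, choices) {
  pg <- (table(factor(good, levels = as.character(choices))) + 1)
  pb <- (table(factor(bad, levels = as.character(choices))) + 1)
  as.character(choices)[which.max(as.numeric(pg) / as.numeric(pb))]
}

# Suggest the next configuration given trial history (features + value).
tpe_suggest <- function(history, space, n_startup = 8, gamma = 0.3) {
  if (is.null(history) || nrow(history) < n_startup) {
    return(sample_config(space))
  }
  ord <- order(-history$value)
  n_good <- max(1, ceiling(gamma * nrow(history)))
  good <- history[ord[seq_len(n_good)], ]
  bad <- history[ord[-seq_len(n_good)], ]
  num <- function(col, lo_hi) {
    round(tpe_numeric(good[[col]], bad[[col]], lo_hi[1], lo_hi[2]))
  }
  cat_ <- function(col, choices) tpe_categorical(good[[col]], bad[[col]], choices)
  w <- as.integer(num("window_length", space$window_length))
  nd <- as.integer(max(space$n_dense_layers[1],
                       min(space$n_dense_layers[2],
                           num("n_dense_layers", space$n_dense_layers))))
  mu <- max(space$units[1],
            min(space$units[2], num("mean_units", space$units)))
  use_conv <- cat_("use_conv", c(0, 1)) == "1" && isTRUE(any(space$use_conv))
  use_lstm <- cat_("use_lstm", c(0, 1)) == "1" && isTRUE(any(space$use_lstm))
  ch_mask <- vapply(gait_channels(), function(ch) {
    cat_(paste0("ch_", ch), c(0, 1)) == "1"
  }, logical(1))
  if (!any(ch_mask)) ch_mask[sample.int(20, 1)] <- TRUE
  model_config(
    n_dense_layers = nd,
    units = pmin(64L, pmax(1L, as.integer(round(
      mu * stats::runif(nd, 0.6, 1.4))))),
    activations = vapply(seq_len(nd), function(i)
      rchoice(space$activations), character(1)),
    use_conv = use_conv,
    conv_filters = if (use_conv) rint(space$conv_filters),
    conv_window = if (use_conv)
      rint(c(space$conv_window[1], min(space$conv_window[2], w))),
    conv_activation = if (use_conv) rchoice(space$conv_activation),
    use_pooling = if (use_conv) rchoice(space$use_pooling) else FALSE,
    use_lstm = use_lstm,
    lstm_units = if (use_lstm) rint(space$lstm_units),
    learning_rate = as.numeric(cat_("learning_rate", space$learning_rate)),
    optimizer = cat_("optimizer", space$optimizer),
    batch_size = as.integer(max(space$batch_size[1],
                                min(space$batch_size[2],
                                    num("batch_size", space$batch_size)))),
    window_length = max(4L, min(32L, w)),
    channels = gait_channels()[ch_mask]
  )
}

# ---- registry ----

#' An empty ranked model registry
#'
#' The registry keeps, per cascade node, every trained model sorted by
#' validation AUC (descending, earlier insertion wins ties) together with
#' its input channel subset — the structure that makes sensor-failure
#' fallback possible.
#'
#' @return An empty registry tibble.
#' @export
new_registry <- function() {
  tibble::tibble(node = character(0), rank = integer(0),
                 validation_auc = numeric(0), window = integer(0),
                 channels = list(), model = list())
}

#' Insert a trained model into the registry
#'
#' @param registry A registry tibble.
#' @param model A `gait_model` (or a function model from
#'   [function_model()]).
#' @param node Node name; defaults to the model's own node.
#' @return The registry with ranks recomputed (stable sort on validation
#'   AUC, descending).
#' @export
registry_insert <- function(registry, model, node = NULL) {
  node <- node %||% model$node
  auc <- model$validation_auc %||% NA_real_
  row <- tibble::tibble(
    node = node, rank = NA_integer_, validation_auc = auc,
    window = model$config$window_length %||% model$window_length,
    channels = list(model$config$channels %||% model$channels),
    model = list(model)
  )
  out <- dplyr::bind_rows(registry, row)
  out |>
    dplyr::group_by(.data$node) |>
    dplyr::mutate(rank = {
      ord <- order(-.data$validation_auc)  # stable: earlier insertion wins
      r <- integer(length(ord)); r[ord] <- seq_along(ord); r
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$node, .data$rank)
}

#' Best registered model avoiding failed channels
#'
#' Implements the sensor-failure fallback: among a node's models ranked by
#' validation AUC, returns the best one whose input channels are disjoint
#' from the failed set, keeping the detector alive when a sensor dies.
#'
#' @param registry A registry tibble.
#' @param node Node name.
#' @param failed_channels Character vector of failed channel names (any
#'   case).
#' @return The selected model.
#' @export
best_without <- function(registry, node, failed_channels = character(0)) {
  if (length(failed_channels) > 0)
    failed_channels <- normalize_channels(failed_channels)
  rows <- registry[registry$node == node, ]
  if (nrow(rows) == 0) {
    rlang::abort(paste0("Node unavailable: no model registered for '",
                        node, "'"),
                 class = "gait_node_unavailable")
  }
  rows <- rows[order(rows$rank), ]
  ok <- vapply(rows$channels, function(ch) {
    length(intersect(normalize_channels(ch), failed_channels)) == 0
  }, logical(1))
  if (!any(ok)) {
    rlang::abort(paste0("Node unavailable: every model for '", node,
                        "' uses a failed channel (",
                        paste(failed_channels, collapse = ", "), ")"),
                 class = "gait_node_unavailable")
  }
  rows$model[[which(ok)[1]]]
}

#' Search configurations for one cascade node
#'
#' Samples `n_trials` configurations (uniformly at random, or with a
#' tree-structured Parzen estimator that models good-vs-bad trials per
#' parameter), trains each with [train_node()], and inserts every result
#' into the registry ranked by validation AUC. Windows are rebuilt per trial
#' because window length is itself searched; the train/validation/test
#' split uses one fixed seed so trials are comparable.
#'
#' @param recordings Nested recordings tibble.
#' @param node Cascade node name.
#' @param n_trials Number of trials (>= 1).
#' @param sampler `"random"` or `"tpe"`.
#' @param seed Integer seed (drives sampling and per-trial training seeds).
#' @param space A [search_space()].
#' @param registry Registry to extend (default empty).
#' @param split_seed Seed of the stratified split (default `seed`).
#' @param patience,max_epochs Passed to [train_node()].
#' @param stride Window stride.
#' @return List with `registry` (updated) and `trials` (tibble with one row
#'   per trial: sampled parameters and validation AUC).
#' @export
run_search <- function(recordings, node, n_trials = 10,
                       sampler = c("random", "tpe"), seed = 1,
                       space = search_space(), registry = new_registry(),
                       split_seed = seed, patience = 5, max_epochs = 30,
                       stride = 1) {
  sampler <- match.arg(sampler)
  stopifnot(n_trials >= 1)
  window_cache <- new.env(parent = emptyenv())
  history <- NULL
  trial_rows <- vector("list", n_trials)
  failures <- character(0)
  for (trial in seq_len(n_trials)) {
    config <- with_seed(derive_seed(seed, 101, trial), {
      if (sampler == "random") sample_config(space)
      else tpe_suggest(history, space)
    })
    key <- paste0("w", config$window_length, "s", stride)
    if (!exists(key, envir = window_cache)) {
      win <- build_windows(recordings, window = config$window_length,
                           stride = stride)
      win <- stratified_split(win, seed = split_seed)
      assign(key, win, envir = window_cache)
    }
    win <- get(key, envir = window_cache)
    labelled <- relabel_binary(win, node)
    fit <- tryCatch(
      train_node(labelled, config, patience = patience,
                 max_epochs = max_epochs,
                 seed = derive_seed(seed, 202, trial)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      failures <- c(failures,
                    paste0("trial ", trial, ": ", conditionMessage(fit)))
      next
    }
    registry <- registry_insert(registry, fit, node = node)
    feat <- config_features(config)
    feat$value <- fit$validation_auc
    feat$trial <- trial
    trial_rows[[trial]] <- tibble::as_tibble(feat)
    history <- dplyr::bind_rows(history, trial_rows[[trial]])
  }
  trials <- dplyr::bind_rows(trial_rows)
  if (nrow(trials) == 0) {
    rlang::abort(paste0("All trials failed for node '", node, "':\n",
                        paste(failures, collapse = "\n")),
                 class = "gait_search_error")
  }
  if (length(failures) > 0) {
    rlang::inform(paste0(length(failures), " trial(s) failed:\n",
                         paste(failures, collapse = "\n")))
  }
  list(registry = registry, trials = trials)
}

# ---- persistence ----

model_to_list <- function(model) {
  list(
    node = model$node,
    config = unclass(model$config),
    scaler = model$scaler,
    validation_auc = model$validation_auc,
    history = as.list(model$history),
    seed = model$seed,
    weights = purrr::map(model$net$layers, function(l) {
      purrr::map(l$params, function(p) {
        list(dim = dim(p) %||% length(p), data = as.numeric(p))
      })
    })
  )
}

model_from_list <- function(x) {
  config <- x$config
  config$channels <- unlist(config$channels)
  config$units <- as.integer(unlist(config$units))
  config$activations <- unlist(config$activations)
  class(config) <- "gait_model_config"
  net <- build_network(config, seed = 1, clamp_conv = TRUE)
  for (i in seq_along(net$layers)) {
    for (pn in names(net$layers[[i]]$params)) {
      w <- x$weights[[i]][[pn]]
      net$layers[[i]]$params[[pn]] <-
        array(unlist(w$data), dim = unlist(w$dim))
    }
  }
  model <- list(
    config = config, net = net,
    scaler = list(mean = unlist(x$scaler$mean), sd = unlist(x$scaler$sd)),
    node = x$node,
    history = tibble::as_tibble(purrr::map(x$history, unlist)),
    validation_auc = x$validation_auc, seed = x$seed
  )
  class(model) <- "gait_model"
  model
}

#' Persist a registry as a directory tree
#'
#' Layout: `dir/<node>/rank_NNN/{config.yaml, weights.json, metrics.json}`.
#'
#' @param registry Registry tibble.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
save_registry <- function(registry, dir) {
  for (i in seq_len(nrow(registry))) {
    model <- registry$model[[i]]
    if (!inherits(model, "gait_model")) next
    sub <- file.path(dir, registry$node[[i]],
                     sprintf("rank_%03d", registry$rank[[i]]))
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    x <- model_to_list(model)
    yaml::write_yaml(x$config, file.path(sub, "config.yaml"))
    jsonlite::write_json(x$weights, file.path(sub, "weights.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(node = x$node, validation_auc = x$validation_auc,
           scaler = x$scaler, history = x$history, seed = x$seed),
      file.path(sub, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Load a registry saved by [save_registry()]
#' @param dir Directory path.
#' @return Registry tibble.
#' @export
load_registry <- function(dir) {
  registry <- new_registry()
  for (node in list.dirs(dir, recursive = FALSE)) {
    for (sub in sort(list.dirs(node, recursive = FALSE))) {
      config <- yaml::read_yaml(file.path(sub, "config.yaml"))
      weights <- jsonlite::read_json(file.path(sub, "weights.json"))
      meta <- jsonlite::read_json(file.path(sub, "metrics.json"))
      model <- model_from_list(list(
        config = config, weights = weights, node = meta$node,
        scaler = meta$scaler, history = meta$history,
        validation_auc = meta$validation_auc, seed = meta$seed))
      registry <- registry_insert(registry, model, node = basename(node))
    }
  }
  registry
}
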