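# End-to-end training and evaluation of the full cascade.

#' Compact per-node training configurations
#'
#' The package's reference setup for training the five nodes on desk-scale
#' data: a two-layer perceptron (24 and 12 units) over a 16-frame window of
#' all 20 channels, adam at learning rate 0.01, batch 32 — small enough to
#' train in seconds per node yet expressive enough for well-separated data.
#'
#' @param window_length Window length shared by the nodes (default 16).
#' @return Named list of [model_config()]s, one per cascade node.
#' @export
default_node_configs <- function(window_length = 16) {
  nodes <- cascade_nodes()$name
  stats::setNames(purrr::map(nodes, function(nm) {
    model_config(n_dense_layers = 2, units = c(24, 12),
                 activations = c("selu", "tanh"),
                 learning_rate = 0.01, optimizer = "adam",
                 batch_size = 32, window_length = window_length,
                 channels = gait_channels())
  }), nodes)
}

#' Train all five cascade nodes
#'
#' Builds windows per node configuration (cached per window length),
#' splits them stratified 60/20/20, relabels for each node, trains each
#' binary classifier and registers it. Per-node test-partition reports are
#' returned alongside the registry.
#'
#' @param recordings Nested recordings tibble.
#' @param configs Named list of per-node [model_config()]s (default
#'   [default_node_configs()]).
#' @param seed Integer seed (training; the split uses `split_seed`).
#' @param split_seed Seed of the stratified split.
#' @param patience,max_epochs Passed to [train_node()].
#' @param stride Window stride.
#' @param registry Registry to extend (default empty).
#' @return List: `registry`, `node_reports` (tibble, one row per node with
#'   test-set metrics), `models` (named list).
#' @export
train_cascade <- function(recordings, configs = default_node_configs(),
                          seed = 1, split_seed = seed, patience = 5,
                          max_epochs = 30, stride = 1,
                          registry = new_registry()) {
  cache <- new.env(parent = emptyenv())
  models <- list()
  reports <- list()
  for (node in cascade_nodes()$name) {
    config <- configs[[node]]
    if (is.null(config)) {
      rlang::abort(paste0("No configuration supplied for node '", node, "'"),
                   class = "gait_config_error")
    }
    key <- paste0("w", config$window_length, "s", stride)
    if (!exists(key, envir = cache)) {
      win <- build_windows(recordings, window = config$window_length,
                           stride = stride)
      assign(key, stratified_split(win, seed = split_seed), envir = cache)
    }
    labelled <- relabel_binary(get(key, envir = cache), node)
    fit <- train_node(labelled, config, patience = patience,
                      max_epochs = max_epochs,
                      seed = derive_seed(seed, match(node, cascade_nodes()$name)),
                      clamp_conv = TRUE)
    models[[node]] <- fit
    registry <- registry_insert(registry, fit, node = node)
    te <- labelled[labelled$split == "test", ]
    if (nrow(te) > 0 && length(unique(te$label)) == 2) {
      reports[[node]] <- binary_report(te$label, predict(fit, te),
                                       scope = node)
    }
  }
  list(registry = registry,
       node_reports = dplyr::bind_rows(reports),
       models = models)
}

#' Evaluate a cascade on labelled recordings
#'
#' Runs batch cascade prediction and aggregates six-class accuracy, macro
#' one-vs-rest AUC and the per-event confusion table.
#'
#' @param tree A `gait_cascade`.
#' @param recordings Labelled recordings (ideally held out from training).
#' @param stride Prediction stride.
#' @return A `gait_cascade_metrics` (see [cascade_metrics()]), with the raw
#'   predictions attached as attribute `results`.
#' @export
evaluate_cascade <- function(tree, recordings, stride = 1) {
  results <- predict_windows(tree, recordings, stride = stride)
  out <- cascade_metrics(results)
  attr(out, "results") <- results
  out
}
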