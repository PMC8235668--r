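# Published best-model configurations, shipped as YAML fixtures.

#' Load the published best-model configurations
#'
#' Reads the five per-node reference configurations shipped with the
#' package, preserving the printed values verbatim, and flags the two
#' internal inconsistencies of the published table rather than silently
#' repairing them: the unbalanced-node units list has 9 entries for 11
#' declared layers with two values outside the searchable `[1, 64]` range,
#' and the stumbling node's convolution window (10) exceeds its window
#' length (4). A mechanical repaired variant (units clamped to `[1, 64]`
#' and padded by repeating the final entry; convolution window clamped to
#' the window length at build time) is provided in the `config` column so
#' the networks can be built; the repair makes no attempt to guess the
#' intended values.
#'
#' @param dir Fixture directory (default: the installed package copy).
#' @return Tibble with one row per node: `node`, `printed` (raw list as
#'   published), `issues` (character vector of flagged inconsistencies) and
#'   `config` (a buildable [model_config()], repaired where flagged).
#' @export
load_reference_configs <- function(dir = system.file("extdata", "best_models",
                                                     package = "gaitcascade")) {
  files <- sort(list.files(dir, pattern = "\\.yaml$", full.names = TRUE))
  stopifnot(length(files) > 0)
  node_order <- cascade_nodes()$name
  rows <- purrr::map(files, function(f) {
    raw <- yaml::read_yaml(f)
    issues <- character(0)
    units <- as.integer(unlist(raw$units))
    nd <- raw$n_dense_layers
    if (length(units) != nd) {
      issues <- c(issues, paste0(
        "units list has ", length(units), " entries for ", nd,
        " declared layers"))
      if (length(units) < nd) {
        units <- c(units, rep(units[length(units)], nd - length(units)))
      } else {
        units <- units[seq_len(nd)]
      }
    }
    out_of_range <- units < 1 | units > 64
    if (any(out_of_range)) {
      issues <- c(issues, paste0(
        "units outside the [1, 64] search range: ",
        paste(units[out_of_range], collapse = ", ")))
      units <- pmin(pmax(units, 1L), 64L)
    }
    if (isTRUE(raw$use_conv) && raw$conv_window > raw$window_length) {
      issues <- c(issues, paste0(
        "conv window (", raw$conv_window, ") exceeds window length (",
        raw$window_length, "); clamped at build time"))
    }
    config <- model_config(
      n_dense_layers = nd, units = units,
      activations = unlist(raw$activations),
      use_conv = isTRUE(raw$use_conv),
      conv_filters = raw$conv_filters,
      conv_window = if (isTRUE(raw$use_conv))
        min(raw$conv_window, 32L),
      conv_activation = raw$conv_activation,
      use_pooling = isTRUE(raw$use_pooling),
      use_lstm = isTRUE(raw$use_lstm),
      lstm_units = raw$lstm_units,
      learning_rate = raw$learning_rate,
      optimizer = raw$optimizer,
      batch_size = raw$batch_size,
      window_length = raw$window_length,
      channels = unlist(raw$channels)
    )
    tibble::tibble(node = raw$node, printed = list(raw),
                   issues = list(issues), config = list(config))
  }) |> dplyr::bind_rows()
  rows[match(node_order, rows$node), ]
}
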