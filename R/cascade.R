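# Hierarchical cascade inference: five binary nodes routing each window to
# one of six events, with per-node sensor-failure fallback.

#' The five binary cascade nodes
#'
#' The decision tree: the root separates sitting (class 0, terminal) from
#' standing in the broad sense; the standing branch separates still from
#' moving; still splits into stable vs imbalance, moving into stumbling vs
#' gait, and gait into walking vs running. Class 0 is always the "calmer"
#' pole (sitting / still / stable / not stumbling / walking).
#'
#' @return Tibble with one row per node: `name`, `class0_events`,
#'   `class1_events` (list-columns), `child_on_0`, `child_on_1` (a node
#'   name, or an event name for a terminal branch).
#' @export
cascade_nodes <- function() {
  tibble::tibble(
    name = c("standing_vs_seated", "moving_vs_still",
             "unbalanced_vs_stable", "stumbling_vs_not",
             "running_vs_walking"),
    class0_events = list(
      "sitting",
      c("standing_still", "standing_imbalance"),
      "standing_still",
      c("walking", "running"),
      "walking"
    ),
    class1_events = list(
      c("standing_still", "standing_imbalance", "stumbling",
        "walking", "running"),
      c("stumbling", "walking", "running"),
      "standing_imbalance",
      "stumbling",
      "running"
    ),
    child_on_0 = c("sitting", "unbalanced_vs_stable", "standing_still",
                   "running_vs_walking", "walking"),
    child_on_1 = c("moving_vs_still", "stumbling_vs_not",
                   "standing_imbalance", "stumbling", "running")
  )
}

resolve_node <- function(node) {
  if (is.data.frame(node)) return(node)
  nodes <- cascade_nodes()
  row <- nodes[nodes$name == node, ]
  if (nrow(row) == 0) {
    rlang::abort(paste0("Unknown cascade node: ", node,
                        ". Nodes: ", paste(nodes$name, collapse = ", ")),
                 class = "gait_schema_error")
  }
  row
}

#' Wrap a probability function as a cascade node model
#'
#' For testing and for plugging rule-based deciders into the cascade: `fn`
#' receives the window as a frames tibble (the last `window_length` rows,
#' all columns, including `event` when the caller supplies labelled data)
#' and must return the class-1 probability.
#'
#' @param fn `function(window_frames) -> probability`.
#' @param window_length Frames of history the model consumes.
#' @param channels Channels the model depends on (for fallback accounting).
#' @param node Optional node name.
#' @param validation_auc Optional ranking score when inserted in a registry.
#' @return A `gait_function_model`.
#' @export
function_model <- function(fn, window_length = 4,
                           channels = gait_channels(), node = NULL,
                           validation_auc = NA_real_) {
  model <- list(fn = fn, window_length = as.integer(window_length),
                channels = normalize_channels(channels), node = node,
                validation_auc = validation_auc,
                config = list(window_length = as.integer(window_length),
                              channels = normalize_channels(channels)))
  class(model) <- "gait_function_model"
  model
}

#' An oracle node model for a given truth column
#'
#' Returns probability 1 for class 1 and 0 for class 0, read off the
#' window's `event` column — the information-lossless reference against
#' which the cascade topology is checked.
#'
#' @param node Node name.
#' @return A `gait_function_model`.
#' @export
oracle_model <- function(node) {
  spec <- resolve_node(node)
  c1 <- spec$class1_events[[1]]
  function_model(function(win) {
    ev <- win$event[nrow(win)]
    as.numeric(ev %in% c1)
  }, window_length = 4, channels = gait_channels(), node = spec$name,
  validation_auc = 1)
}

model_window_length <- function(model) {
  model$config$window_length %||% model$window_length
}

node_model_prob <- function(model, frames, t_index) {
  w <- model_window_length(model)
  if (t_index < w) {
    rlang::abort(paste0("Warming up: node needs ", w,
                        " frames of history, have ", t_index),
                 class = "gait_warmup")
  }
  win <- frames[(t_index - w + 1L):t_index, , drop = FALSE]
  if (inherits(model, "gait_function_model")) {
    as.numeric(model$fn(win))
  } else {
    m <- as.matrix(win[, model$config$channels, drop = FALSE])
    colnames(m) <- model$config$channels
    predict(model, m)
  }
}

#' Assemble a cascade from a model registry
#'
#' @param registry A registry tibble ([registry_insert()]) holding at least
#'   one model per node, or a named list of node models (e.g. from
#'   [oracle_model()]).
#' @param threshold Decision cut-off applied to every node's sigmoid output
#'   (class 1 iff probability >= threshold). Default 0.5.
#' @return A `gait_cascade`.
#' @export
cascade_tree <- function(registry, threshold = 0.5) {
  nodes <- cascade_nodes()
  if (!is.data.frame(registry)) {
    reg <- new_registry()
    for (nm in names(registry)) {
      reg <- registry_insert(reg, registry[[nm]], node = nm)
    }
    registry <- reg
  }
  missing <- setdiff(nodes$name, unique(registry$node))
  if (length(missing) > 0) {
    rlang::abort(paste0("Registry lacks model(s) for node(s): ",
                        paste(missing, collapse = ", ")),
                 class = "gait_node_unavailable")
  }
  out <- list(nodes = nodes, registry = registry, threshold = threshold)
  class(out) <- "gait_cascade"
  out
}

#' Enumerate all decision paths of the cascade
#'
#' Walks both branches of every node; the leaves must cover exactly the six
#' events (the hierarchy loses no label).
#'
#' @param tree A `gait_cascade`, or missing for the canonical topology.
#' @return Tibble with `decisions` (list of 0/1 vectors), `path` (node
#'   names) and terminal `event`.
#' @export
cascade_leaves <- function(tree = NULL) {
  nodes <- if (is.null(tree)) cascade_nodes() else tree$nodes
  walk <- function(name, decisions, path) {
    if (name %in% gait_events()) {
      return(tibble::tibble(decisions = list(decisions),
                            path = list(path), event = name))
    }
    row <- nodes[nodes$name == name, ]
    dplyr::bind_rows(
      walk(row$child_on_0, c(decisions, 0L), c(path, name)),
      walk(row$child_on_1, c(decisions, 1L), c(path, name))
    )
  }
  walk("standing_vs_seated", integer(0), character(0))
}

# Per-event leaf score: product of branch probabilities along each leaf
# path given the five node probabilities.
leaf_scores <- function(node_probs) {
  leaves <- cascade_leaves()
  scores <- vapply(seq_len(nrow(leaves)), function(i) {
    p <- 1
    path <- leaves$path[[i]]
    dec <- leaves$decisions[[i]]
    for (j in seq_along(path)) {
      pj <- node_probs[[path[j]]]
      p <- p * if (dec[j] == 1) pj else 1 - pj
    }
    p
  }, numeric(1))
  stats::setNames(scores, leaves$event)[gait_events()]
}

#' Cascade prediction at one instant
#'
#' Starting at the root, selects each visited node's model through the
#' sensor-failure fallback ([best_without()]), slices that model's window
#' from the frame history, thresholds its probability and descends until a
#' terminal event. Also evaluates all five nodes once to derive per-event
#' leaf scores (products of branch probabilities), used for one-vs-rest
#' AUCs.
#'
#' @param tree A `gait_cascade`.
#' @param frames Frames tibble of one recording (time-ordered).
#' @param t_index Prediction instant: index of the newest frame to use
#'   (default: the last frame).
#' @param failed_channels Channels currently known failed.
#' @return List with `event`, `path` (tibble: node, probability, decision,
#'   branch_prob), `path_probability`, `risk_flag` and `scores` (named
#'   per-event vector, `NA` if some off-path node could not be evaluated).
#' @export
predict_cascade <- function(tree, frames, t_index = nrow(frames),
                            failed_channels = character(0)) {
  stopifnot(inherits(tree, "gait_cascade"))
  node_probs <- list()
  get_prob <- function(name) {
    if (!is.null(node_probs[[name]])) return(node_probs[[name]])
    model <- best_without(tree$registry, name, failed_channels)
    p <- node_model_prob(model, frames, t_index)
    node_probs[[name]] <<- p
    p
  }
  current <- "standing_vs_seated"
  path <- list()
  path_probability <- 1
  while (!current %in% gait_events()) {
    row <- tree$nodes[tree$nodes$name == current, ]
    p <- get_prob(current)
    decision <- as.integer(p >= tree$threshold)
    branch_prob <- if (decision == 1) p else 1 - p
    path[[length(path) + 1]] <- tibble::tibble(
      node = current, probability = p, decision = decision,
      branch_prob = branch_prob)
    path_probability <- path_probability * branch_prob
    current <- if (decision == 1) row$child_on_1 else row$child_on_0
  }
  scores <- tryCatch({
    for (nm in tree$nodes$name) get_prob(nm)
    leaf_scores(node_probs)
  }, error = function(e) {
    stats::setNames(rep(NA_real_, 6), gait_events())
  })
  list(
    event = current,
    path = dplyr::bind_rows(path),
    path_probability = path_probability,
    risk_flag = current %in% gait_risk_events(),
    scores = scores
  )
}

# Largest window any currently-selectable node model needs.
tree_max_window <- function(tree, failed_channels = character(0)) {
  max(vapply(tree$nodes$name, function(nm) {
    model <- best_without(tree$registry, nm, failed_channels)
    model_window_length(model)
  }, numeric(1)))
}

#' Batch cascade prediction over labelled recordings
#'
#' Runs [predict_cascade()] at every prediction instant (stride apart, after
#' the warm-up imposed by the largest node window) of every recording.
#'
#' @param tree A `gait_cascade`.
#' @param recordings Nested recordings tibble.
#' @param stride Hop between prediction instants.
#' @param failed_channels Channels currently known failed.
#' @return Tibble with one row per prediction: `recording_id`, `event`
#'   (truth), `t_index`, `event_pred`, `path_probability`, `risk_flag` and
#'   `score_<event>` columns.
#' @export
predict_windows <- function(tree, recordings, stride = 1,
                            failed_channels = character(0)) {
  warm <- tree_max_window(tree, failed_channels)
  rows <- purrr::pmap(
    recordings[, c("recording_id", "event", "frames")],
    function(recording_id, event, frames) {
      n <- nrow(frames)
      if (n < warm) return(NULL)
      if (!"event" %in% names(frames)) frames$event <- event
      purrr::map(seq.int(warm, n, by = stride), function(t) {
        res <- predict_cascade(tree, frames, t, failed_channels)
        out <- tibble::tibble(
          recording_id = recording_id, event = event, t_index = t,
          event_pred = res$event,
          path_probability = res$path_probability,
          risk_flag = res$risk_flag)
        for (ev in gait_events()) out[[paste0("score_", ev)]] <- res$scores[[ev]]
        out
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  rows
}

# ---- streaming ----

#' Collecting alert sink
#'
#' @return List with `sink` (function consuming one result) and `alerts()`
#'   returning the collected results tibble.
#' @export
alert_collector <- function() {
  store <- new.env(parent = emptyenv())
  store$rows <- list()
  list(
    sink = function(result) {
      store$rows[[length(store$rows) + 1]] <- result
    },
    alerts = function() dplyr::bind_rows(store$rows)
  )
}

#' File alert sink (JSON lines)
#'
#' @param path Output file.
#' @return A sink function writing one JSON object per alert.
#' @export
alert_file_sink <- function(path) {
  if (file.exists(path)) file.remove(path)
  function(result) {
    line <- jsonlite::toJSON(
      list(timestamp = as.character(result$timestamp),
           event = result$event_pred,
           path_probability = result$path_probability,
           risk_flag = result$risk_flag),
      auto_unbox = TRUE, digits = NA)
    cat(line, "\n", sep = "", file = path, append = TRUE)
  }
}

#' Streaming cascade prediction with risk alerts
#'
#' Consumes a time-ordered telemetry stream (an NDJSON character vector of
#' device messages plus auxiliary readings, or an already-aligned frames
#' tibble), maintains a rolling buffer sized to the largest node window, and
#' emits one cascade result per `stride` frames once warmed up. Malformed
#' messages are skipped with a log message and do not disturb the buffer.
#' Every risk-flagged result is forwarded to `alert_sink` exactly once.
#'
#' @param tree A `gait_cascade`.
#' @param messages NDJSON lines (device schema) or a frames tibble.
#' @param aux Auxiliary readings tibble (`timestamp`, `temp`, `ax`, `ay`,
#'   `az`); required when `messages` are NDJSON lines.
#' @param alert_sink Function consuming one result row (see
#'   [alert_collector()], [alert_file_sink()]); `NULL` disables alerts.
#' @param stride Frames between successive emissions.
#' @param failed_channels Channels currently known failed.
#' @return Results tibble (one row per emission): `timestamp`, `t_index`,
#'   `event_pred`, `path_probability`, `risk_flag`.
#' @export
predict_stream <- function(tree, messages, aux = NULL, alert_sink = NULL,
                           stride = 1, failed_channels = character(0)) {
  frames <- if (is.data.frame(messages)) {
    messages
  } else {
    pressure <- parse_stream(messages, on_error = "skip")
    if (is.null(aux)) {
      rlang::abort("aux readings are required with an NDJSON stream",
                   class = "gait_schema_error")
    }
    align_channels(pressure, aux)
  }
  warm <- tree_max_window(tree, failed_channels)
  n <- nrow(frames)
  if (n < warm) {
    return(tibble::tibble(timestamp = frames$timestamp[0],
                          t_index = integer(0), event_pred = character(0),
                          path_probability = numeric(0),
                          risk_flag = logical(0)))
  }
  out <- purrr::map(seq.int(warm, n, by = stride), function(t) {
    res <- predict_cascade(tree, frames, t, failed_channels)
    row <- tibble::tibble(
      timestamp = frames$timestamp[t], t_index = t,
      event_pred = res$event,
      path_probability = res$path_probability,
      risk_flag = res$risk_flag)
    if (res$risk_flag && !is.null(alert_sink)) alert_sink(row)
    row
  }) |> dplyr::bind_rows()
  out
}
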