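# Sliding-window tensors, stratified splits, binary relabelling.

#' Build sliding windows over recordings
#'
#' Each window is the matrix of the last `window` frames (rows, oldest first)
#' by the selected channels (columns, canonical order), the historical input
#' a classifier sees at a prediction instant. Windows never cross recording
#' boundaries, and the first `window - 1` frames of every recording yield no
#' window (insufficient history). For a recording of `n` frames and stride 1
#' the window count is `n - window + 1`; recordings shorter than `window`
#' contribute nothing.
#'
#' @param recordings Nested recordings tibble ([load_recordings()] /
#'   [simulate_dataset()]).
#' @param channels Channel subset (any order/case accepted; columns are
#'   emitted in canonical [gait_channels()] order). Default: all 20.
#' @param window Window length `w`, between 4 and 32.
#' @param stride Hop between prediction instants (default 1).
#' @return Tibble with one row per window: `recording_id`, `event`,
#'   `t_index` (index of the newest frame in its recording) and `values`
#'   (list-column of `w x c` matrices with channel dimnames).
#' @export
build_windows <- function(recordings, channels = gait_channels(),
                          window = 32, stride = 1) {
  stopifnot(window >= 4, window <= 32, stride >= 1)
  channels <- normalize_channels(channels)
  if (length(channels) == 0) {
    rlang::abort("Channel selection must be non-empty",
                 class = "gait_schema_error")
  }
  channels <- gait_channels()[gait_channels() %in% channels]
  short <- 0L
  rows <- purrr::pmap(
    recordings[, c("recording_id", "event", "frames")],
    function(recording_id, event, frames) {
      n <- nrow(frames)
      if (n < window) {
        short <<- short + 1L
        return(NULL)
      }
      mat <- as.matrix(frames[, channels, drop = FALSE])
      t_idx <- seq.int(window, n, by = stride)
      tibble::tibble(
        recording_id = recording_id,
        event = event,
        t_index = t_idx,
        values = purrr::map(t_idx, function(t) {
          m <- mat[(t - window + 1L):t, , drop = FALSE]
          dimnames(m) <- list(NULL, channels)
          m
        })
      )
    }
  )
  if (short > 0) {
    rlang::inform(paste0(short, " recording(s) shorter than the window (",
                         window, " frames) yielded no windows"))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(recording_id = character(0), event = character(0),
                          t_index = integer(0), values = list())
  }
  attr(out, "window") <- window
  attr(out, "channels") <- channels
  attr(out, "stride") <- stride
  out
}

#' Stratified train/validation/test split
#'
#' Partitions windows 60/20/20 (by default) within each class, so every set
#' keeps the class mix of the input to within one sample (largest-remainder
#' allocation, ties favouring train). Deterministic under `seed`.
#'
#' @param windows Windows tibble; the class column is `label` if present
#'   (binary-relabelled data), otherwise `event`.
#' @param proportions Length-3 numeric summing to 1
#'   (train, validation, test).
#' @param seed Integer seed.
#' @param by Split unit: `"window"` (default; matches splitting individual
#'   samples) or `"recording"` (whole recordings assigned to one partition,
#'   the stricter no-temporal-leakage mode).
#' @return The input tibble with an added `split` factor column
#'   (`train`/`validation`/`test`).
#' @export
stratified_split <- function(windows, proportions = c(0.6, 0.2, 0.2),
                             seed = 1, by = c("window", "recording")) {
  by <- match.arg(by)
  stopifnot(length(proportions) == 3, abs(sum(proportions) - 1) < 1e-8)
  cls_col <- if ("label" %in% names(windows)) "label" else "event"
  split_lv <- c("train", "validation", "test")
  unit <- if (by == "window") seq_len(nrow(windows)) else windows$recording_id
  assign_class <- function(idx, cls) {
    n <- length(idx)
    if (n < 3) {
      rlang::abort(paste0("Class '", cls, "' has only ", n,
                          " sample(s); at least 3 are required to split"),
                   class = "gait_split_error")
    }
    # largest-remainder allocation keeps every partition within one sample
    # of its target; ties favour train, then validation
    base <- floor(n * proportions)
    fracs <- n * proportions - base
    extra <- order(-fracs, seq_along(fracs))[seq_len(n - sum(base))]
    base[extra] <- base[extra] + 1L
    perm <- sample(idx)
    out <- rep(split_lv, times = base)
    stats::setNames(out, perm)
  }
  split <- character(nrow(windows))
  with_seed(seed, {
    for (cls in sort(unique(windows[[cls_col]]))) {
      in_cls <- which(windows[[cls_col]] == cls)
      if (by == "window") {
        a <- assign_class(in_cls, cls)
        split[as.integer(names(a))] <- a
      } else {
        recs <- sort(unique(windows$recording_id[in_cls]))
        if (length(recs) < 3) {
          rlang::abort(paste0("Class '", cls, "' has only ", length(recs),
                              " recording(s); at least 3 are required for a ",
                              "recording-level split"),
                       class = "gait_split_error")
        }
        a <- assign_class(seq_along(recs), cls)
        lookup <- stats::setNames(unname(a), recs[as.integer(names(a))])
        split[in_cls] <- lookup[windows$recording_id[in_cls]]
      }
    }
  })
  windows$split <- factor(split, levels = split_lv)
  attr(windows, "split_seed") <- seed
  attr(windows, "split_by") <- by
  windows
}

#' Relabel windows for one binary cascade node
#'
#' Keeps only windows whose event lies in the node's domain and attaches the
#' node's 0/1 class (`label` column). Polarity follows the cascade
#' convention: class 0 is sitting / still / stable / not-stumbling / walking
#' at the respective nodes.
#'
#' @param windows Windows tibble with an `event` column.
#' @param node A node name (see [cascade_nodes()]) or a node-spec row.
#' @return Filtered windows tibble with an integer `label` column.
#' @export
relabel_binary <- function(windows, node) {
  spec <- resolve_node(node)
  keep <- windows$event %in% c(spec$class0_events[[1]], spec$class1_events[[1]])
  out <- windows[keep, , drop = FALSE]
  out$label <- as.integer(out$event %in% spec$class1_events[[1]])
  attr(out, "node") <- spec$name
  for (a in c("window", "channels", "stride", "split_seed"))
    attr(out, a) <- attr(windows, a)
  out
}

# Stack the `values` list-column into an N x w x c array.
windows_to_array <- function(windows) {
  n <- nrow(windows)
  if (n == 0) return(array(numeric(0), dim = c(0, 0, 0)))
  w <- nrow(windows$values[[1]])
  cdim <- ncol(windows$values[[1]])
  x <- array(NA_real_, dim = c(n, w, cdim))
  for (i in seq_len(n)) x[i, , ] <- windows$values[[i]]
  dimnames(x) <- list(NULL, NULL, colnames(windows$values[[1]]))
  x
}

#' Persist windows as array files plus a JSON manifest
#'
#' Writes one whitespace-delimited text matrix per window set under `dir`
#' (rows = windows, columns = flattened `w x c` values, time-major) and a
#' `manifest.json` recording the shape, channel order, label map and seed, so
#' a window tensor directory is self-describing.
#'
#' @param windows Windows tibble (optionally split/relabelled).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_windows <- function(windows, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  x <- windows_to_array(windows)
  flat <- matrix(x, nrow = dim(x)[1])
  utils::write.table(flat, file.path(dir, "values.txt"),
                     row.names = FALSE, col.names = FALSE)
  meta <- list(
    n = nrow(windows),
    window = attr(windows, "window"),
    channels = attr(windows, "channels"),
    stride = attr(windows, "stride"),
    split_seed = attr(windows, "split_seed"),
    event_levels = gait_events(),
    event = windows$event,
    recording_id = windows$recording_id,
    t_index = windows$t_index
  )
  if ("label" %in% names(windows)) meta$label <- windows$label
  if ("split" %in% names(windows)) meta$split <- as.character(windows$split)
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a window directory written by [write_windows()]
#' @param dir Directory path.
#' @return Windows tibble.
#' @export
read_windows <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(file.path(dir, "values.txt")))
  w <- meta$window
  ch <- meta$channels
  out <- tibble::tibble(
    recording_id = as.character(meta$recording_id),
    event = as.character(meta$event),
    t_index = as.integer(meta$t_index),
    values = purrr::map(seq_len(meta$n), function(i) {
      m <- matrix(flat[i, ], nrow = w, ncol = length(ch))
      dimnames(m) <- list(NULL, ch)
      m
    })
  )
  if (!is.null(meta$label)) out$label <- as.integer(meta$label)
  if (!is.null(meta$split))
    out$split <- factor(meta$split, levels = c("train", "validation", "test"))
  attr(out, "window") <- w
  attr(out, "channels") <- ch
  attr(out, "stride") <- meta$stride
  out
}
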