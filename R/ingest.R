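# Telemetry ingestion: message parsing, timestamp alignment, recording files.

#' Parse a device timestamp
#'
#' The insole firmware prints timestamps with a colon before the fractional
#' second (`"2020-10-25T17:12:24:6847"`); standard dot notation
#' (`"...:24.6847"`) is accepted too. A bare time of day (`"HH:MM:SS:ffff"`)
#' is interpreted on the epoch date.
#'
#' @param x Character vector of timestamps.
#' @return `POSIXct` (UTC) vector.
#' @export
#' @examples
#' parse_instant("2020-10-25T17:12:24:6847")
parse_instant <- function(x) {
  x <- as.character(x)
  # time-only dialect -> epoch date
  bare <- grepl("^\\d{2}:\\d{2}:\\d{2}([:.]\\d+)?$", x)
  x[bare] <- paste0("1970-01-01T", x[bare])
  # colon-before-fraction dialect -> dot
  x <- sub("^(\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}:\\d{2}):(\\d+)$",
           "\\1.\\2", x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  miss <- is.na(out) & !is.na(x)
  if (any(miss)) {
    out[miss] <- as.POSIXct(x[miss], format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
  }
  if (anyNA(out[!is.na(x)])) {
    rlang::abort(
      paste0("Unparseable timestamp: ",
             paste(utils::head(x[is.na(out)], 3), collapse = ", ")),
      class = "gait_schema_error"
    )
  }
  out
}

#' Format an instant in canonical ISO-8601 (dot fractional separator)
#' @param x `POSIXct` vector.
#' @param digits Fractional-second digits (default 4).
#' @return Character vector.
#' @export
format_instant <- function(x, digits = 4) {
  format(x, format = paste0("%Y-%m-%dT%H:%M:%OS", digits), tz = "UTC")
}

#' Parse one telemetry message
#'
#' A message is a single JSON object with a `timestamp` and a `data` array of
#' exactly 16 pressure readings (device units), the payload the insole sends
#' per sampling tick.
#'
#' @param raw A JSON string.
#' @return A one-row tibble with `timestamp` and `p0`..`p15`.
#' @export
#' @examples
#' parse_message(
#'   paste0('{"timestamp":"2020-10-25T17:12:24:6847","data":[',
#'          paste(rep(0, 16), collapse = ","), ']}'))
parse_message <- function(raw) {
  obj <- tryCatch(
    jsonlite::fromJSON(raw, simplifyVector = TRUE),
    error = function(e) rlang::abort(
      paste0("Malformed JSON message: ", conditionMessage(e)),
      class = "gait_schema_error")
  )
  if (is.null(obj$timestamp)) {
    rlang::abort("Message is missing field 'timestamp'",
                 class = "gait_schema_error")
  }
  if (is.null(obj$data)) {
    rlang::abort("Message is missing field 'data'",
                 class = "gait_schema_error")
  }
  p <- suppressWarnings(as.numeric(obj$data))
  if (length(p) != 16 || anyNA(p)) {
    rlang::abort(
      paste0("Field 'data' must hold exactly 16 numeric pressure readings, got ",
             length(p), if (anyNA(p)) " (with non-numeric entries)" else ""),
      class = "gait_schema_error"
    )
  }
  out <- tibble::as_tibble(stats::setNames(as.list(p), paste0("p", 0:15)))
  tibble::add_column(out, timestamp = parse_instant(obj$timestamp),
                     .before = 1)
}

#' Serialise a message back to the device JSON schema
#'
#' Round-trips with [parse_message()]: the 16 pressure values and the instant
#' are value-identical after `parse_message(serialize_message(msg))`.
#'
#' @param msg A one-row tibble with `timestamp` and `p0`..`p15`.
#' @return A JSON string (one line, NDJSON-ready).
#' @export
serialize_message <- function(msg) {
  stopifnot(nrow(msg) == 1)
  jsonlite::toJSON(
    list(timestamp = format_instant(msg$timestamp),
         data = as.numeric(msg[1, paste0("p", 0:15)])),
    auto_unbox = TRUE, digits = NA
  )
}

#' Parse an NDJSON message stream
#'
#' @param lines Character vector of JSON lines, or a file path.
#' @param on_error `"abort"` or `"skip"` (malformed lines dropped with a
#'   message).
#' @return Tibble with `timestamp` and `p0`..`p15`, one row per message.
#' @export
parse_stream <- function(lines, on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  lines <- lines[nzchar(trimws(lines))]
  rows <- vector("list", length(lines))
  n_bad <- 0L
  for (i in seq_along(lines)) {
    rows[[i]] <- tryCatch(parse_message(lines[[i]]), gait_schema_error = function(e) {
      if (on_error == "abort") rlang::abort(conditionMessage(e),
                                            class = "gait_schema_error")
      n_bad <<- n_bad + 1L
      NULL
    })
  }
  out <- dplyr::bind_rows(rows)
  if (n_bad > 0) rlang::inform(paste0("Skipped ", n_bad, " malformed message(s)"))
  if (nrow(out) == 0) {
    out <- tibble::as_tibble(stats::setNames(rep(list(numeric(0)), 16),
                                             paste0("p", 0:15)))
    out <- tibble::add_column(out, timestamp = parse_instant(character(0)),
                              .before = 1)
  }
  out
}

#' Align auxiliary channels to the pressure clock
#'
#' The accelerometer and temperature readings arrive with a delay relative to
#' the pressure messages; each pressure timestamp is assigned the auxiliary
#' reading nearest at-or-before it (last observation carried forward), so all
#' 20 channels share the pressure clock. Pressure frames that precede the
#' first auxiliary reading have no history to carry forward and are dropped,
#' with the count reported.
#'
#' @param pressure Tibble with `timestamp`, `p0`..`p15` (time-ordered).
#' @param aux Tibble with `timestamp`, `temp`, `ax`, `ay`, `az` (time-ordered).
#' @return Tibble of aligned frames with the 20 channels in canonical order;
#'   attribute `n_dropped` counts head frames dropped for lack of auxiliary
#'   history.
#' @export
align_channels <- function(pressure, aux) {
  need_p <- c("timestamp", paste0("p", 0:15))
  need_a <- c("timestamp", "temp", "ax", "ay", "az")
  stopifnot(all(need_p %in% names(pressure)), all(need_a %in% names(aux)))
  if (nrow(pressure) == 0) {
    out <- pressure[0, need_p]
    out$temp <- numeric(0); out$ax <- numeric(0)
    out$ay <- numeric(0); out$az <- numeric(0)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  idx <- findInterval(as.numeric(pressure$timestamp), as.numeric(aux$timestamp))
  keep <- idx >= 1L
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    rlang::inform(paste0("Dropped ", n_dropped,
                         " pressure frame(s) preceding the first auxiliary reading"))
  }
  out <- pressure[keep, need_p]
  sel <- aux[idx[keep], c("temp", "ax", "ay", "az")]
  out <- dplyr::bind_cols(out, sel)
  out <- out[, c("timestamp", gait_channels())]
  attr(out, "n_dropped") <- n_dropped
  out
}

recording_csv_columns <- function() {
  c("recording_id", "subject_id", "event", "timestamp", gait_channels())
}

#' Load labelled recordings from CSV
#'
#' One row per frame with columns `recording_id`, `subject_id`, `event`,
#' `timestamp`, `p0`..`p15`, `temp`, `ax`, `ay`, `az`. Frames are grouped by
#' recording, sorted by time, and event labels validated against
#' [gait_events()]. Each recording carries a single event label (the
#' collection protocol tags whole recordings).
#'
#' @param path CSV file path.
#' @param nominal_rate Sampling rate in Hz (default 4, the device average).
#' @return A nested tibble of recordings: one row per recording with columns
#'   `recording_id`, `subject_id`, `event`, `n_frames` and a `frames`
#'   list-column (tibbles of `timestamp` + the 20 channels).
#' @export
load_recordings <- function(path, nominal_rate = 4) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    return(empty_recordings(nominal_rate))
  }
  missing_cols <- setdiff(recording_csv_columns(), names(df))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("Recording file is missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "gait_schema_error")
  }
  assert_event(df$event)
  df$timestamp <- parse_instant(df$timestamp)
  df <- tibble::as_tibble(df)
  neg <- vapply(paste0("p", 0:15), function(ch) any(df[[ch]] < 0), logical(1))
  if (any(neg)) {
    rlang::abort(paste0("Negative pressure values in channel(s): ",
                        paste(names(neg)[neg], collapse = ", ")),
                 class = "gait_schema_error")
  }
  recs <- df |>
    dplyr::group_by(.data$recording_id) |>
    dplyr::group_split() |>
    purrr::map(function(g) {
      ev <- unique(g$event)
      if (length(ev) != 1) {
        rlang::abort(paste0("Recording '", g$recording_id[[1]],
                            "' carries more than one event label"),
                     class = "gait_schema_error")
      }
      g <- dplyr::arrange(g, .data$timestamp)
      if (anyDuplicated(g$timestamp) || is.unsorted(g$timestamp, strictly = TRUE)) {
        rlang::abort(paste0("Non-monotone timestamps in recording '",
                            g$recording_id[[1]], "'"),
                     class = "gait_schema_error")
      }
      tibble::tibble(
        recording_id = as.character(g$recording_id[[1]]),
        subject_id = as.character(g$subject_id[[1]]),
        event = ev,
        n_frames = nrow(g),
        frames = list(g[, c("timestamp", gait_channels())])
      )
    }) |>
    dplyr::bind_rows()
  attr(recs, "nominal_rate") <- nominal_rate
  class(recs) <- c("gait_recordings", class(recs))
  recs
}

empty_recordings <- function(nominal_rate = 4) {
  recs <- tibble::tibble(
    recording_id = character(0), subject_id = character(0),
    event = character(0), n_frames = integer(0), frames = list()
  )
  attr(recs, "nominal_rate") <- nominal_rate
  class(recs) <- c("gait_recordings", class(recs))
  recs
}

#' Write recordings to the flat CSV schema
#'
#' @param recordings Nested recordings tibble (see [load_recordings()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recordings_csv <- function(recordings, path) {
  flat <- purrr::pmap(
    recordings[, c("recording_id", "subject_id", "event", "frames")],
    function(recording_id, subject_id, event, frames) {
      dplyr::bind_cols(
        tibble::tibble(recording_id = recording_id, subject_id = subject_id,
                       event = event)[rep(1, nrow(frames)), ],
        frames
      )
    }
  ) |> dplyr::bind_rows()
  flat$timestamp <- format_instant(flat$timestamp)
  flat <- flat[, recording_csv_columns()]
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' Write the pressure channels of a recording as an NDJSON message stream
#'
#' Emits one device-schema JSON object per frame (timestamp + 16 pressures),
#' matching the payload the real insole transmits.
#'
#' @param frames Frames tibble (`timestamp`, `p0`..`p15`, ...).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ndjson <- function(frames, path) {
  lines <- vapply(seq_len(nrow(frames)), function(i) {
    as.character(serialize_message(frames[i, c("timestamp", paste0("p", 0:15))]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
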