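# Shared fixtures, all built in code.

# A frames tibble with deterministic ramp values on every channel.
make_frames <- function(n, start = "2021-01-01 00:00:00", rate = 4,
                        fill = function(i, ch) i * 100 + ch) {
  ts <- as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) / rate
  cols <- purrr::imap(gait_channels(), function(ch, j)
    rep_len(fill(seq_len(n), j), n))
  out <- tibble::as_tibble(stats::setNames(cols, gait_channels()))
  tibble::add_column(out, timestamp = ts, .before = 1)
}

# A one-row nested recordings tibble.
make_recording <- function(n, event = "walking", id = "r1",
                           subject = "s1", ...) {
  rec <- tibble::tibble(
    recording_id = id, subject_id = subject, event = event,
    n_frames = n, frames = list(make_frames(n, ...))
  )
  class(rec) <- c("gait_recordings", class(rec))
  rec
}

make_message <- function(ts = "2020-10-25T17:12:24:6847",
                         data = rep(0, 16)) {
  jsonlite::toJSON(list(timestamp = ts, data = data), auto_unbox = TRUE,
                   digits = NA)
}

# Small simulated dataset reused across tests (cached per session).
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(
        gait_sim_config(seed = 11, duration = 30),
        c(sitting = 4, standing_still = 5, standing_imbalance = 5,
          walking = 6, running = 4, stumbling = 4))
    }
    cache
  }
})

# An oracle registry: every node decided perfectly from the event column.
oracle_registry <- function() {
  reg <- new_registry()
  for (nm in cascade_nodes()$name) {
    reg <- registry_insert(reg, oracle_model(nm), node = nm)
  }
  reg
}

expect_no_intersect <- function(a, b) {
  expect_length(intersect(a, b), 0)
}
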