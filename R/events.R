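#' The six gait events
#'
#' The closed set of walking-behaviour events the cascade can emit, in their
#' stable ordinal order: `sitting`, `standing_still`, `standing_imbalance`,
#' `walking`, `running`, `stumbling`. The two fall-risk events are
#' `standing_imbalance` and `stumbling`.
#'
#' @return Character vector of the six event names.
#' @export
#' @examples
#' gait_events()
gait_events <- function() {
  c("sitting", "standing_still", "standing_imbalance",
    "walking", "running", "stumbling")
}

#' Events flagged as fall-risk indicators
#' @return Character vector, subset of [gait_events()].
#' @export
gait_risk_events <- function() {
  c("standing_imbalance", "stumbling")
}

#' The 20 telemetry channels
#'
#' Channel order is fixed package-wide: 16 plantar pressure sensors
#' (`p0`..`p15`, heel to toe along the insole), one temperature channel
#' (`temp`) and three acceleration axes (`ax`, `ay`, `az`). Every frame,
#' window matrix and model input uses this column order.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' gait_channels()
gait_channels <- function() {
  c(paste0("p", 0:15), "temp", "ax", "ay", "az")
}

#' Normalise channel names
#'
#' Accepts both the package's lower-case names (`p0`, `temp`, `ax`, ...) and
#' the device-report style (`P0`..`P15`, `T0`, `A0`, `A1`, `A2`), returning
#' canonical lower-case names.
#'
#' @param x Character vector of channel names.
#' @return Character vector of canonical channel names.
#' @export
#' @examples
#' normalize_channels(c("P0", "T0", "A2"))
normalize_channels <- function(x) {
  map <- c(
    stats::setNames(paste0("p", 0:15), paste0("P", 0:15)),
    T0 = "temp", A0 = "ax", A1 = "ay", A2 = "az",
    stats::setNames(gait_channels(), gait_channels())
  )
  out <- unname(map[x])
  if (anyNA(out)) {
    bad <- x[is.na(out)]
    rlang::abort(
      paste0("Unknown channel name(s): ", paste(bad, collapse = ", ")),
      class = "gait_schema_error"
    )
  }
  out
}

assert_event <- function(event) {
  bad <- setdiff(unique(event), gait_events())
  if (length(bad) > 0) {
    rlang::abort(
      paste0("Unknown event label(s): ", paste(bad, collapse = ", "),
             ". Valid events: ", paste(gait_events(), collapse = ", ")),
      class = "gait_schema_error"
    )
  }
  invisible(event)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic sub-seed derivation (kept below 2^31).
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 7919 + as.numeric(p) + 104729) %% 2147483629
  as.integer(h)
}
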