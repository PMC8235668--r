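# Seeded synthetic insole telemetry for the six gait events.

#' Simulator configuration
#'
#' Parameters of the synthetic 4 Hz insole telemetry generator. All pressure
#' quantities are in opaque device units (the hardware reports raw
#' PCB-coded values); acceleration is in g; cadences are single-foot stride
#' frequencies in Hz. Defaults emulate clearly separated renditions of the
#' six events: a seated subject loads the insole lightly; quiet standing
#' loads heel and forefoot statically; imbalance adds a slow medial/lateral
#' sway; walking and running drive a heel-to-toe pressure wave at their
#' cadence, running with higher amplitude and flight phases; stumbling is
#' walking with sporadic transient bursts (acceleration spike plus irregular
#' pressure). The running cadence default (1.7 Hz) is kept below the 2 Hz
#' Nyquist limit of the 4 Hz sampling clock so that cadence remains
#' spectrally identifiable.
#'
#' @param seed Integer master seed.
#' @param rate Sampling rate, Hz.
#' @param duration Recording length, seconds.
#' @param sit_base,sit_noise,sit_shift_rate,sit_shift_amp Sitting: baseline
#'   pressure, noise sd, foot-shift burst rate (per second) and amplitude.
#' @param stand_heel,stand_toe,stand_mid,stand_noise Quiet standing: heel,
#'   forefoot/toe and midfoot baseline pressures and noise sd.
#' @param stand_tap_rate,stand_tap_amp Small foot-tap rate (per second) and
#'   amplitude while standing.
#' @param sway_freq,sway_amp,sway_accel_amp Imbalance sway frequency (Hz),
#'   pressure amplitude and matched acceleration amplitude.
#' @param walk_cadence,walk_amp,walk_accel_amp Walking cadence (Hz), gait
#'   wave amplitude and acceleration amplitude.
#' @param run_cadence,run_amp,run_accel_amp,run_flight_duty Running cadence
#'   (Hz), amplitude, acceleration amplitude and flight-phase duty cycle
#'   (fraction of each stride with the foot off the ground).
#' @param gait_noise Pressure noise sd during walking/running/stumbling.
#' @param stumble_rate,stumble_accel_amp,stumble_press_amp,stumble_len
#'   Stumble burst rate (per second), acceleration spike amplitude (g),
#'   pressure irregularity amplitude and burst length in frames.
#' @param accel_noise Acceleration noise sd (g).
#' @param temp_base,temp_drift_sd Temperature baseline and per-frame random
#'   walk sd (device units).
#' @param wave_span Fraction of the gait cycle spanned by the heel-to-toe
#'   activation offsets (sensor 0 leads, sensor 15 trails).
#' @return A `gait_sim_config` list.
#' @export
gait_sim_config <- function(seed = 1, rate = 4, duration = 60,
                            sit_base = 30, sit_noise = 5,
                            sit_shift_rate = 0.05, sit_shift_amp = 40,
                            stand_heel = 350, stand_toe = 250,
                            stand_mid = 120, stand_noise = 8,
                            stand_tap_rate = 0.02, stand_tap_amp = 30,
                            sway_freq = 0.4, sway_amp = 120,
                            sway_accel_amp = 0.3,
                            walk_cadence = 1.0, walk_amp = 450,
                            walk_accel_amp = 0.35,
                            run_cadence = 1.7, run_amp = 800,
                            run_accel_amp = 0.9, run_flight_duty = 0.35,
                            gait_noise = 15,
                            stumble_rate = 0.6, stumble_accel_amp = 3,
                            stumble_press_amp = 300, stumble_len = 3,
                            accel_noise = 0.05,
                            temp_base = 30, temp_drift_sd = 0.02,
                            wave_span = 0.35) {
  stopifnot(rate > 0, run_cadence > walk_cadence,
            sway_amp >= 0, walk_amp >= 0, run_amp >= 0,
            stumble_press_amp >= 0, run_flight_duty >= 0,
            run_flight_duty < 1)
  cfg <- as.list(environment())
  class(cfg) <- "gait_sim_config"
  cfg
}

# Insole geometry: pressure sensor index groups (heel -> toe along the
# insole; alternating medial/lateral bands).
insole_geometry <- function() {
  list(
    heel = 0:4, midfoot = 5:10, toe = 11:15,
    medial = c(0, 2, 4, 6, 8, 10, 12, 14),
    lateral = c(1, 3, 5, 7, 9, 11, 13, 15)
  )
}

# Squared raised cosine: periodic at `cadence`, fundamental dominant.
gait_wave <- function(t, cadence, phase) {
  (0.5 + 0.5 * sin(2 * pi * (cadence * t - phase)))^2
}

# Poisson-timed burst envelope: 1 within `len` frames after each burst onset.
burst_envelope <- function(n, rate_hz, sample_rate, len) {
  n_bursts <- stats::rpois(1, rate_hz * n / sample_rate)
  env <- rep(0, n)
  if (n_bursts > 0) {
    starts <- sort(sample.int(n, min(n_bursts, n)))
    for (s in starts) env[s:min(n, s + len - 1L)] <- 1
  }
  env
}

#' Simulate one labelled recording
#'
#' Generates `round(rate * duration)` frames of 20-channel telemetry for one
#' event, bitwise-reproducible for a given configuration and recording id.
#'
#' @param config A [gait_sim_config()].
#' @param event One of [gait_events()].
#' @param recording_id Identifier; also salts the per-recording sub-seed.
#' @param subject_id Identifier (default `"sim"`).
#' @return A one-row nested recordings tibble (same shape as
#'   [load_recordings()] output).
#' @export
simulate_recording <- function(config, event, recording_id,
                               subject_id = "sim") {
  stopifnot(inherits(config, "gait_sim_config"))
  assert_event(event)
  if (config$duration <= 0) {
    rlang::abort("duration must be positive", class = "gait_schema_error")
  }
  n <- round(config$rate * config$duration)
  tt <- (seq_len(n) - 1) / config$rate
  geom <- insole_geometry()
  phase <- config$wave_span * (0:15) / 15
  sub_seed <- derive_seed(config$seed, match(event, gait_events()),
                          sum(utf8ToInt(as.character(recording_id))))
  frames <- with_seed(sub_seed, {
    P <- matrix(0, nrow = n, ncol = 16)
    ax <- stats::rnorm(n, 0, config$accel_noise)
    ay <- stats::rnorm(n, 0, config$accel_noise)
    az <- 1 + stats::rnorm(n, 0, config$accel_noise)
    if (event == "sitting") {
      P[] <- config$sit_base +
        stats::rnorm(n * 16, 0, config$sit_noise)
      env <- burst_envelope(n, config$sit_shift_rate, config$rate, 4L)
      if (any(env > 0)) {
        sensors <- sample(0:15, 6) + 1L
        P[env > 0, sensors] <- P[env > 0, sensors] + config$sit_shift_amp
      }
    } else if (event %in% c("standing_still", "standing_imbalance")) {
      base <- numeric(16)
      base[geom$heel + 1L] <- config$stand_heel
      base[geom$midfoot + 1L] <- config$stand_mid
      base[geom$toe + 1L] <- config$stand_toe
      P <- matrix(base, nrow = n, ncol = 16, byrow = TRUE) +
        stats::rnorm(n * 16, 0, config$stand_noise)
      env <- burst_envelope(n, config$stand_tap_rate, config$rate, 2L)
      if (any(env > 0)) {
        P[env > 0, geom$toe + 1L] <- P[env > 0, geom$toe + 1L] +
          config$stand_tap_amp
      }
      if (event == "standing_imbalance") {
        sway <- sin(2 * pi * config$sway_freq * tt)
        P[, geom$medial + 1L] <- P[, geom$medial + 1L] +
          config$sway_amp * sway
        P[, geom$lateral + 1L] <- P[, geom$lateral + 1L] -
          config$sway_amp * sway
        ax <- ax + config$sway_accel_amp * sway
        ay <- ay + 0.5 * config$sway_accel_amp *
          sin(2 * pi * config$sway_freq * tt + pi / 3)
      }
    } else {
      # gait events: walking, running, stumbling
      cad <- if (event == "running") config$run_cadence else config$walk_cadence
      amp <- if (event == "running") config$run_amp else config$walk_amp
      a_amp <- if (event == "running") config$run_accel_amp else config$walk_accel_amp
      for (i in 1:16) {
        P[, i] <- amp * gait_wave(tt, cad, phase[i])
      }
      if (event == "running") {
        gate <- as.numeric((cad * tt) %% 1 < 1 - config$run_flight_duty)
        P <- P * gate
      }
      P <- P + stats::rnorm(n * 16, 0, config$gait_noise)
      ax <- ax + a_amp * sin(2 * pi * cad * tt)
      az <- az + a_amp * abs(sin(2 * pi * cad * tt))
      if (event == "stumbling") {
        env <- burst_envelope(n, config$stumble_rate, config$rate,
                              as.integer(config$stumble_len))
        hit <- which(env > 0)
        if (length(hit) > 0) {
          ax[hit] <- ax[hit] + config$stumble_accel_amp *
            (1 + 0.2 * stats::rnorm(length(hit)))
          ay[hit] <- ay[hit] + 0.7 * config$stumble_accel_amp *
            stats::rnorm(length(hit))
          jitter <- matrix(stats::runif(length(hit) * 16, -1, 1) *
                             config$stumble_press_amp,
                           nrow = length(hit))
          jitter[, sample.int(16, 8)] <- 0
          P[hit, ] <- P[hit, ] + jitter
        }
      }
    }
    P[P < 0] <- 0
    temp <- config$temp_base +
      cumsum(stats::rnorm(n, 0, config$temp_drift_sd))
    out <- tibble::as_tibble(
      stats::setNames(as.data.frame(P), paste0("p", 0:15)))
    out$temp <- temp
    out$ax <- ax; out$ay <- ay; out$az <- az
    out <- tibble::add_column(
      out,
      timestamp = as.POSIXct("2021-01-01 00:00:00", tz = "UTC") + tt,
      .before = 1)
    out
  })
  rec <- tibble::tibble(
    recording_id = as.character(recording_id),
    subject_id = as.character(subject_id),
    event = event, n_frames = n, frames = list(frames)
  )
  attr(rec, "nominal_rate") <- config$rate
  class(rec) <- c("gait_recordings", class(rec))
  rec
}

#' Simulate a labelled multi-event dataset
#'
#' Generates the requested number of independent recordings per event, each
#' with a distinct sub-seed derived deterministically from the master seed.
#'
#' @param config A [gait_sim_config()].
#' @param counts Named integer vector or list, events to recording counts
#'   (events absent from `counts` get zero recordings).
#' @return A nested recordings tibble.
#' @export
#' @examples
#' recs <- simulate_dataset(gait_sim_config(seed = 7, duration = 10),
#'                          counts = c(walking = 2, running = 1))
simulate_dataset <- function(config, counts) {
  stopifnot(inherits(config, "gait_sim_config"))
  counts <- unlist(counts)
  assert_event(names(counts))
  stopifnot(all(counts >= 0))
  recs <- purrr::map(names(counts), function(ev) {
    k <- counts[[ev]]
    if (k == 0) return(NULL)
    purrr::map(seq_len(k), function(i) {
      simulate_recording(config, ev, sprintf("%s_%03d", ev, i))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (nrow(recs) == 0) return(empty_recordings(config$rate))
  attr(recs, "nominal_rate") <- config$rate
  class(recs) <- c("gait_recordings", class(recs))
  recs
}

#' Recording counts proportional to the observed event mix
#'
#' The labelled corpus behind the method had an uneven event mix (walking
#' most frequent, stumbling rarest). This helper scales that mix to a total
#' recording budget, keeping at least one recording per event.
#'
#' @param scale Divisor applied to the observed per-event sample counts.
#' @return Named integer vector of recordings per event.
#' @export
event_mix_counts <- function(scale = 100) {
  obs <- c(sitting = 3020, standing_still = 6920, standing_imbalance = 5230,
           walking = 9620, running = 3480, stumbling = 820)
  n <- pmax(1L, as.integer(round(obs / scale)))
  stats::setNames(n, names(obs))
}
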