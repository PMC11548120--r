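#' Simulate a rumen temperature stream with drinking-induced drops
#'
#' Produces samples at `temp_interval` spacing. At each drinking time the
#' next temperature sample drops abruptly by `drink_drop` degrees (the cold
#' water mixing into the rumen) and then relaxes exponentially back toward
#' the baseline with time constant `recovery_tau`. Independent Gaussian
#' noise of sd `temp_noise_sd` is added to every sample.
#'
#' @param config A [sim_config()].
#' @param drink_times Numeric vector of drinking event times in seconds,
#'   all within `[0, duration]`.
#' @return A [temp_series()].
#' @examples
#' cfg <- sim_config(3600 * 4, temp_noise_sd = 0, rng_seed = 1)
#' ts <- simulate_temperature(cfg, drink_times = 3600)
#' @export
simulate_temperature <- function(config, drink_times = numeric()) {
  stopifnot(inherits(config, "sim_config"))
  if (length(drink_times) &&
      (any(drink_times < 0) || any(drink_times > config$duration)))
    stop("drink times must lie within [0, duration]", call. = FALSE)
  times <- seq(0, config$duration, by = config$temp_interval)
  vals <- rep(config$baseline_temp, length(times))
  for (ev in drink_times) {
    idx <- which(times > ev)
    if (!length(idx)) next
    s0 <- times[idx[1]]
    vals[idx] <- vals[idx] -
      config$drink_drop * exp(-(times[idx] - s0) / config$recovery_tau)
  }
  if (config$temp_noise_sd > 0) {
    vals <- vals + with_sim_seed(config, 1L, function()
      stats::rnorm(length(times), 0, config$temp_noise_sd))
  }
  temp_series(times, vals)
}

# Piecewise-constant bpm lookup; falls back to the config default when the
# profile is empty.
profile_bpm <- function(hr_profile, t, default_bpm) {
  if (is.null(hr_profile) || nrow(hr_profile) == 0L) return(default_bpm)
  o <- order(hr_profile$time_s)
  starts <- hr_profile$time_s[o]
  bpm <- hr_profile$bpm[o]
  i <- findInterval(t, starts)
  ifelse(i == 0, bpm[1], bpm[pmax(i, 1)])
}

# Beat onset times over [0, duration] for a piecewise-constant bpm profile.
beat_times <- function(hr_profile, duration, default_bpm) {
  out <- numeric(0)
  t <- 0
  while (t < duration) {
    bpm <- profile_bpm(hr_profile, t, default_bpm)
    if (bpm <= 0) stop("heart rate must be > 0 bpm", call. = FALSE)
    out <- c(out, t)
    t <- t + 60 / bpm
  }
  out
}

#' Simulate the 3-axis acceleration stream
#'
#' The generated signal is the sum of: a constant-orientation gravity
#' vector of norm `gravity_g`; aperiodic Gaussian motion bursts during the
#' log's activity bouts (amplitude scaled by the bout's intensity class);
#' square-wave-modulated bursts during rumination intervals, cycling
#' between short active chewing phases and quiet gaps with full periods in
#' `rum_period_range`; a periodic biphasic heartbeat pulse train following
#' the log's heart-rate profile; and per-axis white noise.
#'
#' The heartbeat pulse is biphasic (one positive and one negative lobe per
#' beat) so that both maxima and minima recur once per cardiac cycle, as
#' the heart-rate front-end expects.
#'
#' @param config A [sim_config()].
#' @param events An [event_log()]; intervals must lie within the configured
#'   duration.
#' @return An [accel_series()] at `config$accel_rate`.
#' @export
simulate_acceleration <- function(config, events = event_log()) {
  stopifnot(inherits(config, "sim_config"), inherits(events, "event_log"))
  n <- floor(config$duration * config$accel_rate)
  if (n < 1L) stop("duration too short for one acceleration sample",
                   call. = FALSE)
  times <- (seq_len(n) - 1) / config$accel_rate
  acc <- matrix(0, nrow = n, ncol = 3)

  ## gravity: fixed direction, optionally rotating slowly about z
  if (is.null(config$reorient_period)) {
    acc <- acc + matrix(rep(config$gravity_dir * config$gravity_g, each = n),
                        nrow = n)
  } else {
    th <- 2 * pi * times / config$reorient_period
    d <- config$gravity_dir
    acc[, 1] <- config$gravity_g * (d[1] * cos(th) - d[2] * sin(th))
    acc[, 2] <- config$gravity_g * (d[1] * sin(th) + d[2] * cos(th))
    acc[, 3] <- config$gravity_g * d[3]
  }

  with_sim_seed(config, 2L, function() {
    ## general motion bouts: aperiodic Gaussian bursts
    ab <- events$activity_bouts
    if (!is.null(ab) && nrow(ab)) {
      for (b in seq_len(nrow(ab))) {
        if (ab$end[b] > config$duration + 1e-9 || ab$start[b] < 0)
          stop("activity bout outside simulated duration", call. = FALSE)
        m <- times >= ab$start[b] & times < ab$end[b]
        k <- sum(m)
        if (k && config$activity_amp > 0) {
          amp <- config$activity_amp * ab$class[b]
          acc[m, ] <<- acc[m, ] + matrix(stats::rnorm(3 * k, 0, amp / 3),
                                         ncol = 3)
        }
      }
    }

    ## rumination: square-wave cycling of burst intensity
    ri <- events$rumination_intervals
    if (!is.null(ri) && nrow(ri) && config$rum_amp > 0) {
      for (b in seq_len(nrow(ri))) {
        if (ri$end[b] > config$duration + 1e-9 || ri$start[b] < 0)
          stop("rumination interval outside simulated duration", call. = FALSE)
        base <- stats::runif(1, config$rum_period_range[1],
                             config$rum_period_range[2])
        t0 <- ri$start[b]
        while (t0 < ri$end[b]) {
          j <- config$rum_period_jitter
          period <- base * stats::runif(1, 1 - j, 1 + j)
          period <- min(max(period, config$rum_period_range[1]),
                        config$rum_period_range[2])
          act <- stats::runif(1, config$rum_active_range[1],
                              config$rum_active_range[2])
          m <- times >= t0 & times < min(t0 + act, ri$end[b])
          k <- sum(m)
          if (k) acc[m, ] <<- acc[m, ] +
              matrix(stats::rnorm(3 * k, 0, config$rum_amp / 3), ncol = 3)
          t0 <- t0 + period
        }
      }
    }

    ## heartbeat: biphasic pulse train, weighted over axes
    if (config$heartbeat_amp > 0) {
      pulse_len <- 0.3 # seconds per biphasic pulse
      beats <- beat_times(events$hr_profile, config$duration,
                          config$heartbeat_bpm)
      w <- config$heartbeat_axes
      for (bt in beats) {
        i0 <- ceiling(bt * config$accel_rate) + 1L
        i1 <- min(floor((bt + pulse_len) * config$accel_rate) + 1L, n)
        if (i0 > n || i1 < i0) next
        u <- times[i0:i1] - bt
        p <- config$heartbeat_amp * sin(2 * pi * u / pulse_len)
        acc[i0:i1, ] <<- acc[i0:i1, ] + outer(p, w)
      }
    }

    ## sensor noise
    if (config$motion_noise_sd > 0)
      acc <<- acc + matrix(stats::rnorm(3 * n, 0, config$motion_noise_sd),
                           ncol = 3)
  })

  accel_series(times, acc[, 1], acc[, 2], acc[, 3],
               rate_hz = config$accel_rate)
}

# Place `n` interval starts in equal slots over [0, duration] with uniform
# jitter inside the middle of each slot, guaranteeing separation.
slotted_times <- function(n, duration, width = 0) {
  if (n < 1L) return(numeric())
  slot <- duration / n
  if (width >= slot)
    stop("bout duration too long for the requested bout count", call. = FALSE)
  starts <- (seq_len(n) - 1) * slot
  starts + stats::runif(n, 0.1 * slot, 0.9 * slot - width)
}

#' Generate a complete synthetic fixture
#'
#' Samples drinking times, rumination bouts, general-motion bouts and a
#' heart-rate profile from the configured daily rates, then simulates the
#' paired temperature and acceleration streams. The exact event log used
#' is returned alongside the streams, so detector outputs can be scored
#' against ground truth.
#'
#' @param config A [sim_config()].
#' @return A list of class `bolus_fixture` with elements `temperature`
#'   ([temp_series()]), `acceleration` ([accel_series()]) and `events`
#'   ([event_log()]).
#' @examples
#' fx <- make_fixture(sim_config(3600, rng_seed = 42))
#' @export
make_fixture <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  frac_day <- config$duration / 86400
  events <- with_sim_seed(config, 0L, function() {
    n_drink <- round(config$drink_events_per_day * frac_day)
    n_rum <- round(config$rum_bouts_per_day * frac_day)
    n_act <- round(config$activity_bouts_per_day * frac_day)

    drink <- slotted_times(n_drink, config$duration)

    rum_start <- slotted_times(n_rum, config$duration,
                               width = config$rum_bout_duration)
    rum <- data.frame(start = rum_start,
                      end = rum_start + config$rum_bout_duration)

    act <- data.frame(start = numeric(), end = numeric(), class = integer())
    if (n_act > 0) {
      cand <- slotted_times(n_act, config$duration,
                            width = config$activity_bout_duration)
      keep <- vapply(cand, function(s) {
        e <- s + config$activity_bout_duration
        !any(s < rum$end & e > rum$start)
      }, logical(1))
      cand <- cand[keep]
      act <- data.frame(start = cand,
                        end = cand + config$activity_bout_duration,
                        class = sample(1:3, length(cand), replace = TRUE))
    }

    event_log(drink_times = drink, rumination_intervals = rum,
              activity_bouts = act,
              hr_profile = data.frame(time_s = 0,
                                      bpm = config$heartbeat_bpm))
  })
  structure(list(temperature = simulate_temperature(config,
                                                    events$drink_times),
                 acceleration = simulate_acceleration(config, events),
                 events = events),
            class = "bolus_fixture")
}
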