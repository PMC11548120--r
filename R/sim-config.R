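#' Simulation configuration
#'
#' Parameters of the synthetic-signal generator that emulates the raw
#' streams a rumen bolus measures: a slowly varying rumen temperature with
#' abrupt drinking-induced drops, and a 3-axis acceleration signal composed
#' of a ~1 G gravity component, aperiodic motion bursts, square-wave-cycled
#' rumination bursts, a small periodic heartbeat pulse train and white
#' sensor noise.
#'
#' @param duration Total simulated time in seconds (> 0).
#' @param temp_interval Temperature sampling interval in seconds
#'   (default 300, i.e. one sample per 5 min).
#' @param accel_rate Accelerometer rate in Hz (12.5 for the activity and
#'   rumination paths, 25 for the heart-rate path).
#' @param baseline_temp Baseline rumen temperature in degrees C.
#' @param temp_noise_sd Standard deviation of i.i.d. Gaussian temperature
#'   noise, degrees C.
#' @param drink_drop Magnitude of the abrupt temperature drop caused by a
#'   drinking event, degrees C (>= 0).
#' @param recovery_tau Time constant of the exponential return to baseline
#'   after a drinking event, seconds (> 0).
#' @param gravity_g Norm of the gravity component, in G.
#' @param gravity_dir Length-3 direction of gravity in the sensor frame;
#'   normalised internally. Fixed per fixture (the bolus settles in the
#'   rumen; slow re-orientation can be emulated via `reorient_period`).
#' @param reorient_period Optional period in seconds of a slow rotation of
#'   the gravity direction about the z axis; `NULL` (default) keeps the
#'   orientation fixed.
#' @param motion_noise_sd Standard deviation of the per-axis white
#'   acceleration noise, G.
#' @param heartbeat_amp Amplitude of the heartbeat pulse, G.
#' @param heartbeat_axes Length-3 non-negative weights distributing the
#'   heartbeat pulse over the axes (the heart sits close to one axis).
#' @param heartbeat_bpm Default constant heart rate in beats per minute,
#'   used when a fixture's event log carries no explicit profile.
#' @param rum_amp Amplitude of the motion bursts during the active phase of
#'   a rumination cycle, G.
#' @param rum_period_range Length-2 range in seconds of the full
#'   active+passive rumination period (default 50-100 s).
#' @param rum_active_range Length-2 range in seconds of the active
#'   (chewing) part of each cycle.
#' @param rum_period_jitter Relative jitter applied to consecutive periods
#'   within one bout; a single base period per bout is drawn from
#'   `rum_period_range` and each cycle deviates by at most this fraction,
#'   so consecutive periods stay similar, as in real rumination.
#' @param activity_amp Base amplitude of general-motion bursts, G; scaled
#'   by the bout's intensity class (1-3).
#' @param drink_events_per_day Expected number of drinking events per day.
#' @param rum_bouts_per_day Expected number of rumination bouts per day.
#' @param rum_bout_duration Duration of a rumination bout, seconds.
#' @param activity_bouts_per_day Expected number of general-motion bouts
#'   per day.
#' @param activity_bout_duration Duration of a motion bout, seconds.
#' @param rng_seed Integer seed; identical seed and configuration give
#'   bit-identical output streams. `NULL` uses the current RNG state.
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(duration = 3600, rng_seed = 1)
#' @export
sim_config <- function(duration,
                       temp_interval = 300,
                       accel_rate = 12.5,
                       baseline_temp = 39.0,
                       temp_noise_sd = 0.1,
                       drink_drop = 3.0,
                       recovery_tau = 1800,
                       gravity_g = 1.0,
                       gravity_dir = c(0.36, 0.48, 0.80),
                       reorient_period = NULL,
                       motion_noise_sd = 0.01,
                       heartbeat_amp = 0.02,
                       heartbeat_axes = c(0.2, 1.0, 0.6),
                       heartbeat_bpm = 72,
                       rum_amp = 0.6,
                       rum_period_range = c(50, 100),
                       rum_active_range = c(8, 24),
                       rum_period_jitter = 0.05,
                       activity_amp = 0.5,
                       drink_events_per_day = 8,
                       rum_bouts_per_day = 4,
                       rum_bout_duration = 960,
                       activity_bouts_per_day = 6,
                       activity_bout_duration = 600,
                       rng_seed = NULL) {
  if (!is.numeric(duration) || duration <= 0)
    stop("`duration` must be > 0", call. = FALSE)
  if (temp_interval <= 0) stop("`temp_interval` must be > 0", call. = FALSE)
  if (accel_rate <= 0) stop("`accel_rate` must be > 0", call. = FALSE)
  if (drink_drop < 0) stop("`drink_drop` must be >= 0", call. = FALSE)
  if (recovery_tau <= 0) stop("`recovery_tau` must be > 0", call. = FALSE)
  if (temp_noise_sd < 0 || motion_noise_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  if (length(gravity_dir) != 3 || sum(gravity_dir^2) == 0)
    stop("`gravity_dir` must be a non-zero length-3 vector", call. = FALSE)
  if (length(rum_period_range) != 2 || diff(rum_period_range) < 0 ||
      rum_period_range[1] <= 0)
    stop("`rum_period_range` must be a positive ascending pair", call. = FALSE)
  if (length(rum_active_range) != 2 || diff(rum_active_range) < 0 ||
      rum_active_range[1] <= 0 || rum_active_range[2] >= rum_period_range[1])
    stop("`rum_active_range` must be positive, ascending and shorter than the minimum period",
         call. = FALSE)
  if (heartbeat_bpm <= 0)
    stop("`heartbeat_bpm` must be > 0", call. = FALSE)
  structure(list(
    duration = duration, temp_interval = temp_interval,
    accel_rate = accel_rate, baseline_temp = baseline_temp,
    temp_noise_sd = temp_noise_sd, drink_drop = drink_drop,
    recovery_tau = recovery_tau, gravity_g = gravity_g,
    gravity_dir = gravity_dir / sqrt(sum(gravity_dir^2)),
    reorient_period = reorient_period,
    motion_noise_sd = motion_noise_sd, heartbeat_amp = heartbeat_amp,
    heartbeat_axes = heartbeat_axes, heartbeat_bpm = heartbeat_bpm,
    rum_amp = rum_amp, rum_period_range = rum_period_range,
    rum_active_range = rum_active_range,
    rum_period_jitter = rum_period_jitter,
    activity_amp = activity_amp,
    drink_events_per_day = drink_events_per_day,
    rum_bouts_per_day = rum_bouts_per_day,
    rum_bout_duration = rum_bout_duration,
    activity_bouts_per_day = activity_bouts_per_day,
    activity_bout_duration = activity_bout_duration,
    rng_seed = rng_seed), class = "sim_config")
}

#' Ground-truth event log
#'
#' The labels attached to a simulated fixture: drinking times, rumination
#' intervals, general-motion bouts with their intensity class, and a
#' piecewise-constant heart-rate profile.
#'
#' @param drink_times Numeric vector of drinking event times, seconds.
#' @param rumination_intervals Data frame with columns `start`, `end`
#'   (seconds); intervals must be non-overlapping.
#' @param activity_bouts Data frame with columns `start`, `end`, `class`
#'   (intensity class 1-3); non-overlapping.
#' @param hr_profile Data frame with columns `time_s` (segment start) and
#'   `bpm`; each rate holds from its start time to the next. All rates
#'   must be positive.
#' @return An `event_log` list.
#' @export
event_log <- function(drink_times = numeric(),
                      rumination_intervals = data.frame(start = numeric(),
                                                        end = numeric()),
                      activity_bouts = data.frame(start = numeric(),
                                                  end = numeric(),
                                                  class = integer()),
                      hr_profile = data.frame(time_s = numeric(),
                                              bpm = numeric())) {
  check_intervals <- function(d, what) {
    if (nrow(d) == 0L) return(invisible())
    if (any(d$end <= d$start))
      stop(what, " intervals must have end > start", call. = FALSE)
    o <- order(d$start)
    if (any(d$start[o][-1] < d$end[o][-nrow(d)]))
      stop(what, " intervals must not overlap", call. = FALSE)
  }
  check_intervals(rumination_intervals, "rumination")
  check_intervals(activity_bouts, "activity")
  if (nrow(hr_profile) > 0 && any(hr_profile$bpm <= 0))
    stop("heart rates must be > 0 bpm", call. = FALSE)
  structure(list(drink_times = sort(as.numeric(drink_times)),
                 rumination_intervals = rumination_intervals,
                 activity_bouts = activity_bouts,
                 hr_profile = hr_profile),
            class = "event_log")
}

# Run `fn()` under a temporary seed derived from the config, restoring the
# caller's RNG state afterwards; with a NULL seed the ambient RNG is used.
with_sim_seed <- function(config, offset, fn) {
  if (is.null(config$rng_seed)) return(fn())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(config$rng_seed) + as.integer(offset))
  fn()
}

#' Serialize / read an event log as JSON
#' @param log An `event_log`.
#' @param path File path.
#' @export
write_event_log <- function(log, path) {
  jsonlite::write_json(unclass(log), path, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_df <- function(d, cols) {
    if (is.null(d) || length(d) == 0 || (is.list(d) && length(d[[1]]) == 0)) {
      return(stats::setNames(as.data.frame(rep(list(numeric()), length(cols))),
                             cols))
    }
    as.data.frame(d)
  }
  event_log(drink_times = unlist(x$drink_times),
            rumination_intervals = as_df(x$rumination_intervals,
                                         c("start", "end")),
            activity_bouts = as_df(x$activity_bouts,
                                   c("start", "end", "class")),
            hr_profile = as_df(x$hr_profile, c("time_s", "bpm")))
}
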