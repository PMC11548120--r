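#' Envelope state for rumination detection
#'
#' The rumination path tracks an envelope of the raw motion intensity:
#' instant attack (a new intensity above the envelope replaces it
#' immediately) and smoothed exponential decay otherwise. This keeps short
#' chewing bursts visible long enough for threshold crossings to be
#' reliable.
#'
#' @param ie Current envelope value (>= 0).
#' @param beta Decay averager parameter in (0, 1]; shared default with the
#'   activity smoother.
#' @return An `envelope_state` list.
#' @export
envelope_state <- function(ie = 0, beta = 0.05) {
  if (ie < 0) stop("`ie` must be >= 0", call. = FALSE)
  if (beta <= 0 || beta > 1) stop("`beta` must be in (0, 1]", call. = FALSE)
  structure(list(ie = ie, beta = beta), class = "envelope_state")
}

#' One envelope update
#'
#' If the new intensity exceeds the envelope the envelope jumps to it;
#' otherwise it decays as `ie' = beta * i + (1 - beta) * ie`.
#'
#' @param state An [envelope_state()].
#' @param i New intensity (>= 0).
#' @return Updated [envelope_state()].
#' @examples
#' envelope_step(envelope_state(100), 500)$ie # 500 (attack)
#' @export
envelope_step <- function(state, i) {
  stopifnot(inherits(state, "envelope_state"))
  if (i < 0) stop("intensity must be >= 0", call. = FALSE)
  state$ie <- if (i > state$ie) i else
    state$beta * i + (1 - state$beta) * state$ie
  state
}

# Vectorised envelope over an intensity vector.
envelope_series <- function(i, beta = 0.05, init = 0) {
  out <- numeric(length(i))
  e <- init
  for (n in seq_along(i)) {
    e <- if (i[n] > e) i[n] else beta * i[n] + (1 - beta) * e
    out[n] <- e
  }
  out
}

#' Rumination detector parameters
#'
#' Rumination shows up as a regular cycle: a short active chewing burst
#' followed by a longer quiet gap, repeating with a full period of 50-100 s.
#' The detector applies hysteresis thresholding to the envelope intensity,
#' measures active-part and full-period lengths in samples, and confirms
#' rumination only after `k` consecutive full periods of similar length.
#'
#' @param th_h High threshold: the active state starts when the envelope
#'   rises to it. Default 6000 (raw intensity scale).
#' @param th_l Low threshold: the active state ends when the envelope
#'   falls to it. Default 3500.
#' @param t_act_min,t_act_max Accepted active-part length in samples
#'   (default 25-375, i.e. 2-30 s at 12.5 Hz).
#' @param t_int_min,t_int_max Accepted full-period length in samples
#'   (default 625 and 1250, i.e. 50 and 100 s at 12.5 Hz).
#' @param k Number of consecutive similar periods required to confirm
#'   rumination (default 5, must be >= 2).
#' @param delta_t_im Relative similarity tolerance: the `k` buffered
#'   periods are similar when `min/max > 1 - delta_t_im` (default 0.2).
#' @param enforce_hysteresis Require `th_h >= th_l` (default `TRUE`).
#'   Setting `FALSE` permits an inverted pair for experimentation.
#' @return A `rumination_params` list.
#' @export
rumination_params <- function(th_h = 6000, th_l = 3500,
                              t_act_min = 25L, t_act_max = 375L,
                              t_int_min = 625L, t_int_max = 1250L,
                              k = 5L, delta_t_im = 0.2,
                              enforce_hysteresis = TRUE) {
  if (enforce_hysteresis && th_h < th_l)
    stop("`th_h` must be >= `th_l` for hysteresis", call. = FALSE)
  if (!(t_int_min > 0 && t_int_min < t_int_max))
    stop("need 0 < t_int_min < t_int_max", call. = FALSE)
  if (!(t_act_min > 0 && t_act_min < t_act_max))
    stop("need 0 < t_act_min < t_act_max", call. = FALSE)
  if (delta_t_im <= 0 || delta_t_im >= 1)
    stop("`delta_t_im` must be in (0, 1)", call. = FALSE)
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  structure(list(th_h = th_h, th_l = th_l,
                 t_act_min = t_act_min, t_act_max = t_act_max,
                 t_int_min = t_int_min, t_int_max = t_int_max,
                 k = as.integer(k), delta_t_im = delta_t_im),
            class = "rumination_params")
}

#' Rumination detector state
#'
#' Tracks the activity state `s` (0 inactive, 1 active), the sample
#' numbers of the last active-period start (`t0`) and end (`t1`), a FIFO
#' buffer `L` of up to `k` full-period lengths, the cumulated rumination
#' count `c` in samples, and the ongoing-rumination flag `o`. Interval
#' bookkeeping (`cur_start`, `cur_end`, `intervals`) records the confirmed
#' rumination stretches.
#'
#' @return A `rumination_state` list.
#' @export
rumination_state <- function() {
  structure(list(s = 0L, t0 = NA_real_, t1 = NA_real_,
                 L = numeric(), c = 0, o = 0L,
                 cur_start = NA_real_, cur_end = NA_real_,
                 intervals = list()),
            class = "rumination_state")
}

# Close any open confirmed interval and reset confirmation.
rum_reset_confirmation <- function(state) {
  if (state$o == 1L && !is.na(state$cur_start)) {
    state$intervals[[length(state$intervals) + 1L]] <-
      c(state$cur_start, state$cur_end)
  }
  state$cur_start <- NA_real_
  state$cur_end <- NA_real_
  state$o <- 0L
  state$L <- numeric()
  state
}

#' Advance the rumination detector by one envelope sample
#'
#' On a rising crossing of `th_h` a new active period starts; the elapsed
#' samples since the previous active start form the just-completed full
#' period. A period outside `[t_int_min, t_int_max]` interrupts the
#' pattern (buffer cleared, confirmation dropped); an in-range period is
#' appended to the FIFO buffer. When the buffer holds `k` periods whose
#' `min/max` ratio exceeds `1 - delta_t_im`, rumination is confirmed: on a
#' fresh confirmation the whole buffered time `sum(L)` is credited at
#' once, afterwards each further period adds its own length. On a falling
#' crossing of `th_l` the active part ends; an active part outside
#' `[t_act_min, t_act_max]` also interrupts the pattern. The very first
#' active onset has no preceding period and only arms the period clock.
#'
#' @param state A [rumination_state()].
#' @param t Current sample number (strictly increasing across calls).
#' @param ie Envelope intensity at this sample.
#' @param params A [rumination_params()].
#' @return Updated [rumination_state()].
#' @export
rumination_step <- function(state, t, ie, params = rumination_params()) {
  stopifnot(inherits(state, "rumination_state"),
            inherits(params, "rumination_params"))
  if (state$s == 0L && ie >= params$th_h) {
    state$s <- 1L
    if (is.na(state$t0)) {
      state$t0 <- t
    } else {
      l <- t - state$t0
      state$t0 <- t
      if (l < params$t_int_min || l > params$t_int_max) {
        state <- rum_reset_confirmation(state)
      } else {
        state$L <- c(state$L, l)
        if (length(state$L) > params$k) state$L <- state$L[-1L]
        if (length(state$L) == params$k &&
            min(state$L) / max(state$L) > 1 - params$delta_t_im) {
          if (state$o == 0L) {
            state$c <- state$c + sum(state$L)
            state$o <- 1L
            state$cur_start <- t - sum(state$L)
          } else {
            state$c <- state$c + l
          }
          state$cur_end <- t
        }
      }
    }
  }
  if (state$s == 1L && ie <= params$th_l) {
    state$s <- 0L
    state$t1 <- t
    l_act <- t - state$t0
    if (l_act < params$t_act_min || l_act > params$t_act_max)
      state <- rum_reset_confirmation(state)
  }
  state
}

#' Detect rumination in an acceleration stream
#'
#' Chains the gravity filter, intensity computation and envelope over the
#' stream, then folds [rumination_step()] over the envelope. The cumulated
#' count is converted from samples to seconds with the nominal rate.
#'
#' @param series An [accel_series()].
#' @param params A [rumination_params()]. Note that the default thresholds
#'   are on a raw-sensor intensity scale; for streams in G choose
#'   thresholds on the same scale as the intensity (e.g. a fraction of the
#'   burst amplitude).
#' @param activity An [activity_params()] supplying `alpha` and `beta`.
#' @return A list with `seconds` (cumulated rumination time),
#'   `samples` (the raw cumulated count), `intervals` (data frame of
#'   confirmed stretches, seconds) and `state` (final detector state).
#' @export
detect_rumination <- function(series, params = rumination_params(),
                              activity = activity_params()) {
  stopifnot(inherits(series, "accel_series"))
  if (nrow(series) == 0L) stop("empty series", call. = FALSE)
  chain <- intensity_series(series, activity)
  env <- envelope_series(chain$intensity, beta = activity$beta)
  st <- rumination_state()
  for (n in seq_along(env)) st <- rumination_step(st, n, env[n], params)
  ## close an interval still open at end of stream
  if (st$o == 1L && !is.na(st$cur_start)) {
    st$intervals[[length(st$intervals) + 1L]] <- c(st$cur_start, st$cur_end)
  }
  rate <- accel_rate(series)
  iv <- if (length(st$intervals)) {
    m <- do.call(rbind, st$intervals)
    data.frame(start_s = series$time_s[pmax(m[, 1], 1)],
               end_s = series$time_s[pmin(m[, 2], nrow(series))])
  } else {
    data.frame(start_s = numeric(), end_s = numeric())
  }
  list(seconds = st$c / rate, samples = st$c, intervals = iv, state = st)
}
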