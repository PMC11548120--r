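#' Drinking detector parameters
#'
#' A drinking event appears in the rumen temperature stream as an abrupt
#' drop: a large volume of cold water enters the rumen and the measured
#' temperature falls by several degrees within one sampling interval
#' before slowly recovering. The detector compares consecutive samples
#' against a drop threshold and enforces a refractory window so a single
#' event is not counted twice.
#'
#' @param th Drop threshold in degrees C (default 2.0). The sensor's noise
#'   floor makes thresholds below 1 degree unreliable, so `th >= 1` is
#'   enforced.
#' @param w Refractory window in samples (default 2, i.e. 10 min at one
#'   sample per 5 min): at most one detection within any `w` consecutive
#'   samples.
#' @return A `drinking_params` list.
#' @export
drinking_params <- function(th = 2.0, w = 2L) {
  if (!is.numeric(th) || th < 1.0)
    stop("`th` must be >= 1 degree C", call. = FALSE)
  w <- as.integer(w)
  if (is.na(w) || w < 1L)
    stop("`w` must be an integer >= 1", call. = FALSE)
  structure(list(th = th, w = w), class = "drinking_params")
}

#' Drinking detector state
#'
#' @param t_last Last observed temperature, degrees C.
#' @param r Samples remaining until the next possible detection (0 when
#'   armed).
#' @param c Event counter.
#' @return A `drinking_state` list.
#' @export
drinking_state <- function(t_last, r = 0L, c = 0L) {
  if (!is.finite(t_last)) stop("`t_last` must be finite", call. = FALSE)
  structure(list(r = as.integer(r), t_last = as.numeric(t_last),
                 c = as.integer(c)),
            class = "drinking_state")
}

#' Advance the drinking detector by one temperature sample
#'
#' Implements the per-sample transition: if the new temperature is more
#' than `th` below the previous one and the detector is armed (`r == 0`),
#' the event counter increments and the refractory window is loaded with
#' `w`; any positive refractory count then decrements; finally the stored
#' temperature is updated. The stored temperature updates on *every*
#' sample, so a gradual decline spread over many samples never trips the
#' detector - only abrupt drops do.
#'
#' @param state A [drinking_state()].
#' @param t New temperature sample, degrees C (finite).
#' @param params A [drinking_params()].
#' @return A list with elements `state` (updated [drinking_state()]) and
#'   `fired` (logical, whether this sample was counted as a drinking
#'   event).
#' @examples
#' st <- drinking_state(t_last = 39.0)
#' drinking_step(st, 36.5, drinking_params())$fired # TRUE
#' @export
drinking_step <- function(state, t, params = drinking_params()) {
  stopifnot(inherits(state, "drinking_state"),
            inherits(params, "drinking_params"))
  if (!is.finite(t)) stop("temperature sample must be finite", call. = FALSE)
  fired <- FALSE
  if (t < state$t_last - params$th && state$r == 0L) {
    state$c <- state$c + 1L
    state$r <- params$w
    fired <- TRUE
  }
  if (state$r > 0L) state$r <- state$r - 1L
  state$t_last <- t
  list(state = state, fired = fired)
}

#' Detect drinking events in a temperature series
#'
#' Folds [drinking_step()] over the stream. The stored temperature is
#' initialised to the first sample and stepping starts from the second,
#' which prevents a spurious detection at startup. Reported timestamps are
#' those of the low sample that fired.
#'
#' @param series A [temp_series()].
#' @param params A [drinking_params()].
#' @return A list with `count` (integer) and `event_times` (seconds).
#' @examples
#' ts <- temp_series(c(0, 300, 600), c(39, 36.5, 36.4))
#' detect_drinking(ts)$count # 1
#' @export
detect_drinking <- function(series, params = drinking_params()) {
  stopifnot(inherits(series, "temp_series"))
  st <- drinking_state(t_last = series$temp_c[1])
  fired_at <- logical(nrow(series))
  for (i in seq_len(nrow(series))[-1]) {
    res <- drinking_step(st, series$temp_c[i], params)
    st <- res$state
    fired_at[i] <- res$fired
  }
  list(count = st$c, event_times = series$time_s[fired_at])
}
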