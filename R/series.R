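#' Time-stamped rumen temperature series
#'
#' Container for a rumen temperature stream as sampled by the bolus
#' (nominally one sample every 5 or 10 minutes). A plain data frame with
#' columns `time_s` (seconds, strictly increasing) and `temp_c` (degrees
#' Celsius), carrying class `temp_series`.
#'
#' @param time_s Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param temp_c Numeric vector of temperatures in degrees Celsius, same
#'   length as `time_s`.
#' @return A `temp_series` data frame.
#' @examples
#' ts <- temp_series(c(0, 300, 600), c(39.0, 39.1, 36.8))
#' @export
temp_series <- function(time_s, temp_c) {
  time_s <- as.numeric(time_s)
  temp_c <- as.numeric(temp_c)
  if (length(time_s) != length(temp_c))
    stop("`time_s` and `temp_c` must have the same length", call. = FALSE)
  if (length(time_s) == 0L)
    stop("temperature series must be non-empty", call. = FALSE)
  if (any(!is.finite(time_s)) || any(!is.finite(temp_c)))
    stop("temperature series must be finite", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("`time_s` must be strictly increasing", call. = FALSE)
  structure(data.frame(time_s = time_s, temp_c = temp_c),
            class = c("temp_series", "data.frame"))
}

#' Time-stamped 3-axis acceleration series
#'
#' Container for the accelerometer stream: columns `time_s` (seconds,
#' strictly increasing at the nominal rate) and `ax`, `ay`, `az`
#' (acceleration per axis, in G). Carries class `accel_series` and a
#' `rate_hz` attribute with the nominal sampling rate.
#'
#' @param time_s Numeric vector of sample times in seconds.
#' @param ax,ay,az Numeric per-axis acceleration in G.
#' @param rate_hz Nominal sampling rate in Hz. Inferred from the median
#'   time step when `NULL`.
#' @return An `accel_series` data frame.
#' @export
accel_series <- function(time_s, ax, ay, az, rate_hz = NULL) {
  n <- length(time_s)
  if (n == 0L) stop("acceleration series must be non-empty", call. = FALSE)
  if (length(ax) != n || length(ay) != n || length(az) != n)
    stop("axis vectors must match `time_s` in length", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("`time_s` must be strictly increasing", call. = FALSE)
  if (is.null(rate_hz)) {
    rate_hz <- if (n > 1L) 1 / stats::median(diff(time_s)) else NA_real_
  }
  structure(data.frame(time_s = as.numeric(time_s), ax = as.numeric(ax),
                       ay = as.numeric(ay), az = as.numeric(az)),
            rate_hz = rate_hz,
            class = c("accel_series", "data.frame"))
}

#' Nominal sampling rate of an acceleration series
#' @param series An `accel_series`.
#' @return Rate in Hz.
#' @export
accel_rate <- function(series) {
  r <- attr(series, "rate_hz")
  if (is.null(r) || !is.finite(r))
    r <- 1 / stats::median(diff(series$time_s))
  r
}

#' Convert a duration in seconds to a sample count
#'
#' Unit conversion used throughout the rumination and heart-rate paths,
#' e.g. 50 s at 12.5 Hz corresponds to 625 samples.
#'
#' @param seconds Duration in seconds.
#' @param rate_hz Sampling rate in Hz.
#' @return Number of samples (numeric; exact when the product is integral).
#' @examples
#' seconds_to_samples(50, 12.5) # 625
#' @export
seconds_to_samples <- function(seconds, rate_hz) {
  stopifnot(rate_hz > 0)
  seconds * rate_hz
}

#' Read / write sensor streams as CSV
#'
#' Plain-text interchange format: `time_s,temp_c` for temperature and
#' `time_s,ax,ay,az` for acceleration.
#'
#' @param path File path.
#' @return The parsed series object.
#' @export
read_temp_csv <- function(path) {
  d <- utils::read.csv(path)
  temp_series(d$time_s, d$temp_c)
}

#' @rdname read_temp_csv
#' @param series Series to write.
#' @export
write_temp_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_temp_csv
#' @export
read_accel_csv <- function(path) {
  d <- utils::read.csv(path)
  accel_series(d$time_s, d$ax, d$ay, d$az)
}

#' @rdname read_temp_csv
#' @export
write_accel_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
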