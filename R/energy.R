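#' Radio profile for the LPWAN uplink
#'
#' Transmission characteristics of the hourly uplink. At the allowed
#' spreading factors the full 51-byte packet takes a fixed air time
#' (SF10: 416 ms, SF11: 927 ms, SF12: 1632 ms at bitrates 980, 440 and
#' 250 bps); the radio otherwise sits in standby.
#'
#' @param sf Spreading factor, one of 10, 11, 12 (default 12, the
#'   worst-case air time with the best link budget).
#' @param t_period Seconds between packets (default 3600).
#' @param i_tx_ma Active transmit current, mA (default 120, worst case).
#' @param i_st_ma Standby current of MCU + sensors + radio, mA
#'   (default 0.1, a flat worst-case bound).
#' @param t_tx Override the air time in seconds; defaults to the value for
#'   `sf`.
#' @return A `radio_profile` list with `t_tx`, `t_period`, `i_tx_ma`,
#'   `i_st_ma`, `bitrate_bps`.
#' @export
radio_profile <- function(sf = 12, t_period = 3600, i_tx_ma = 120,
                          i_st_ma = 0.1, t_tx = NULL) {
  sf <- as.character(sf)
  ttx_map <- c(`10` = 0.416, `11` = 0.927, `12` = 1.632)
  bps_map <- c(`10` = 980, `11` = 440, `12` = 250)
  if (is.null(t_tx)) {
    if (!sf %in% names(ttx_map))
      stop("`sf` must be 10, 11 or 12", call. = FALSE)
    t_tx <- ttx_map[[sf]]
  }
  if (t_tx <= 0 || t_period <= 0 || t_tx >= t_period)
    stop("need 0 < t_tx < t_period", call. = FALSE)
  if (i_tx_ma <= 0 || i_st_ma <= 0)
    stop("currents must be > 0", call. = FALSE)
  structure(list(t_tx = t_tx, t_period = t_period, i_tx_ma = i_tx_ma,
                 i_st_ma = i_st_ma,
                 bitrate_bps = if (sf %in% names(bps_map)) bps_map[[sf]]
                               else NA_real_),
            class = "radio_profile")
}

#' Radio duty cycle
#'
#' Fraction of time the radio transmits: `d = t_tx / t_period`.
#'
#' @param profile A [radio_profile()].
#' @return Duty cycle in (0, 1).
#' @examples
#' duty_cycle(radio_profile(sf = 12)) # ~0.45e-3
#' @export
duty_cycle <- function(profile) {
  stopifnot(inherits(profile, "radio_profile"))
  profile$t_tx / profile$t_period
}

#' Battery description
#' @param capacity_ah Capacity in ampere-hours (default 19, a D-type
#'   Li-SOCl2 cell).
#' @return A `battery` list.
#' @export
battery <- function(capacity_ah = 19) {
  if (capacity_ah <= 0) stop("capacity must be > 0", call. = FALSE)
  structure(list(capacity_ah = capacity_ah), class = "battery")
}

#' Battery lifetime under a duty-cycled radio load
#'
#' Mean current is the duty-cycle-weighted mix of active and standby
#' currents; lifetime in hours is `C / (d * i_tx + (1 - d) * i_st)` with
#' the capacity expressed in mAh. With the defaults (19 Ah cell, hourly
#' SF12 packets) the radio budget alone supports roughly 14 years.
#'
#' @param batt A [battery()].
#' @param profile A [radio_profile()].
#' @return A list with `hours`, `years` (raw values) and
#'   `years_display` (2 significant figures).
#' @export
lifetime <- function(batt = battery(), profile = radio_profile()) {
  stopifnot(inherits(batt, "battery"))
  d <- duty_cycle(profile)
  hours <- batt$capacity_ah * 1000 /
    (d * profile$i_tx_ma + (1 - d) * profile$i_st_ma)
  years <- hours / (24 * 365.25)
  list(hours = hours, years = years, years_display = signif(years, 2))
}

#' Sensing data budget for compression accounting
#'
#' Describes how many raw bytes the sensors produce per reporting period:
#' the accelerometer contributes `rate * axes * bytes_per_sample * period`
#' bytes and the temperature sensor `temp_per_period * temp_bytes` bytes.
#'
#' @param accel_rate_hz Accelerometer rate (default 12.5).
#' @param axes Number of axes (default 3).
#' @param bytes_per_sample Bytes per axis sample (default 2).
#' @param temp_per_period Temperature measurements per period (default 6,
#'   one per 10 min).
#' @param temp_bytes Bytes per temperature measurement (default 2).
#' @param period_s Period length in seconds (default 3600).
#' @param d_o Output bytes per period (default 51, one packet).
#' @return A `data_budget` list.
#' @export
data_budget <- function(accel_rate_hz = 12.5, axes = 3L,
                        bytes_per_sample = 2L, temp_per_period = 6L,
                        temp_bytes = 2L, period_s = 3600, d_o = 51L) {
  vals <- c(accel_rate_hz, axes, bytes_per_sample, temp_bytes, period_s,
            d_o)
  if (any(vals <= 0) || temp_per_period < 0)
    stop("budget fields must be positive", call. = FALSE)
  structure(list(accel_rate_hz = accel_rate_hz, axes = as.integer(axes),
                 bytes_per_sample = as.integer(bytes_per_sample),
                 temp_per_period = as.integer(temp_per_period),
                 temp_bytes = as.integer(temp_bytes), period_s = period_s,
                 d_o = as.integer(d_o)),
            class = "data_budget")
}

#' Raw input bytes per period
#' @param budget A [data_budget()].
#' @return Total sensor bytes produced in one period.
#' @examples
#' input_bytes(data_budget()) # 270012
#' @export
input_bytes <- function(budget = data_budget()) {
  stopifnot(inherits(budget, "data_budget"))
  budget$period_s * budget$accel_rate_hz * budget$axes *
    budget$bytes_per_sample + budget$temp_per_period * budget$temp_bytes
}

#' On-device compression ratio
#'
#' The preprocessing chain acts as lossy compression: an hour of raw
#' sensing collapses into one 51-byte packet. The ratio is
#' `r_c = d_o / d_i`.
#'
#' @param budget A [data_budget()].
#' @return Compression ratio (dimensionless).
#' @examples
#' compression_ratio(data_budget()) # ~1.9e-4
#' @export
compression_ratio <- function(budget = data_budget()) {
  d_i <- input_bytes(budget)
  if (d_i == 0) stop("zero input bytes", call. = FALSE)
  budget$d_o / d_i
}
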