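#' Telemetry packet bit layout
#'
#' The hourly uplink is a single 51-byte payload (the largest packet the
#' SF10-SF12 link allows). Fields are written big-endian, most significant
#' bit first, in this order:
#'
#' | field                  | width        | coding                      |
#' |------------------------|--------------|-----------------------------|
#' | packet_id              | 16 bit       | unsigned                    |
#' | body temperature       | 12 bit       | 0.05 degC steps from 30 degC|
#' | drinking counter       | 8 bit        | unsigned                    |
#' | activity class counters| 3 x 8 bit    | quantized counts            |
#' | peak activity values   | 12 x 4 bit   | one category per 5-min block|
#' | rumination counter     | 12 bit       | 16 s steps                  |
#' | heart-rate values      | 12 x 4 bit   | category 0-7, 15 = absent   |
#' | firmware version       | 8 bit        | unsigned                    |
#' | system status          | 8 bit        | bit flags                   |
#' | battery voltage        | 8 bit        | 20 mV steps                 |
#'
#' 24 bytes are used; the remaining 27 bytes are reserved and zero. All
#' fields saturate rather than overflow.
#'
#' @return A `packet_layout` list (field widths in bits and codec
#'   constants).
#' @export
packet_layout <- function() {
  structure(list(
    size_bytes = 51L,
    n_blocks = 12L,
    n_hr = 12L,
    temp_offset_c = 30, temp_step_c = 0.05,
    rum_step_s = 16, batt_step_mv = 20,
    hr_absent_code = 15L,
    version = 1L), class = "packet_layout")
}

# --- bit helpers (big-endian, MSB first) ---------------------------------

uint_to_bits <- function(v, width) {
  stopifnot(v >= 0, v < 2^width)
  as.integer(rev(as.integer(intToBits(as.integer(v)))[seq_len(width)]))
}

bits_to_uint <- function(bits) {
  sum(bits * 2^(rev(seq_along(bits)) - 1))
}

bits_to_raw <- function(bits) {
  stopifnot(length(bits) %% 8 == 0)
  m <- matrix(bits, nrow = 8)
  as.raw(colSums(m * 2^(7:0)))
}

raw_to_bits <- function(payload) {
  as.integer(rev(as.integer(rawToBits(rev(payload)))))
}

clampi <- function(v, lo, hi) as.integer(pmin(pmax(round(v), lo), hi))

#' Hourly report of detector outputs
#'
#' Collects one reporting period's worth of un-encoded detector outputs
#' and maintenance values, the direct input to [encode_packet()].
#'
#' @param packet_id Sequence number (0-65535).
#' @param temperature_c Last measured rumen temperature, degrees C.
#' @param drinking_count Drinking events this hour.
#' @param activity_class_counts Integer vector of 3 quantized class
#'   counter codes (0-255 each).
#' @param peak_categories Integer vector of 12 peak categories (0-15),
#'   one per 5-min block.
#' @param rumination_s Cumulated rumination this hour, seconds.
#' @param hr_codes Integer vector of 12 heart-rate category codes (0-7,
#'   or 15 for no estimate).
#' @param firmware_version Firmware version (0-255).
#' @param system_status Status bit flags (0-255).
#' @param battery_mv Battery voltage, millivolts.
#' @return An `hourly_report` list.
#' @export
hourly_report <- function(packet_id, temperature_c, drinking_count,
                          activity_class_counts, peak_categories,
                          rumination_s, hr_codes,
                          firmware_version = 1L, system_status = 0L,
                          battery_mv = 3600) {
  if (length(activity_class_counts) != 3L)
    stop("need 3 activity class counters", call. = FALSE)
  if (length(peak_categories) != 12L)
    stop("need 12 peak categories (one per 5-min block)", call. = FALSE)
  if (length(hr_codes) != 12L)
    stop("need 12 heart-rate codes", call. = FALSE)
  if (any(peak_categories < 0 | peak_categories > 15))
    stop("peak categories must be 4-bit values", call. = FALSE)
  structure(list(packet_id = as.integer(packet_id),
                 temperature_c = temperature_c,
                 drinking_count = as.integer(drinking_count),
                 activity_class_counts = as.integer(activity_class_counts),
                 peak_categories = as.integer(peak_categories),
                 rumination_s = rumination_s,
                 hr_codes = as.integer(hr_codes),
                 firmware_version = as.integer(firmware_version),
                 system_status = as.integer(system_status),
                 battery_mv = battery_mv),
            class = "hourly_report")
}

#' Encode an hourly report into the 51-byte payload
#'
#' Applies the documented quantizations (saturating) and packs the fields
#' big-endian per [packet_layout()].
#'
#' @param report An [hourly_report()].
#' @param layout A [packet_layout()].
#' @return A raw vector of exactly 51 bytes.
#' @export
encode_packet <- function(report, layout = packet_layout()) {
  stopifnot(inherits(report, "hourly_report"))
  bits <- c(
    uint_to_bits(clampi(report$packet_id, 0, 65535), 16),
    uint_to_bits(clampi((report$temperature_c - layout$temp_offset_c) /
                          layout$temp_step_c, 0, 4095), 12),
    uint_to_bits(clampi(report$drinking_count, 0, 255), 8),
    unlist(lapply(clampi(report$activity_class_counts, 0, 255),
                  uint_to_bits, width = 8)),
    unlist(lapply(clampi(report$peak_categories, 0, 15),
                  uint_to_bits, width = 4)),
    uint_to_bits(min(report$rumination_s %/% layout$rum_step_s, 4095), 12),
    unlist(lapply(clampi(report$hr_codes, 0, 15), uint_to_bits, width = 4)),
    uint_to_bits(clampi(report$firmware_version, 0, 255), 8),
    uint_to_bits(clampi(report$system_status, 0, 255), 8),
    uint_to_bits(clampi(report$battery_mv / layout$batt_step_mv, 0, 255), 8))
  payload <- bits_to_raw(bits)
  c(payload, as.raw(rep(0L, layout$size_bytes - length(payload))))
}

#' Decode a 51-byte payload back into the quantized report
#'
#' Inverse of [encode_packet()] on the quantized domain:
#' `decode(encode(r))` reproduces `r` up to the documented quantization
#' steps.
#'
#' @param payload Raw vector of exactly 51 bytes.
#' @param layout A [packet_layout()].
#' @return An [hourly_report()] with quantized field values.
#' @export
decode_packet <- function(payload, layout = packet_layout()) {
  if (!is.raw(payload) || length(payload) != layout$size_bytes)
    stop("payload must be exactly ", layout$size_bytes, " raw bytes",
         call. = FALSE)
  bits <- raw_to_bits(payload)
  pos <- 0L
  take <- function(width) {
    out <- bits[(pos + 1L):(pos + width)]
    pos <<- pos + width
    out
  }
  packet_id <- bits_to_uint(take(16))
  temp_code <- bits_to_uint(take(12))
  drink <- bits_to_uint(take(8))
  act <- vapply(1:3, function(i) bits_to_uint(take(8)), numeric(1))
  peak <- vapply(1:12, function(i) bits_to_uint(take(4)), numeric(1))
  rum_code <- bits_to_uint(take(12))
  hr <- vapply(1:12, function(i) bits_to_uint(take(4)), numeric(1))
  fw <- bits_to_uint(take(8))
  status <- bits_to_uint(take(8))
  batt_code <- bits_to_uint(take(8))
  hourly_report(packet_id = packet_id,
                temperature_c = layout$temp_offset_c +
                  temp_code * layout$temp_step_c,
                drinking_count = drink,
                activity_class_counts = act,
                peak_categories = peak,
                rumination_s = rum_code * layout$rum_step_s,
                hr_codes = hr,
                firmware_version = fw,
                system_status = status,
                battery_mv = batt_code * layout$batt_step_mv)
}

#' Payloads as hex strings
#' @param payload Raw vector.
#' @return Lower-case hex string (one packet).
#' @export
packet_to_hex <- function(payload) paste(format(payload), collapse = "")

#' @rdname packet_to_hex
#' @param hex Hex string of 102 characters.
#' @export
hex_to_packet <- function(hex) {
  hex <- gsub("\\s", "", hex)
  if (nchar(hex) %% 2 != 0) stop("odd-length hex string", call. = FALSE)
  as.raw(strtoi(substring(hex, seq(1, nchar(hex), 2),
                          seq(2, nchar(hex), 2)), 16L))
}

#' Aggregate one hour of detector outputs into a report
#'
#' @param drinking Output of [detect_drinking()] for the hour.
#' @param activity Output of [process_activity()] for the hour (must
#'   cover exactly 12 five-minute blocks).
#' @param rumination Output of [detect_rumination()] for the hour.
#' @param hr Output of [estimate_hr()] for the hour, or `NULL` when the
#'   heart-rate path is not running; categories are aggregated to one
#'   code per 5-min block (modal category; 15 when absent).
#' @param packet_id Sequence number.
#' @param temperature_c Last measured rumen temperature.
#' @param firmware_version,system_status,battery_mv Maintenance fields.
#' @param layout A [packet_layout()].
#' @return An [hourly_report()].
#' @export
hourly_aggregate <- function(drinking, activity, rumination, hr = NULL,
                             packet_id = 0L, temperature_c = 39,
                             firmware_version = 1L, system_status = 0L,
                             battery_mv = 3600, layout = packet_layout()) {
  peak <- as.integer(activity$peak_categories)
  if (length(peak) != layout$n_blocks)
    stop("activity must cover exactly ", layout$n_blocks,
         " five-minute blocks (one hour)", call. = FALSE)
  codes <- as.integer(activity$class_codes[1, ])
  hr_codes <- rep(layout$hr_absent_code, layout$n_hr)
  if (!is.null(hr) && nrow(hr)) {
    blk <- floor(hr$start_s %/% 300) %% layout$n_hr + 1L
    for (b in unique(blk)) {
      cats <- hr$category[blk == b]
      cats <- cats[!is.na(cats)]
      if (length(cats)) {
        tab <- table(cats)
        hr_codes[b] <- as.integer(names(tab)[which.max(tab)])
      }
    }
  }
  hourly_report(packet_id = packet_id, temperature_c = temperature_c,
                drinking_count = drinking$count,
                activity_class_counts = codes,
                peak_categories = peak,
                rumination_s = rumination$seconds,
                hr_codes = hr_codes,
                firmware_version = firmware_version,
                system_status = system_status,
                battery_mv = battery_mv)
}

#' Run the full per-hour pipeline and encode the uplink packet
#'
#' Chains all detectors over one hour of paired temperature and
#' acceleration data, aggregates their outputs and encodes the 51-byte
#' payload. Also reports the measured input/output byte counts, which tie
#' the telemetry path to the energy module's compression arithmetic
#' (2 bytes per axis sample and per temperature sample).
#'
#' @param temp An hour of [temp_series()].
#' @param accel An hour of [accel_series()].
#' @param drinking_p,activity_p,rumination_p Detector parameter objects.
#' @param hr_model Optional `ibi_classifier`; heart-rate codes are marked
#'   absent when `NULL`.
#' @param packet_id,battery_mv,firmware_version,system_status Maintenance
#'   fields.
#' @return A list with `report`, `payload` (51 raw bytes), `input_bytes`
#'   and `output_bytes`.
#' @export
run_hourly <- function(temp, accel,
                       drinking_p = drinking_params(),
                       activity_p = activity_params(),
                       rumination_p = rumination_params(),
                       hr_model = NULL,
                       packet_id = 0L, battery_mv = 3600,
                       firmware_version = 1L, system_status = 0L) {
  span_t <- diff(range(temp$time_s))
  span_a <- diff(range(accel$time_s))
  if (span_t > 3600 || span_a > 3600)
    stop("inputs must cover at most one hour", call. = FALSE)
  drink <- detect_drinking(temp, drinking_p)
  act <- process_activity(accel, activity_p)
  rum <- detect_rumination(accel, rumination_p, activity_p)
  hr <- if (!is.null(hr_model)) estimate_hr(accel, hr_model) else NULL
  report <- hourly_aggregate(drink, act, rum, hr,
                             packet_id = packet_id,
                             temperature_c = temp$temp_c[nrow(temp)],
                             firmware_version = firmware_version,
                             system_status = system_status,
                             battery_mv = battery_mv)
  payload <- encode_packet(report)
  list(report = report, payload = payload,
       input_bytes = nrow(accel) * 3L * 2L + nrow(temp) * 2L,
       output_bytes = length(payload))
}
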