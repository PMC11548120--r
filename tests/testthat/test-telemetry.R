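test_that("every encoding is exactly 51 bytes", {
  set.seed(61)
  for (k in 1:50) expect_length(encode_packet(random_report()), 51L)
})

test_that("decode is the inverse of encode on the quantized domain", {
  set.seed(62)
  for (k in 1:200) {
    r <- random_report() # fields drawn on the quantization lattice
    back <- decode_packet(encode_packet(r))
    expect_equal(back$packet_id, r$packet_id)
    expect_equal(back$temperature_c, r$temperature_c, tolerance = 1e-9)
    expect_equal(back$drinking_count, r$drinking_count)
    expect_equal(back$activity_class_counts, r$activity_class_counts)
    expect_equal(back$peak_categories, r$peak_categories)
    expect_equal(back$rumination_s, r$rumination_s, tolerance = 1e-9)
    expect_equal(back$hr_codes, r$hr_codes)
    expect_equal(back$firmware_version, r$firmware_version)
    expect_equal(back$system_status, r$system_status)
    expect_equal(back$battery_mv, r$battery_mv, tolerance = 1e-9)
  }
})

test_that("off-lattice values quantize to the documented steps", {
  r <- hourly_report(packet_id = 1, temperature_c = 38.527,
                     drinking_count = 2,
                     activity_class_counts = c(1, 2, 3),
                     peak_categories = rep(0, 12), rumination_s = 1000,
                     hr_codes = rep(15, 12), battery_mv = 3611)
  back <- decode_packet(encode_packet(r))
  expect_equal(back$temperature_c, 38.55, tolerance = 1e-9) # 0.05 steps
  expect_equal(back$rumination_s, 992) # floor(1000/16)*16
  expect_equal(back$battery_mv, 3620)  # 20 mV steps
  ## saturation, never overflow
  r2 <- hourly_report(packet_id = 70000, temperature_c = 300,
                      drinking_count = 999,
                      activity_class_counts = c(999, 0, 0),
                      peak_categories = rep(15, 12),
                      rumination_s = 1e6, hr_codes = rep(15, 12),
                      battery_mv = 99999)
  b2 <- decode_packet(encode_packet(r2))
  expect_equal(b2$packet_id, 65535L)
  expect_equal(b2$drinking_count, 255L)
  expect_equal(b2$rumination_s, 4095 * 16)
})

test_that("golden packet matches the independently written bit-level oracle", {
  r <- hourly_report(packet_id = 258, temperature_c = 36.55,
                     drinking_count = 3,
                     activity_class_counts = c(10, 20, 30),
                     peak_categories = 0:11, rumination_s = 1000,
                     hr_codes = c(0:7, 15, 15, 15, 15),
                     firmware_version = 7, system_status = 165,
                     battery_mv = 3000)
  got <- packet_to_hex(encode_packet(r))
  want <- oracle_packet_hex(packet_id = 258, temp_code = 131, drink = 3,
                            act3 = c(10, 20, 30), peak12 = 0:11,
                            rum_code = 62, hr12 = c(0:7, 15, 15, 15, 15),
                            fw = 7, status = 165, batt_code = 150)
  expect_equal(got, want)
  ## frozen value guards the layout against silent drift
  expect_equal(got, paste0("0102083030a141e0123456789ab03e",
                           "01234567ffff07a596", strrep("0", 54)))
})

test_that("wrong payload length is a format error", {
  r <- random_report()
  expect_error(decode_packet(encode_packet(r)[1:50]), "51")
  expect_error(decode_packet("not raw"), "raw")
})

test_that("hex round-trip preserves the payload", {
  set.seed(63)
  p <- encode_packet(random_report())
  expect_identical(hex_to_packet(packet_to_hex(p)), p)
})

test_that("hourly aggregation collects detector outputs into the packet fields", {
  cfg <- sim_config(3600, rng_seed = 19)
  fx <- make_fixture(cfg)
  drink <- detect_drinking(fx$temperature)
  act <- process_activity(fx$acceleration)
  rum <- detect_rumination(fx$acceleration,
                           rumination_params(th_h = 0.25, th_l = 0.1))
  rep_ <- hourly_aggregate(drink, act, rum, hr = NULL, packet_id = 5,
                           temperature_c = 38.9)
  expect_s3_class(rep_, "hourly_report")
  expect_equal(rep_$drinking_count, drink$count)
  expect_length(rep_$peak_categories, 12L)
  expect_true(all(rep_$hr_codes == 15)) # HR path not running
  ## zero-signal streams (weightless quiet case): all counters and
  ## categories at zero
  quiet <- sim_config(3600, drink_events_per_day = 0,
                      rum_bouts_per_day = 0, activity_bouts_per_day = 0,
                      heartbeat_amp = 0, motion_noise_sd = 0,
                      temp_noise_sd = 0, gravity_g = 0, rng_seed = 2)
  qf <- make_fixture(quiet)
  qa <- process_activity(qf$acceleration)
  qr <- hourly_aggregate(detect_drinking(qf$temperature), qa,
                         detect_rumination(qf$acceleration,
                                           rumination_params(th_h = 0.25,
                                                             th_l = 0.1)))
  expect_equal(qr$drinking_count, 0L)
  expect_true(all(qr$peak_categories == 0))
  expect_equal(qr$rumination_s, 0)
})

test_that("mismatched block counts are rejected", {
  act <- list(peak_categories = rep(0, 7),
              class_codes = matrix(0, 1, 3))
  expect_error(hourly_aggregate(list(count = 0), act,
                                list(seconds = 0)), "blocks")
})

test_that("the full hourly pipeline emits a decodable 51-byte packet", {
  cfg <- sim_config(3600, rng_seed = 29)
  fx <- make_fixture(cfg)
  temp_hour <- fx$temperature[fx$temperature$time_s < 3600, ]
  out <- run_hourly(temp_hour, fx$acceleration,
                    rumination_p = rumination_params(th_h = 0.25,
                                                     th_l = 0.1),
                    packet_id = 9)
  expect_length(out$payload, 51L)
  back <- decode_packet(out$payload)
  expect_equal(back$packet_id, 9L)
  expect_equal(back$drinking_count, out$report$drinking_count)
  expect_equal(out$output_bytes, 51L)
  expect_equal(out$input_bytes, nrow(fx$acceleration) * 6 +
                 nrow(temp_hour) * 2)
})
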