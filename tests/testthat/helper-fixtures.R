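# Shared fixtures built in code. The trained heart-rate classifier is
# cached so the training cost is paid once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_hr_model <- function() {
  if (is.null(.fixture_cache$hr_model)) {
    td <- hr_training_data(n_per_class = 60, seed = 5)
    .fixture_cache$hr_model <-
      train_hr_classifier(td[, 1:4], td$bpm, seed = 5)
  }
  .fixture_cache$hr_model
}

# One 3-s heartbeat-only window at the given rate and seed.
hb_window <- function(bpm, seed, noise_sd = 0.004, rate = 25) {
  cfg <- sim_config(3, accel_rate = rate, motion_noise_sd = noise_sd,
                    rng_seed = seed)
  acc <- simulate_acceleration(
    cfg, event_log(hr_profile = data.frame(time_s = 0, bpm = bpm)))
  hr_window(acc$ax, acc$ay, acc$az, rate)
}

# Square-wave envelope: `n_onsets` active phases of `active` samples at
# `high`, separated by passive gaps so the full period is `period`.
square_envelope <- function(n_onsets, active, period, high = 7000,
                            low = 0) {
  rep(c(rep(high, active), rep(low, period - active)), n_onsets)
}

random_report <- function() {
  hourly_report(
    packet_id = sample(0:65535, 1),
    temperature_c = 30 + 0.05 * sample(0:4095, 1),
    drinking_count = sample(0:255, 1),
    activity_class_counts = sample(0:255, 3, replace = TRUE),
    peak_categories = sample(0:15, 12, replace = TRUE),
    rumination_s = 16 * sample(0:225, 1),
    hr_codes = sample(c(0:7, 15), 12, replace = TRUE),
    firmware_version = sample(0:255, 1),
    system_status = sample(0:255, 1),
    battery_mv = 20 * sample(0:255, 1))
}
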