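test_that("envelope has instant attack and smoothed decay", {
  expect_equal(envelope_step(envelope_state(100), 500)$ie, 500)
  expect_equal(envelope_step(envelope_state(500, beta = 0.05), 100)$ie,
               0.05 * 100 + 0.95 * 500, tolerance = 1e-12)
  ## constant input converges to the input
  st <- envelope_state(0, beta = 0.2)
  for (k in 1:200) st <- envelope_step(st, 3)
  expect_equal(st$ie, 3, tolerance = 1e-10)
})

test_that("envelope dominates the plain smoothed intensity", {
  set.seed(12)
  i <- abs(rnorm(500, 0, 2))
  beta <- 0.05
  env <- envelope_state(0, beta = beta)
  sm <- intensity_state(0, beta = beta)
  for (k in seq_along(i)) {
    env <- envelope_step(env, i[k])
    sm <- smooth_intensity(sm, i[k])
    expect_gte(env$ie, sm$ihat - 1e-12)
  }
})

test_that("square-wave pattern is confirmed at the k+1-th onset with the buffered credit", {
  p <- rumination_params()
  ## active 100 samples, full period 750 (within [625, 1250]), 8 onsets
  env <- square_envelope(n_onsets = 8, active = 100, period = 750)
  st <- rumination_state()
  conf_at <- NA
  for (n in seq_along(env)) {
    st <- rumination_step(st, n, env[n], p)
    if (is.na(conf_at) && st$o == 1L) conf_at <- n
  }
  ## onset j starts at (j-1)*750 + 1; confirmation on the 6th onset
  expect_equal(conf_at, 5 * 750 + 1)
  expect_equal(st$c, 5250) # 5*750 on confirmation + 750 + 750
  ## and the same value from the independent segment-based trace
  expect_equal(st$c, rumination_trace(env, p))
})

test_that("intermediate credit equals the buffered sum at confirmation", {
  p <- rumination_params()
  env6 <- square_envelope(n_onsets = 6, active = 100, period = 750)
  st <- rumination_state()
  for (n in seq_along(env6)) st <- rumination_step(st, n, env6[n], p)
  expect_equal(st$c, 5 * 750)
  expect_equal(st$o, 1L)
})

test_that("an out-of-range full period clears the buffer and confirmation", {
  p <- rumination_params()
  ## alternating 700 / 1400: the 1400-sample period is beyond t_int_max
  env <- unlist(rep(list(c(rep(7000, 100), rep(0, 600)),
                         c(rep(7000, 100), rep(0, 1300))), 6))
  st <- rumination_state()
  for (n in seq_along(env)) st <- rumination_step(st, n, env[n], p)
  expect_equal(st$c, 0)
  expect_equal(st$o, 0L)
  ## the buffer can never grow to k: every other period clears it
  expect_lt(length(st$L), p$k)
  expect_equal(rumination_trace(env, p), 0)
})

test_that("dissimilar in-range periods are never confirmed", {
  p <- rumination_params() # delta 0.2: need min/max > 0.8
  ## periods alternate 650 and 1200: ratio 0.54, both in range
  env <- unlist(rep(list(c(rep(7000, 100), rep(0, 550)),
                         c(rep(7000, 100), rep(0, 1100))), 8))
  st <- rumination_state()
  for (n in seq_along(env)) st <- rumination_step(st, n, env[n], p)
  expect_equal(st$c, 0)
  expect_equal(st$c, rumination_trace(env, p))
})

test_that("an out-of-range active part interrupts the pattern", {
  p <- rumination_params() # t_act range 25..375
  ## proper periods but active part of 500 samples (too long)
  env <- square_envelope(n_onsets = 8, active = 500, period = 750)
  st <- rumination_state()
  for (n in seq_along(env)) st <- rumination_step(st, n, env[n], p)
  expect_equal(st$c, 0)
  expect_length(st$L, 0) # cleared at the falling edge
  expect_equal(rumination_trace(env, p), 0)
})

test_that("credit is non-decreasing, bounded by elapsed time, and matches the trace on random envelopes", {
  set.seed(31)
  for (case in 1:8) {
    p <- rumination_params(th_h = 6000, th_l = 3500,
                           t_int_min = 50, t_int_max = 200,
                           t_act_min = 5, t_act_max = 60, k = 3)
    ## random telegraph-like envelope
    n_seg <- 40
    lens <- sample(10:150, n_seg, replace = TRUE)
    lvls <- sample(c(0, 7000), n_seg, replace = TRUE)
    env <- rep(lvls, lens)
    st <- rumination_state()
    prev_c <- 0
    for (n in seq_along(env)) {
      st <- rumination_step(st, n, env[n], p)
      expect_gte(st$c, prev_c)
      prev_c <- st$c
    }
    expect_lte(st$c, length(env))
    expect_equal(st$c, rumination_trace(env, p))
  }
})

test_that("flat envelope below both thresholds accumulates nothing", {
  st <- rumination_state()
  for (n in 1:2000) st <- rumination_step(st, n, 100, rumination_params())
  expect_equal(st$c, 0)
})

test_that("a simulated 16-min rumination bout is recovered within 15%", {
  cfg <- sim_config(1800, rng_seed = 3, motion_noise_sd = 0.005,
                    heartbeat_amp = 0)
  log <- event_log(rumination_intervals = data.frame(start = 300,
                                                     end = 300 + 960))
  acc <- simulate_acceleration(cfg, log)
  ## thresholds on the same scale as the simulated intensity (G);
  ## period bounds carry a small margin for envelope crossing-time
  ## jitter, since the bout's base period can sit at the 100 s edge
  r <- detect_rumination(acc, rumination_params(th_h = 0.25, th_l = 0.1,
                                                t_int_min = 600,
                                                t_int_max = 1300))
  expect_lt(abs(r$seconds - 960) / 960, 0.15)
  expect_equal(nrow(r$intervals), 1L)
  expect_lt(abs(r$intervals$start_s - 300), 60)
})

test_that("two separated bouts yield two confirmed intervals", {
  cfg <- sim_config(4200, rng_seed = 17, motion_noise_sd = 0.005,
                    heartbeat_amp = 0)
  log <- event_log(rumination_intervals =
                     data.frame(start = c(200, 2600),
                                end = c(200 + 960, 2600 + 960)))
  acc <- simulate_acceleration(cfg, log)
  r <- detect_rumination(acc, rumination_params(th_h = 0.25, th_l = 0.1,
                                                t_int_min = 600,
                                                t_int_max = 1300))
  expect_equal(nrow(r$intervals), 2L)
})

test_that("a quiet stream yields zero rumination", {
  cfg <- sim_config(600, motion_noise_sd = 0, heartbeat_amp = 0)
  acc <- simulate_acceleration(cfg)
  r <- detect_rumination(acc, rumination_params(th_h = 0.25, th_l = 0.1))
  expect_equal(r$seconds, 0)
})

test_that("parameter validation enforces hysteresis and bounds", {
  expect_error(rumination_params(th_h = 3500, th_l = 6000), "hysteresis")
  expect_silent(rumination_params(th_h = 3500, th_l = 6000,
                                  enforce_hysteresis = FALSE))
  expect_error(rumination_params(k = 1), "k")
  expect_error(rumination_params(delta_t_im = 1.5), "delta_t_im")
  expect_error(rumination_params(t_int_min = 0), "t_int")
})
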