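test_that("axis selection ranks by variability with a deterministic tie-break", {
  n <- 75
  t <- (0:(n - 1)) / 25
  sig <- sin(2 * pi * 1.3 * t)
  w <- hr_window(sig, rep(0.5, n), 0.4 * sig, 25)
  expect_setequal(select_axes(w), c(1L, 3L)) # flat y never wins
  ## equal variance on all axes: tie-break picks x then y
  w2 <- hr_window(sig, sig, sig, 25)
  expect_equal(select_axes(w2), c(1L, 2L))
  ## gravity-loaded but quiet z loses to a pulsed y after mean removal
  w3 <- hr_window(rep(0, n), 0.05 * sin(2 * pi * 1.5 * t), rep(1, n), 25)
  expect_true(2L %in% select_axes(w3))
})

test_that("conditioning removes baseline and attenuates high frequencies", {
  n <- 75
  expect_equal(condition_signal(rep(3.7, n)), rep(0, n), tolerance = 1e-9)
  ## DC + slow ramp leaves almost nothing
  v <- 5 + 0.01 * (0:(n - 1))
  out <- condition_signal(v)
  expect_lt(sqrt(sum(out^2)) / sqrt(sum(v^2)), 0.05)
  ## 11 Hz is attenuated at least 10x more than 1.33 Hz
  t <- (0:(n - 1)) / 25
  f_lo <- 4 * 25 / 75   # exact DFT bins of the 75-sample window
  f_hi <- 33 * 25 / 75
  v2 <- sin(2 * pi * f_lo * t) + sin(2 * pi * f_hi * t)
  out2 <- condition_signal(v2)
  amp <- function(x, f) Mod(sum(x * exp(-2i * pi * f * t)))
  gain_lo <- amp(out2, f_lo) / amp(v2, f_lo)
  gain_hi <- amp(out2, f_hi) / amp(v2, f_hi)
  expect_gt(gain_lo / gain_hi, 10)
  ## output has exactly zero mean
  expect_equal(mean(out2), 0, tolerance = 1e-12)
})

test_that("extrema detection respects periodicity, refractory and monotone inputs", {
  expect_length(detect_extrema(1:50)$maxima, 0)
  expect_length(detect_extrema(1:50)$minima, 0)
  ## sinusoid of period 20 over 75 samples: maxima spaced 20 apart
  v <- sin(2 * pi * (0:74) / 20)
  ext <- detect_extrema(v)
  expect_true(length(ext$maxima) %in% 3:4)
  expect_true(all(diff(ext$maxima) == 20))
  expect_true(all(diff(ext$minima) == 20))
  ## two close maxima: only the larger survives the refractory distance
  v2 <- rep(0, 30)
  v2[10] <- 1
  v2[13] <- 2
  ext2 <- detect_extrema(v2, refractory = 8, min_height_frac = 0)
  expect_equal(ext2$maxima, 13L)
})

test_that("pure sinusoid features equal the period on all four streams", {
  v <- sin(2 * pi * (0:74) / 20)
  w <- hr_window(v, 0.5 * v, rep(0, 75), 25)
  f <- hr_features(w)
  expect_equal(unname(as.numeric(f)), rep(20, 4), tolerance = 1e-3)
})

test_that("an 80-bpm pulse train yields median periods near 18.75 samples", {
  ## individual features can fall on a harmonic confusion; over a batch
  ## of windows the large majority must sit on the true period, and every
  ## window must carry at least two concordant features for the
  ## server-side classifier to out-vote the rest
  ok <- 0
  total <- 0
  for (seed in 1:10) {
    f <- hr_features(hb_window(80, seed = 100 + seed))
    hits <- sum(abs(f - 18.75) <= 1, na.rm = TRUE)
    expect_gte(hits, 2)
    ok <- ok + hits
    total <- total + sum(!is.na(f))
  }
  expect_gte(ok / total, 0.8)
})

test_that("a flat window yields all-absent features and no estimate", {
  w <- hr_window(rep(0, 75), rep(0, 75), rep(1, 75), 25)
  f <- hr_features(w)
  expect_true(all(is.na(f)))
  cls <- classify_ibi(f, cached_hr_model())
  expect_true(is.na(cls$category))
})

test_that("heart-rate bins tile 50-130 bpm in eight 10-bpm steps", {
  expect_equal(hr_bin(c(50, 59.9, 60, 125, 129.9)), c(0, 0, 1, 7, 7))
  expect_equal(hr_bin_center(0:7), seq(55, 125, by = 10))
  expect_equal(length(unique(hr_bin(seq(50, 129, by = 0.5)))), 8L)
})

test_that("training is deterministic and separable features reach full accuracy", {
  ## noiseless features: exact period for a dense bpm grid
  bpm <- rep(seq(51, 129, by = 1), each = 3)
  per <- 25 * 60 / bpm
  feats <- data.frame(IA_max = per, IA_min = per, IB_max = per,
                      IB_min = per)
  m1 <- train_hr_classifier(feats, bpm, seed = 2, hidden = 12,
                            maxit = 400)
  expect_equal(m1$accuracy, 1.0)
  m2 <- train_hr_classifier(feats, bpm, seed = 2, hidden = 12,
                            maxit = 400)
  expect_identical(m1$net$wts, m2$net$wts)
  ## probabilities normalise for arbitrary inputs
  p <- classify_ibi(c(IA_max = 20, IA_min = 21, IB_max = 19.5,
                      IB_min = 40), m1)$probs
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_length(p, 8L)
})

test_that("missing categories in the training labels are rejected", {
  per <- 25 * 60 / rep(c(55, 65), each = 10)
  feats <- data.frame(IA_max = per, IA_min = per, IB_max = per,
                      IB_min = per)
  expect_error(train_hr_classifier(feats, rep(c(55, 65), each = 10)),
               "category")
})

test_that("one discordant half-period feature is out-voted", {
  m <- cached_hr_model()
  per <- 25 * 60 / 75 # 75 bpm -> 20 samples
  f <- c(IA_max = per, IA_min = per, IB_max = per, IB_min = per / 2)
  expect_equal(classify_ibi(f, m)$category, hr_bin(75))
})

test_that("median robustness: a minority of corrupted intervals cannot move the median outside the clean range", {
  clean <- c(20, 20, 21, 20, 19)
  corrupted <- c(clean[1:3], 10, 40) # 2 of 5 corrupted
  expect_true(stats::median(corrupted) >= min(clean) &&
                stats::median(corrupted) <= max(clean))
})

test_that("models survive a JSON round-trip with identical predictions", {
  m <- cached_hr_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_hr_model(m, path)
  m2 <- read_hr_model(path)
  for (per in c(12, 15, 20, 26)) {
    f <- c(IA_max = per, IA_min = per, IB_max = per, IB_min = per)
    expect_equal(classify_ibi(f, m2)$probs, classify_ibi(f, m)$probs,
                 tolerance = 1e-9)
  }
})

test_that("windowed estimation over a long stream recovers a constant rate", {
  cfg <- sim_config(30, accel_rate = 25, motion_noise_sd = 0.004,
                    rng_seed = 55)
  ## 95 bpm sits mid-bin; windows at a bin edge legitimately flip
  ## between the two adjacent categories
  acc <- simulate_acceleration(
    cfg, event_log(hr_profile = data.frame(time_s = 0, bpm = 95)))
  est <- estimate_hr(acc, cached_hr_model())
  expect_equal(nrow(est), 10L) # 30 s -> ten 3-s windows
  expect_gte(mean(est$category == hr_bin(95), na.rm = TRUE), 0.8)
})
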