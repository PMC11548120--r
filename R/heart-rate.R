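#' A 3-second heart-rate analysis window
#'
#' The heartbeat is visible in the acceleration signal as a small periodic
#' pulse superimposed on locomotor noise. The on-device front-end works on
#' windows of 75 samples per axis (3 s at 25 Hz).
#'
#' @param x,y,z Per-axis buffers, each of length `rate * 3`.
#' @param rate_hz Sampling rate in Hz (default 25).
#' @return An `hr_window` list.
#' @export
hr_window <- function(x, y, z, rate_hz = 25) {
  len <- as.integer(round(rate_hz * 3))
  if (length(x) != len || length(y) != len || length(z) != len)
    stop("each buffer must hold exactly 3 s of samples (", len, ")",
         call. = FALSE)
  structure(list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                 rate_hz = rate_hz),
            class = "hr_window")
}

#' Select the two axes carrying the most signal
#'
#' The heart sits close to one sensor axis, so the two axes with the
#' greatest acceleration variability are analysed. The selection statistic
#' is computed after mean removal (so a gravity-loaded but quiet axis does
#' not win); ties break deterministically in axis order x < y < z.
#'
#' @param window An [hr_window()].
#' @param stat Selection statistic: `"variance"` (default),
#'   `"p2p"` (peak-to-peak) or `"energy"` (mean square after mean removal).
#' @return Integer vector of length 2: the selected axis indices
#'   (1 = x, 2 = y, 3 = z), highest-ranked first.
#' @export
select_axes <- function(window, stat = c("variance", "p2p", "energy")) {
  stopifnot(inherits(window, "hr_window"))
  stat <- match.arg(stat)
  score <- vapply(list(window$x, window$y, window$z), function(v) {
    v <- v - mean(v)
    switch(stat,
           variance = stats::var(v),
           p2p = diff(range(v)),
           energy = mean(v^2))
  }, numeric(1))
  order(-score, seq_along(score))[1:2]
}

#' Condition one axis buffer
#'
#' Baseline removal (moving-mean subtraction over `baseline_win` samples,
#' edges padded by replication) followed by zero-phase Butterworth
#' low-pass filtering at `cutoff` Hz, then exact mean removal. Linear and
#' deterministic.
#'
#' @param v Numeric buffer.
#' @param rate_hz Sampling rate in Hz.
#' @param cutoff Low-pass cutoff in Hz (default 5).
#' @param baseline_win Moving-mean window in samples (default 25, i.e. 1 s
#'   at 25 Hz).
#' @return Conditioned buffer with zero mean.
#' @export
condition_signal <- function(v, rate_hz = 25, cutoff = 5,
                             baseline_win = 25L) {
  n <- length(v)
  if (n < 3L) stop("buffer too short", call. = FALSE)
  half <- baseline_win %/% 2L
  padded <- c(rep(v[1], half), v, rep(v[n], half))
  kernel <- rep(1 / baseline_win, baseline_win)
  base <- stats::filter(padded, kernel, sides = 2)
  base <- as.numeric(base)[half + seq_len(n)]
  base[is.na(base)] <- mean(v) # degenerate very-short windows
  detrended <- v - base
  bf <- signal::butter(2, cutoff / (rate_hz / 2), type = "low")
  out <- signal::filtfilt(bf, detrended)
  out - mean(out)
}

#' Locate strict local extrema with refractory distance and height gate
#'
#' Interior samples strictly greater (maxima) or smaller (minima) than
#' both neighbours are candidates. Candidates whose amplitude is below
#' `min_height_frac` of the strongest candidate of the same polarity are
#' discarded - low-level noise wiggles in the quiet gap between beats must
#' not split the inter-beat interval. Remaining candidates closer than
#' `refractory` samples to a stronger accepted candidate are discarded
#' (greedy by amplitude). The default distance of 8 samples (0.32 s at
#' 25 Hz) sits safely below the 130-bpm beat spacing of ~11.5 samples.
#'
#' @param v Conditioned buffer.
#' @param refractory Minimum distance between retained extrema, samples.
#' @param min_height_frac Relative amplitude gate in `[0, 1)`
#'   (default 0.4).
#' @return A list with ascending index vectors `maxima` and `minima`.
#' @export
detect_extrema <- function(v, refractory = 8L, min_height_frac = 0.4) {
  pick <- function(sig) {
    n <- length(sig)
    if (n < 3L) return(integer())
    idx <- which(sig[2:(n - 1)] > sig[1:(n - 2)] &
                   sig[2:(n - 1)] > sig[3:n]) + 1L
    if (!length(idx)) return(integer())
    idx <- idx[sig[idx] >= min_height_frac * max(sig[idx])]
    keep <- integer()
    for (i in idx[order(-sig[idx], idx)]) {
      if (!length(keep) || all(abs(keep - i) >= refractory))
        keep <- c(keep, i)
    }
    sort(keep)
  }
  list(maxima = pick(v), minima = pick(-v))
}

#' Extract the four median inter-beat period features from a window
#'
#' Bolus-side pipeline: select the two most active axes, condition each,
#' detect local maxima and minima, take successive differences of the
#' extremum positions as candidate inter-beat intervals, and report the
#' median interval per stream. The median suppresses spurious
#' periodicities injected by motion artifacts. Ideally all four features
#' equal the true inter-beat interval.
#'
#' @param window An [hr_window()].
#' @param cutoff,baseline_win,refractory,min_height_frac Conditioning and
#'   peak-detection parameters, see [condition_signal()] and
#'   [detect_extrema()].
#' @param stat Axis-selection statistic, see [select_axes()].
#' @param interp Refine extremum positions to sub-sample resolution by
#'   parabolic vertex interpolation (default `TRUE`); integer sample
#'   positions quantize the interval estimate by up to half a sample,
#'   which matters near category boundaries.
#' @return Named numeric vector
#'   `c(IA_max, IA_min, IB_max, IB_min)` of median period lengths in
#'   samples; a stream with fewer than two extrema yields `NA` (feature
#'   absent). The selected axis indices are attached as attribute `axes`.
#' @export
hr_features <- function(window, cutoff = 5, baseline_win = 25L,
                        refractory = 8L, min_height_frac = 0.4,
                        stat = "variance", interp = TRUE) {
  stopifnot(inherits(window, "hr_window"))
  axes <- select_axes(window, stat)
  bufs <- list(window$x, window$y, window$z)
  refine <- function(ix, v) {
    if (!interp) return(as.numeric(ix))
    vapply(ix, function(i) {
      if (i <= 1L || i >= length(v)) return(as.numeric(i))
      denom <- v[i - 1] - 2 * v[i] + v[i + 1]
      if (denom == 0) return(as.numeric(i))
      d <- 0.5 * (v[i - 1] - v[i + 1]) / denom
      i + max(min(d, 0.5), -0.5)
    }, numeric(1))
  }
  feats <- unlist(lapply(axes, function(a) {
    cond <- condition_signal(bufs[[a]], window$rate_hz, cutoff, baseline_win)
    ext <- detect_extrema(cond, refractory, min_height_frac)
    med <- function(ix, sig) if (length(ix) >= 2L)
      stats::median(diff(refine(ix, sig))) else NA_real_
    c(med(ext$maxima, cond), med(ext$minima, -cond))
  }))
  names(feats) <- c("IA_max", "IA_min", "IB_max", "IB_min")
  attr(feats, "axes") <- axes
  feats
}

#' Heart-rate category bins
#'
#' Eight equal 10-bpm bins spanning 50-130 bpm. Rates below 50 map to bin
#' 0 and rates at or above 130 to bin 7.
#'
#' @param bpm Heart rate in beats per minute.
#' @return Integer bin index in 0..7.
#' @examples
#' hr_bin(c(55, 87, 125)) # 0 3 7
#' @export
hr_bin <- function(bpm) {
  pmin(pmax(floor((bpm - 50) / 10), 0), 7)
}

#' @rdname hr_bin
#' @param bin Bin index in 0..7.
#' @return Centre of the bin in bpm.
#' @export
hr_bin_center <- function(bin) 55 + 10 * bin

# Features (samples) -> classifier inputs (seconds), imputing absent
# features with the mean of the present ones.
hr_impute <- function(features, rate_hz) {
  x <- as.numeric(features) / rate_hz
  if (all(is.na(x))) return(NULL)
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  x
}

#' Simulate a labelled training set for the IBI classifier
#'
#' For each of the eight heart-rate categories, draws rates uniformly
#' within the bin, simulates a 3-s acceleration window containing only the
#' heartbeat pulse train plus sensor noise, and runs the bolus-side
#' feature extraction. A fraction of the feature vectors is corrupted by
#' halving or doubling one feature, emulating the harmonic and
#' sub-harmonic confusions peak detection produces on real signals, so the
#' classifier learns to out-vote a single discordant feature.
#'
#' @param n_per_class Windows per category (default 40).
#' @param rate_hz Sampling rate (default 25).
#' @param noise_sd Acceleration noise sd in G.
#' @param heartbeat_amp Pulse amplitude in G.
#' @param corrupt_frac Fraction of windows with one corrupted feature.
#' @param seed Integer seed (deterministic output).
#' @param ... Front-end settings passed on to [hr_features()].
#' @return A data frame with columns `IA_max`, `IA_min`, `IB_max`,
#'   `IB_min` (samples), `bpm` and `bin`.
#' @export
hr_training_data <- function(n_per_class = 40L, rate_hz = 25,
                             noise_sd = 0.004, heartbeat_amp = 0.02,
                             corrupt_frac = 0.1, seed = 1L, ...) {
  rows <- vector("list", 8L * n_per_class)
  k <- 0L
  for (bin in 0:7) {
    for (j in seq_len(n_per_class)) {
      k <- k + 1L
      sub_seed <- (seed * 1000L + k) %% .Machine$integer.max
      cfg <- sim_config(duration = 3, accel_rate = rate_hz,
                        motion_noise_sd = noise_sd,
                        heartbeat_amp = heartbeat_amp,
                        heartbeat_bpm = 60, # overridden by profile
                        drink_events_per_day = 0, rum_bouts_per_day = 0,
                        activity_bouts_per_day = 0,
                        rng_seed = sub_seed)
      bpm <- with_sim_seed(cfg, 10L, function()
        stats::runif(1, 50 + 10 * bin, 50 + 10 * (bin + 1)))
      log <- event_log(hr_profile = data.frame(time_s = 0, bpm = bpm))
      acc <- simulate_acceleration(cfg, log)
      w <- hr_window(acc$ax, acc$ay, acc$az, rate_hz)
      f <- hr_features(w, ...)
      corrupt <- with_sim_seed(cfg, 11L, function()
        stats::runif(1) < corrupt_frac)
      if (corrupt) {
        pick <- with_sim_seed(cfg, 12L, function()
          c(sample(4L, 1L), sample(c(0.5, 2), 1L)))
        f[pick[1]] <- f[pick[1]] * pick[2]
      }
      rows[[k]] <- c(f, bpm = bpm, bin = bin)
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("IA_max", "IA_min", "IB_max", "IB_min", "bpm", "bin")
  out
}

#' Train the server-side IBI classifier
#'
#' A single-hidden-layer perceptron with four inputs (the median period
#' features, converted to seconds) and eight softmax outputs (the
#' heart-rate categories). Training is deterministic given the seed. A
#' stratified 80/20 split provides a held-out categorical accuracy
#' estimate; the returned model is then refitted on the full data set
#' with the same initialisation.
#'
#' @param features Data frame or matrix with columns `IA_max`, `IA_min`,
#'   `IB_max`, `IB_min` in samples.
#' @param bpm True heart rates (bpm) used as labels via [hr_bin()].
#' @param rate_hz Sampling rate the features were measured at.
#' @param hidden Hidden-layer width (default 16).
#' @param maxit Optimiser iterations (default 500).
#' @param decay Weight-decay regularisation (default 1e-4); a little
#'   shrinkage stabilises the decision boundaries near bin edges.
#' @param seed Integer seed for weight initialisation and the split.
#' @return An `ibi_classifier` with elements `net` (the fitted
#'   [nnet::nnet()]), `rate_hz`, `hidden`, `accuracy` (held-out) and
#'   `seed`.
#' @export
train_hr_classifier <- function(features, bpm, rate_hz = 25, hidden = 16L,
                                maxit = 500L, decay = 1e-4, seed = 1L) {
  X <- as.matrix(features[, c("IA_max", "IA_min", "IB_max", "IB_min")])
  bins <- hr_bin(bpm)
  if (length(unique(bins)) < 8L)
    stop("training data must contain at least one example per category",
         call. = FALSE)
  ## samples -> seconds, impute row-wise
  Xs <- t(apply(X, 1, function(r) {
    r <- r / rate_hz
    if (all(is.na(r))) r[] <- 0 else r[is.na(r)] <- mean(r, na.rm = TRUE)
    r
  }))
  set.seed(seed)
  idx_test <- unlist(lapply(split(seq_along(bins), bins), function(ix)
    sample(ix, max(1L, round(0.2 * length(ix))))))
  idx_train <- setdiff(seq_along(bins), idx_test)
  Y <- nnet::class.ind(factor(bins, levels = 0:7))
  set.seed(seed)
  net <- nnet::nnet(Xs[idx_train, , drop = FALSE],
                    Y[idx_train, , drop = FALSE],
                    size = hidden, softmax = TRUE, maxit = maxit,
                    decay = decay, trace = FALSE, MaxNWts = 5000)
  pred <- max.col(stats::predict(net, Xs[idx_test, , drop = FALSE])) - 1L
  acc <- mean(pred == bins[idx_test])
  set.seed(seed)
  net <- nnet::nnet(Xs, Y, size = hidden, softmax = TRUE, maxit = maxit,
                    decay = decay, trace = FALSE, MaxNWts = 5000)
  structure(list(net = net, rate_hz = rate_hz, hidden = hidden,
                 accuracy = acc, seed = seed),
            class = "ibi_classifier")
}

#' Classify a window's features into a heart-rate category
#'
#' Converts the four median period features to seconds, imputes absent
#' features with the mean of the present ones, and takes the argmax of the
#' perceptron's eight softmax outputs. A window with all four features
#' absent yields no estimate (`NA`).
#'
#' @param features Output of [hr_features()] (samples).
#' @param model An [train_hr_classifier()] model.
#' @return A list with `category` (0..7 or `NA`), `bpm_center` and
#'   `probs` (length-8 probability vector summing to 1, or `NULL`).
#' @export
classify_ibi <- function(features, model) {
  if (!inherits(model, "ibi_classifier"))
    stop("`model` must be a trained ibi_classifier", call. = FALSE)
  x <- hr_impute(features, model$rate_hz)
  if (is.null(x))
    return(list(category = NA_integer_, bpm_center = NA_real_, probs = NULL))
  p <- as.numeric(stats::predict(model$net, matrix(x, nrow = 1)))
  p <- p / sum(p)
  cat <- which.max(p) - 1L
  list(category = cat, bpm_center = hr_bin_center(cat), probs = p)
}

#' Estimate heart-rate categories over a long stream
#'
#' Splits the stream into non-overlapping 3-s windows, runs the bolus-side
#' feature extraction and the server-side classifier on each.
#'
#' @param series An [accel_series()] sampled at the heart-rate path rate.
#' @param model An `ibi_classifier`.
#' @return Data frame with `start_s`, `category`, `bpm_center` per window.
#' @export
estimate_hr <- function(series, model) {
  stopifnot(inherits(series, "accel_series"))
  rate <- accel_rate(series)
  len <- as.integer(round(rate * 3))
  n_win <- nrow(series) %/% len
  if (n_win < 1L) stop("series shorter than one 3-s window", call. = FALSE)
  out <- lapply(seq_len(n_win), function(wi) {
    ix <- ((wi - 1L) * len + 1L):(wi * len)
    w <- hr_window(series$ax[ix], series$ay[ix], series$az[ix], rate)
    cls <- classify_ibi(hr_features(w), model)
    data.frame(start_s = series$time_s[ix[1]],
               category = cls$category, bpm_center = cls$bpm_center)
  })
  do.call(rbind, out)
}

#' Save / load an IBI classifier as portable JSON
#'
#' Serialises the network shape and weights so a model trained once can be
#' shipped to the server side and reloaded without refitting.
#'
#' @param model An `ibi_classifier`.
#' @param path File path.
#' @export
write_hr_model <- function(model, path) {
  stopifnot(inherits(model, "ibi_classifier"))
  obj <- list(n = model$net$n, wts = model$net$wts, rate_hz = model$rate_hz,
              hidden = model$hidden, accuracy = model$accuracy,
              seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_hr_model
#' @return The reconstructed `ibi_classifier`.
#' @export
read_hr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ## rebuild a nnet skeleton with the stored weights (no optimisation)
  dummy_x <- matrix(0, nrow = 16, ncol = obj$n[1])
  dummy_y <- nnet::class.ind(factor(rep(0:7, 2), levels = 0:7))
  net <- nnet::nnet(dummy_x, dummy_y, size = obj$n[2], softmax = TRUE,
                    maxit = 0, trace = FALSE, Wts = obj$wts, MaxNWts = 5000)
  net$wts <- obj$wts
  structure(list(net = net, rate_hz = obj$rate_hz, hidden = obj$hidden,
                 accuracy = obj$accuracy, seed = obj$seed),
            class = "ibi_classifier")
}
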