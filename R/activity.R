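#' Motion-activity parameters
#'
#' Two independent activity measures run over the raw acceleration stream.
#' The first is a block peak detector: within non-overlapping blocks
#' (default 5 min) the largest absolute acceleration is found and binned
#' into one of 16 categories by 15 ascending thresholds, encoded as a
#' 4-bit value. The second removes the slowly varying gravity component
#' with a per-axis exponential averager, measures the instantaneous motion
#' intensity as the Euclidean distance between the raw and filtered
#' vectors, smooths it with a second averager, and classifies the smoothed
#' intensity into three classes by two thresholds, incrementing a
#' per-class counter.
#'
#' @param alpha Gravity-averager parameter in (0, 1]; the default 0.01
#'   gives a gravity time constant of roughly 8 s at 12.5 Hz, slow enough
#'   to pass movement transients yet able to track bolus re-orientation.
#' @param beta Intensity-smoothing averager parameter in (0, 1]
#'   (default 0.05).
#' @param block_len Peak-detector block length in seconds (default 300).
#' @param peak_thresholds 15 strictly ascending thresholds in G defining
#'   the 16 peak categories; default a linear grid 0.5-7.5 G.
#' @param class_thresholds 2 ascending thresholds on the smoothed
#'   intensity defining the 3 intensity classes.
#' @param counter_quant_bits Bit width for transmitted class counters
#'   (default 8).
#' @param counter_quant_scale Right-shift scale for counter quantization
#'   (default 16 counts per code step).
#' @param peak_mode `"per_axis"` (default) takes the peak of
#'   `max(|x|,|y|,|z|)` over the block; `"norm"` uses the vector norm
#'   instead.
#' @return An `activity_params` list.
#' @export
activity_params <- function(alpha = 0.01, beta = 0.05, block_len = 300,
                            peak_thresholds = seq(0.5, 7.5, by = 0.5),
                            class_thresholds = c(0.05, 0.5),
                            counter_quant_bits = 8L,
                            counter_quant_scale = 16L,
                            peak_mode = c("per_axis", "norm")) {
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]", call. = FALSE)
  if (beta <= 0 || beta > 1) stop("`beta` must be in (0, 1]", call. = FALSE)
  if (block_len <= 0) stop("`block_len` must be > 0", call. = FALSE)
  if (length(peak_thresholds) != 15L || any(diff(peak_thresholds) <= 0))
    stop("`peak_thresholds` must be 15 strictly ascending values",
         call. = FALSE)
  if (length(class_thresholds) != 2L || diff(class_thresholds) <= 0)
    stop("`class_thresholds` must be 2 ascending values", call. = FALSE)
  if (counter_quant_bits <= 0)
    stop("`counter_quant_bits` must be positive", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, block_len = block_len,
                 peak_thresholds = peak_thresholds,
                 class_thresholds = class_thresholds,
                 counter_quant_bits = as.integer(counter_quant_bits),
                 counter_quant_scale = as.integer(counter_quant_scale),
                 peak_mode = match.arg(peak_mode)),
            class = "activity_params")
}

#' Gravity filter state
#' @param xhat,yhat,zhat Filtered per-axis acceleration, G.
#' @param alpha Averager parameter in (0, 1].
#' @return A `gravity_state` list.
#' @export
gravity_state <- function(xhat = 0, yhat = 0, zhat = 0, alpha = 0.01) {
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]", call. = FALSE)
  structure(list(xhat = xhat, yhat = yhat, zhat = zhat, alpha = alpha),
            class = "gravity_state")
}

#' One step of the per-axis gravity exponential averager
#'
#' Each filtered axis follows `xhat' = alpha * x + (1 - alpha) * xhat`.
#'
#' @param state A [gravity_state()].
#' @param sample Length-3 numeric `(x, y, z)` in G.
#' @return Updated [gravity_state()].
#' @export
gravity_filter_step <- function(state, sample) {
  stopifnot(inherits(state, "gravity_state"), length(sample) == 3L)
  a <- state$alpha
  state$xhat <- a * sample[1] + (1 - a) * state$xhat
  state$yhat <- a * sample[2] + (1 - a) * state$yhat
  state$zhat <- a * sample[3] + (1 - a) * state$zhat
  state
}

#' Instantaneous motion intensity
#'
#' Euclidean distance between the raw sample and the gravity-filtered
#' vector: with gravity removed, what remains measures movement.
#'
#' @param sample Length-3 numeric `(x, y, z)` in G.
#' @param state A [gravity_state()].
#' @return Non-negative intensity.
#' @examples
#' st <- gravity_state(0, 0, 0)
#' intensity(c(3, 4, 0), st) # 5
#' @export
intensity <- function(sample, state) {
  stopifnot(inherits(state, "gravity_state"), length(sample) == 3L)
  sqrt((sample[1] - state$xhat)^2 + (sample[2] - state$yhat)^2 +
         (sample[3] - state$zhat)^2)
}

#' Intensity smoothing state
#' @param ihat Smoothed intensity (>= 0).
#' @param beta Averager parameter in (0, 1].
#' @return An `intensity_state` list.
#' @export
intensity_state <- function(ihat = 0, beta = 0.05) {
  if (ihat < 0) stop("`ihat` must be >= 0", call. = FALSE)
  if (beta <= 0 || beta > 1) stop("`beta` must be in (0, 1]", call. = FALSE)
  structure(list(ihat = ihat, beta = beta), class = "intensity_state")
}

#' One step of the intensity exponential averager
#'
#' `ihat' = beta * i + (1 - beta) * ihat`.
#'
#' @param state An [intensity_state()].
#' @param i New intensity value (>= 0).
#' @return Updated [intensity_state()].
#' @export
smooth_intensity <- function(state, i) {
  stopifnot(inherits(state, "intensity_state"))
  if (i < 0) stop("intensity must be >= 0", call. = FALSE)
  state$ihat <- state$beta * i + (1 - state$beta) * state$ihat
  state
}

# Vectorised first-order recursion y_n = a*x_n + (1-a)*y_{n-1}, y_0 = init.
ewma_filter <- function(x, a, init) {
  as.numeric(stats::filter(a * x, filter = 1 - a, method = "recursive",
                           init = init))
}

#' Run the gravity filter and intensity chain over a series
#'
#' Vectorised equivalent of folding [gravity_filter_step()],
#' [intensity()] and [smooth_intensity()] over the stream. The gravity
#' filter is initialised to the first sample (so a resting stream yields
#' zero intensity from the start); the intensity averager starts at 0.
#'
#' @param series An [accel_series()].
#' @param params An [activity_params()].
#' @return A list with `gravity` (n x 3 matrix of filtered axes),
#'   `intensity` (raw intensity per sample) and `smoothed` (the smoothed
#'   intensity, input to classification and to the rumination envelope).
#' @export
intensity_series <- function(series, params = activity_params()) {
  stopifnot(inherits(series, "accel_series"))
  a <- params$alpha
  xh <- ewma_filter(series$ax, a, series$ax[1])
  yh <- ewma_filter(series$ay, a, series$ay[1])
  zh <- ewma_filter(series$az, a, series$az[1])
  ## per sample: filter update first, then intensity against the updated
  ## gravity estimate
  i <- sqrt((series$ax - xh)^2 + (series$ay - yh)^2 + (series$az - zh)^2)
  list(gravity = cbind(xhat = xh, yhat = yh, zhat = zh),
       intensity = i,
       smoothed = ewma_filter(i, params$beta, 0))
}

#' Peak activity category of one block
#'
#' Finds the largest absolute acceleration in the block (per-axis maxima
#' by default, vector norm optionally) and bins it into one of 16
#' categories with the 15 configured thresholds. Category 0 lies below
#' the first threshold; values above the last saturate at category 15.
#'
#' @param block An [accel_series()] spanning at most one block.
#' @param params An [activity_params()].
#' @return Integer category in 0..15.
#' @export
peak_block_category <- function(block, params = activity_params()) {
  stopifnot(inherits(block, "accel_series"))
  if (nrow(block) == 0L) stop("empty block", call. = FALSE)
  m <- if (params$peak_mode == "per_axis") {
    max(abs(block$ax), abs(block$ay), abs(block$az))
  } else {
    max(sqrt(block$ax^2 + block$ay^2 + block$az^2))
  }
  as.integer(findInterval(m, params$peak_thresholds))
}

#' Classify a smoothed intensity value and update class counters
#'
#' Exactly one of the three counters is incremented per sample, chosen by
#' the two class thresholds.
#'
#' @param ihat Smoothed intensity (>= 0).
#' @param params An [activity_params()].
#' @param counters Integer vector of 3 non-negative class counts.
#' @return Updated counters.
#' @export
classify_intensity <- function(ihat, params = activity_params(),
                               counters = integer(3)) {
  if (ihat < 0) stop("intensity must be >= 0", call. = FALSE)
  stopifnot(length(counters) == 3L)
  cls <- findInterval(ihat, params$class_thresholds) + 1L
  counters[cls] <- counters[cls] + 1L
  counters
}

#' Quantize a counter for transmission
#'
#' Saturating right-shift: `floor(count / scale)`, capped at the largest
#' code representable in `bits` bits. Monotone non-decreasing in `count`.
#'
#' @param count Non-negative count.
#' @param bits Code width in bits (> 0).
#' @param scale Counts per code step (default 16).
#' @return Integer code in `[0, 2^bits - 1]`.
#' @examples
#' quantize_counter(100, bits = 8, scale = 16) # 6
#' @export
quantize_counter <- function(count, bits, scale = 16L) {
  if (any(count < 0)) stop("count must be >= 0", call. = FALSE)
  if (bits <= 0) stop("`bits` must be positive", call. = FALSE)
  pmin(count %/% scale, 2^bits - 1)
}

#' Run both activity measures over a stream
#'
#' Splits the stream into non-overlapping peak blocks and hourly reporting
#' periods, returning one 4-bit peak category per block and per-hour class
#' counters (raw and quantized). Class counters reset at each hourly
#' boundary, matching the hourly telemetry packet.
#'
#' @param series An [accel_series()].
#' @param params An [activity_params()].
#' @param period_s Reporting period in seconds (default 3600).
#' @return A list with `peak_categories` (integer per block, with block
#'   start times), `class_counts` (hours x 3 matrix), `class_codes`
#'   (quantized counters) and `smoothed` (the smoothed intensity series).
#' @export
process_activity <- function(series, params = activity_params(),
                             period_s = 3600) {
  stopifnot(inherits(series, "accel_series"))
  chain <- intensity_series(series, params)
  blk <- floor(series$time_s / params$block_len)
  peak <- vapply(split(seq_len(nrow(series)), blk), function(idx) {
    b <- series[idx, , drop = FALSE]
    m <- if (params$peak_mode == "per_axis") {
      max(abs(b$ax), abs(b$ay), abs(b$az))
    } else {
      max(sqrt(b$ax^2 + b$ay^2 + b$az^2))
    }
    as.integer(findInterval(m, params$peak_thresholds))
  }, integer(1))
  hour <- floor(series$time_s / period_s)
  cls <- findInterval(chain$smoothed, params$class_thresholds)
  counts <- t(vapply(split(cls, hour),
                     function(v) tabulate(v + 1L, nbins = 3L), integer(3)))
  colnames(counts) <- paste0("class", 0:2)
  list(peak_categories = peak,
       block_start_s = as.numeric(names(peak)) * params$block_len,
       class_counts = counts,
       class_codes = quantize_counter(counts, params$counter_quant_bits,
                                      params$counter_quant_scale),
       smoothed = chain$smoothed)
}
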