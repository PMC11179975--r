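#' Construct a raw movement signal
#'
#' A `raw_signal` holds one time-stamped channel as streamed from a motion
#' controller or touchscreen: rotation angle in degrees, force in grams, or
#' touch-swipe displacement. Timestamps are seconds from session start and
#' must be strictly increasing.
#'
#' @param timestamps Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param values Numeric vector of sensor readings, same length as
#'   `timestamps`.
#' @param channel_label Name of the sensor channel (e.g. `"rotation_x"`).
#' @param sampling_rate Nominal sampling rate in Hz. The rate estimated from
#'   the timestamps (median of successive differences) is compared against
#'   this; a deviation beyond 20% raises a warning, since it usually means
#'   the wrong channel or corrupted timestamps.
#' @param units Unit string for `values` (e.g. `"degrees"`, `"grams"`).
#'
#' @return An object of class `raw_signal`: a list with fields `timestamps`,
#'   `values`, `channel_label`, `sampling_rate`, `units`.
#' @export
raw_signal <- function(timestamps, values, channel_label = "signal",
                       sampling_rate = 60, units = "units") {
  if (!is.numeric(timestamps) || !is.numeric(values)) {
    stop("`timestamps` and `values` must be numeric", call. = FALSE)
  }
  if (length(timestamps) != length(values)) {
    stop("`timestamps` and `values` must have the same length", call. = FALSE)
  }
  if (length(timestamps) < 1L) {
    stop("signal must contain at least one sample", call. = FALSE)
  }
  if (anyNA(timestamps) || anyNA(values)) {
    stop("signal contains missing (NA/NaN) samples", call. = FALSE)
  }
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    stop("`timestamps` must be strictly increasing", call. = FALSE)
  }
  stop_if_not_scalar_number(sampling_rate, "sampling_rate", 0, strict = TRUE)
  est <- estimate_sampling_rate(timestamps)
  if (is.finite(est) && abs(est - sampling_rate) / sampling_rate > 0.2) {
    warning(sprintf(
      "estimated sampling rate %.2f Hz deviates >20%% from nominal %.2f Hz",
      est, sampling_rate
    ), call. = FALSE)
  }
  new_raw_signal(as.numeric(timestamps), as.numeric(values),
                 channel_label, sampling_rate, units)
}

new_raw_signal <- function(timestamps, values, channel_label,
                           sampling_rate, units) {
  structure(
    list(timestamps = timestamps, values = values,
         channel_label = channel_label, sampling_rate = sampling_rate,
         units = units),
    class = "raw_signal"
  )
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("<raw_signal> channel '%s': %d samples, %.1f s, %s\n",
              x$channel_label, length(x$values),
              diff(range(x$timestamps)), x$units))
  invisible(x)
}

# Median of successive timestamp differences; robust to dropped samples from
# a streaming tablet. Returns NA for single-sample signals.
estimate_sampling_rate <- function(timestamps) {
  if (length(timestamps) < 2L) return(NA_real_)
  1 / stats::median(diff(timestamps))
}

#' Per-exercise configuration
#'
#' Bundles the channel selection and triggering options that are fixed for
#' one exercise: which sensor dimension to analyse, the calibrated movement
#' minimum (noise floor) for that exercise, and the allowed trigger
#' direction(s).
#'
#' @param exercise_id Free-text exercise identifier.
#' @param channel_label Sensor channel the exercise is scored on.
#' @param movement_minimum Noise floor in rate-of-change units (signal units
#'   per second); activity with absolute rate of change at or below this is
#'   treated as noise. Must be >= 0.
#' @param directionality One of `"both"`, `"positive_only"`,
#'   `"negative_only"`, `"bidirectional"`. `"bidirectional"` maintains two
#'   separate movement distributions, one per direction, for patients with
#'   unbalanced deficits.
#' @param units Unit string of the raw channel.
#'
#' @return An object of class `exercise_config`.
#' @export
exercise_config <- function(exercise_id, channel_label,
                            movement_minimum = 0,
                            directionality = c("both", "positive_only",
                                               "negative_only",
                                               "bidirectional"),
                            units = "units") {
  directionality <- match.arg(directionality)
  stop_if_not_scalar_number(movement_minimum, "movement_minimum", 0)
  structure(
    list(exercise_id = as.character(exercise_id)[1],
         channel_label = as.character(channel_label)[1],
         movement_minimum = movement_minimum,
         directionality = directionality,
         units = as.character(units)[1]),
    class = "exercise_config"
  )
}

#' Construct a rate-of-change signal
#'
#' Usually produced by [rate_of_change()]; the constructor is exported so
#' that synthetic or externally computed rate-of-change streams can enter
#' the trigger algorithms directly.
#'
#' @param timestamps,values As in [raw_signal()]; `values` are signed rates
#'   of change in signal units per second.
#' @param window_ms Width of the trailing window (ms) used to produce the
#'   signal.
#' @param source_channel Label of the raw channel this was derived from.
#' @param sampling_rate Nominal sampling rate in Hz.
#'
#' @return An object of class `roc_signal`. The fields `supra_minimum`
#'   (logical per-sample flags) and `movement_minimum` are attached by
#'   [gate_noise()].
#' @export
roc_signal <- function(timestamps, values, window_ms = 300,
                       source_channel = "signal", sampling_rate = 60) {
  if (length(timestamps) != length(values)) {
    stop("`timestamps` and `values` must have the same length", call. = FALSE)
  }
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    stop("`timestamps` must be strictly increasing", call. = FALSE)
  }
  stop_if_not_scalar_number(window_ms, "window_ms", 0, strict = TRUE)
  structure(
    list(timestamps = as.numeric(timestamps), values = as.numeric(values),
         window_ms = window_ms, source_channel = source_channel,
         sampling_rate = sampling_rate,
         supra_minimum = NULL, movement_minimum = NULL),
    class = "roc_signal"
  )
}

#' @export
print.roc_signal <- function(x, ...) {
  gated <- if (is.null(x$supra_minimum)) "ungated" else
    sprintf("gated at %.4g/s (%d supra-minimum)",
            x$movement_minimum, sum(x$supra_minimum))
  cat(sprintf("<roc_signal> from '%s': %d samples, window %g ms, %s\n",
              x$source_channel, length(x$values), x$window_ms, gated))
  invisible(x)
}

#' Select the sensor channel for an exercise
#'
#' Each exercise is scored on a single sensor dimension; this isolates that
#' channel from a multi-channel recording.
#'
#' @param record Named list of [raw_signal()] objects, one per channel.
#' @param config An [exercise_config()] naming the channel to use.
#'
#' @return The named `raw_signal`, untouched.
#' @export
select_channel <- function(record, config) {
  lbl <- config$channel_label
  if (!lbl %in% names(record)) {
    stop(sprintf("channel '%s' not found; available channels: %s",
                 lbl, paste(names(record), collapse = ", ")), call. = FALSE)
  }
  record[[lbl]]
}

#' Smooth a raw signal with a causal moving average
#'
#' Applies a discrete moving-average (uniform-kernel convolution) filter.
#' The kernel covers `window_ms` of data, so its size in samples scales with
#' the sampling rate estimated from the timestamps:
#' `k = round(window_ms / 1000 * rate)`, with a minimum of 1. The filter is
#' causal (trailing window only), matching a system that streams samples in
#' real time; the first `k - 1` samples use a growing window (the average of
#' all samples seen so far) to avoid startup artifacts without peeking at
#' future data.
#'
#' @param raw A [raw_signal()].
#' @param window_ms Smoothing window in milliseconds. The 300 ms default
#'   reflects the approximate duration of a large voluntary movement.
#'
#' @return A `raw_signal` of the same length with smoothed values.
#' @export
smooth_signal <- function(raw, window_ms = 300) {
  stopifnot(inherits(raw, "raw_signal"))
  stop_if_not_scalar_number(window_ms, "window_ms", 0, strict = TRUE)
  n <- length(raw$values)
  if (n < 1L) stop("cannot smooth an empty signal", call. = FALSE)
  k <- kernel_size(raw$timestamps, window_ms, raw$sampling_rate)
  out <- causal_moving_average(raw$values, k)
  new_raw_signal(raw$timestamps, out, raw$channel_label,
                 raw$sampling_rate, raw$units)
}

kernel_size <- function(timestamps, window_ms, nominal_rate) {
  rate <- estimate_sampling_rate(timestamps)
  if (!is.finite(rate)) rate <- nominal_rate
  max(1L, as.integer(round(window_ms / 1000 * rate)))
}

# Trailing moving average with growing-window head; cumulative-sum form.
causal_moving_average <- function(v, k) {
  n <- length(v)
  cs <- cumsum(v)
  idx <- seq_len(n)
  out <- cs / idx
  if (k > 1L && n >= k) {
    i <- k:n
    out[i] <- (cs[i] - c(0, cs)[i - k + 1L]) / k
  }
  out
}

#' Compute the windowed rate-of-change signal
#'
#' For each sample, the local gradient of the smoothed signal is taken
#' (central finite differences on the timestamps where both neighbours
#' exist, one-sided at the edges) and the gradient values in the trailing
#' `window_ms` window are averaged. The result is a signed rate of change
#' in signal units per second: positive for pressing/gripping or clockwise
#' rotation, negative for releasing or counter-clockwise rotation. This is
#' the signal every trigger algorithm consumes.
#'
#' @param smoothed A smoothed [raw_signal()] (see [smooth_signal()]).
#' @param window_ms Trailing averaging window in milliseconds (default
#'   300 ms, matching the smoothing window).
#'
#' @return A [roc_signal()] of the same length.
#' @export
rate_of_change <- function(smoothed, window_ms = 300) {
  stopifnot(inherits(smoothed, "raw_signal"))
  stop_if_not_scalar_number(window_ms, "window_ms", 0, strict = TRUE)
  t <- smoothed$timestamps
  v <- smoothed$values
  n <- length(v)
  if (n < 2L) stop("rate of change needs at least 2 samples", call. = FALSE)
  grad <- numeric(n)
  if (n > 2L) {
    i <- 2:(n - 1L)
    grad[i] <- (v[i + 1L] - v[i - 1L]) / (t[i + 1L] - t[i - 1L])
  }
  grad[1L] <- (v[2L] - v[1L]) / (t[2L] - t[1L])
  grad[n] <- (v[n] - v[n - 1L]) / (t[n] - t[n - 1L])
  k <- kernel_size(t, window_ms, smoothed$sampling_rate)
  roc <- causal_moving_average(grad, k)
  out <- roc_signal(t, roc, window_ms = window_ms,
                    source_channel = smoothed$channel_label,
                    sampling_rate = smoothed$sampling_rate)
  out
}

#' Calibrate the movement minimum from at-rest recordings
#'
#' The movement minimum (per-exercise noise floor) is the mean, across
#' rest recordings, of the maximum absolute rate of change observed while a
#' control subject holds the controller with the arm at rest.
#'
#' @param rest_recordings List of [roc_signal()] objects recorded at rest.
#'
#' @return Movement minimum in rate-of-change units (>= 0).
#' @export
estimate_movement_minimum <- function(rest_recordings) {
  if (inherits(rest_recordings, "roc_signal")) {
    rest_recordings <- list(rest_recordings)
  }
  if (length(rest_recordings) < 1L) {
    stop("need at least one rest recording", call. = FALSE)
  }
  maxima <- vapply(rest_recordings, function(r) {
    stopifnot(inherits(r, "roc_signal"))
    if (length(r$values) < 1L) {
      stop("rest recording is empty", call. = FALSE)
    }
    max(abs(r$values))
  }, numeric(1))
  mean(maxima)
}

#' Flag samples above the movement minimum
#'
#' Marks each rate-of-change sample as supra-minimum when its absolute
#' value strictly exceeds the movement minimum. Values are not altered and
#' sub-minimum samples are not removed, so timestamps stay uniform for the
#' rolling buffer; downstream consumers decide how to use the flags.
#'
#' @param roc A [roc_signal()].
#' @param movement_minimum Noise floor in rate-of-change units (>= 0).
#'
#' @return The same `roc_signal` with `supra_minimum` flags and
#'   `movement_minimum` attached.
#' @export
gate_noise <- function(roc, movement_minimum) {
  stopifnot(inherits(roc, "roc_signal"))
  stop_if_not_scalar_number(movement_minimum, "movement_minimum", 0)
  roc$supra_minimum <- abs(roc$values) > movement_minimum
  roc$movement_minimum <- movement_minimum
  roc
}

#' Full preprocessing chain
#'
#' Convenience wrapper: smooth, differentiate, gate. Identical input yields
#' bit-identical output (the chain is fully deterministic).
#'
#' @param raw A [raw_signal()].
#' @param window_ms Smoothing/averaging window in milliseconds.
#' @param movement_minimum Noise floor in rate-of-change units.
#'
#' @return A gated [roc_signal()].
#' @export
preprocess_signal <- function(raw, window_ms = 300, movement_minimum = 0) {
  gate_noise(rate_of_change(smooth_signal(raw, window_ms), window_ms),
             movement_minimum)
}

#' Estimate the clock offset between two devices
#'
#' When triggers are logged on one device (e.g. a phone) and movement on
#' another (a tablet), the mean pairwise difference between matched event
#' start times gives the clock offset. Callers subtract the returned offset
#' from device-B timestamps to realign them with device A.
#'
#' @param session_start_times_device_a Numeric vector of start times
#'   (seconds) on the reference device.
#' @param event_start_times_device_b Numeric vector of the matching start
#'   times on the second device; same length.
#'
#' @return Mean offset in seconds (`b - a`).
#' @export
align_clocks <- function(session_start_times_device_a,
                         event_start_times_device_b) {
  a <- session_start_times_device_a
  b <- event_start_times_device_b
  if (length(a) < 1L || length(b) < 1L) {
    stop("both time lists must be non-empty", call. = FALSE)
  }
  if (length(a) != length(b)) {
    stop("time lists must be paired (equal length)", call. = FALSE)
  }
  mean(b - a)
}
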