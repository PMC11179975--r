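DIRECTION_MODES <- c(both = 0L, positive_only = 1L, negative_only = 2L,
                     bidirectional = 3L)

#' Linearly interpolated percentile of a buffer
#'
#' The order statistic used by the dynamic algorithm: sort the buffered
#' rate-of-change values and interpolate linearly at position
#' `(n - 1) * percentile / 100` (the same convention as
#' `quantile(..., type = 7)`).
#'
#' @param values Numeric vector, at least 2 values.
#' @param percentile Percent in (0, 100).
#'
#' @return The interpolated order statistic.
#' @export
percentile_threshold <- function(values, percentile) {
  if (length(values) < 2L) {
    stop("need at least 2 values to form a percentile threshold",
         call. = FALSE)
  }
  stop_if_not_scalar_number(percentile, "percentile")
  if (percentile <= 0 || percentile >= 100) {
    stop("`percentile` must lie strictly between 0 and 100", call. = FALSE)
  }
  s <- sort(values)
  n <- length(s)
  h <- (n - 1) * (percentile / 100)
  lo <- floor(h)
  if (lo >= n - 1) return(s[n])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

# Largest percent rank r such that the interpolated quantile of `s_sorted`
# at r does not exceed v. Mirrors the C++ implementation bit for bit.
inv_quantile_rank_r <- function(s_sorted, v) {
  n <- length(s_sorted)
  if (n == 1L) return(if (v >= s_sorted[1]) 100 else 0)
  if (v < s_sorted[1]) return(0)
  if (v >= s_sorted[n]) return(100)
  j <- sum(s_sorted <= v)
  h <- (j - 1) + (v - s_sorted[j]) / (s_sorted[j + 1] - s_sorted[j])
  100 * h / (n - 1)
}

#' Parameters of the dynamic rolling-percentile algorithm
#'
#' @param percentile Trigger percentile in (0, 100). The study values are
#'   45, 55, 65, 75, 85 and 95; 95 is the recommended operating point.
#' @param buffer_size Capacity of the rolling buffer of recent
#'   rate-of-change samples (default 3000: long enough to span a short
#'   game session at 60 Hz, short enough to track fatigue and level
#'   changes in longer ones).
#' @param min_isi Minimum inter-stimulus interval in seconds (default 5).
#' @param directionality `"both"`, `"positive_only"`, `"negative_only"`, or
#'   `"bidirectional"` (two separate distributions, one per direction).
#' @param min_fill Minimum buffer occupancy before the threshold is defined
#'   (default 30); the percentile of a near-empty buffer is meaningless, so
#'   no triggers are emitted until this many samples have been buffered.
#' @param include_subminimum Should sub-movement-minimum samples enter the
#'   buffer? Default `FALSE`: excluded activity is kept out of the movement
#'   distribution so long rests do not deflate the threshold.
#'
#' @return An object of class `dynamic_params`.
#' @export
dynamic_params <- function(percentile = 95, buffer_size = 3000, min_isi = 5,
                           directionality = c("both", "positive_only",
                                              "negative_only",
                                              "bidirectional"),
                           min_fill = 30, include_subminimum = FALSE) {
  directionality <- match.arg(directionality)
  stop_if_not_scalar_number(percentile, "percentile")
  if (percentile <= 0 || percentile >= 100) {
    stop("`percentile` must lie strictly between 0 and 100", call. = FALSE)
  }
  stop_if_not_scalar_number(buffer_size, "buffer_size", 2)
  stop_if_not_scalar_number(min_isi, "min_isi", 0)
  stop_if_not_scalar_number(min_fill, "min_fill", 2)
  if (min_fill > buffer_size) {
    stop("`min_fill` cannot exceed `buffer_size`", call. = FALSE)
  }
  structure(
    list(percentile = percentile, buffer_size = as.integer(buffer_size),
         min_isi = min_isi, directionality = directionality,
         min_fill = as.integer(min_fill),
         include_subminimum = isTRUE(include_subminimum)),
    class = "dynamic_params"
  )
}

#' Parameters of the static threshold algorithm
#'
#' @param multiplier Dimensionless multiple of the movement minimum; the
#'   study values are 1, 2, 4, 8, 16 and 32.
#' @param movement_minimum Calibrated noise floor (rate-of-change units,
#'   must be > 0 when the algorithm runs, else the threshold degenerates
#'   to zero).
#' @param min_isi Minimum inter-stimulus interval in seconds (default 5).
#' @param directionality Trigger direction mode, as in [dynamic_params()].
#' @param retrigger During a sustained supra-threshold plateau, retrigger
#'   every `min_isi` seconds (`TRUE`, default) or only on upward threshold
#'   crossings (`FALSE`).
#'
#' @return An object of class `static_params`.
#' @export
static_params <- function(multiplier = 32, movement_minimum, min_isi = 5,
                          directionality = c("both", "positive_only",
                                             "negative_only",
                                             "bidirectional"),
                          retrigger = TRUE) {
  directionality <- match.arg(directionality)
  stop_if_not_scalar_number(multiplier, "multiplier", 0, strict = TRUE)
  stop_if_not_scalar_number(movement_minimum, "movement_minimum", 0)
  stop_if_not_scalar_number(min_isi, "min_isi", 0)
  structure(
    list(multiplier = multiplier, movement_minimum = movement_minimum,
         min_isi = min_isi, directionality = directionality,
         retrigger = isTRUE(retrigger)),
    class = "static_params"
  )
}

#' Parameters of the periodic algorithm
#'
#' @param interval Seconds between triggers; study values are 6, 6.67, 7.5,
#'   10, 12 and 15. The 12 s default yields 5 triggers per minute.
#'
#' @return An object of class `periodic_params`.
#' @export
periodic_params <- function(interval = 12) {
  stop_if_not_scalar_number(interval, "interval", 0, strict = TRUE)
  structure(list(interval = interval), class = "periodic_params")
}

trigger_events <- function(time = numeric(0), paired_value = numeric(0),
                           threshold = numeric(0), algorithm = character(0),
                           direction = character(0),
                           buffer_rank = numeric(0)) {
  data.frame(time = time, paired_value = paired_value, threshold = threshold,
             algorithm = algorithm, direction = direction,
             buffer_rank = buffer_rank, stringsAsFactors = FALSE)
}

#' Initialise the streaming state of the dynamic algorithm
#'
#' @param params A [dynamic_params()] object.
#'
#' @return An object of class `dynamic_state` to be threaded through
#'   [dynamic_step()]. Fields: the rolling buffer(s) in arrival order, the
#'   last trigger time, and the movement-initiated flag (set at the first
#'   supra-minimum sample and never reverted within a session).
#' @export
dynamic_state <- function(params) {
  stopifnot(inherits(params, "dynamic_params"))
  structure(
    list(buffer = numeric(0), buffer_negative = numeric(0),
         last_trigger_time = NA_real_, movement_initiated = FALSE,
         prev_time = -Inf, params = params),
    class = "dynamic_state"
  )
}

#' Advance the dynamic algorithm by one sample
#'
#' Pure-R reference implementation of one streaming step: the sample is
#' appended to the appropriate buffer (evicting the oldest at capacity),
#' the percentile threshold is recomputed, and a trigger is emitted iff
#' movement has been initiated, the value strictly exceeds the threshold in
#' an allowed direction, and the inter-stimulus-interval gate passes.
#' Folding this step over a session reproduces [run_dynamic()] exactly; the
#' batch runner is the fast path, this is the streaming semantics it must
#' match.
#'
#' @param state A [dynamic_state()].
#' @param time Sample time in seconds (must strictly exceed the previous
#'   sample's time).
#' @param value Rate-of-change value (signed).
#' @param supra_minimum Logical; is the sample above the movement minimum?
#'
#' @return A list with `state` (updated), `event` (one-row trigger
#'   data frame or `NULL`), `threshold_pos` and `threshold_neg` (the
#'   current threshold(s), `NA` while the buffer is below its minimum
#'   fill), and `snapshot` (sorted governing buffer at the trigger, or
#'   `NULL`).
#' @export
dynamic_step <- function(state, time, value, supra_minimum = TRUE) {
  stopifnot(inherits(state, "dynamic_state"))
  p <- state$params
  if (!(time > state$prev_time)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  state$prev_time <- time
  if (supra_minimum) state$movement_initiated <- TRUE

  mode <- p$directionality
  if (supra_minimum || p$include_subminimum) {
    if (mode == "both") {
      state$buffer <- buffer_push(state$buffer, value, p$buffer_size)
    } else if (mode == "positive_only") {
      if (value > 0) state$buffer <- buffer_push(state$buffer, value,
                                                 p$buffer_size)
    } else if (mode == "negative_only") {
      if (value < 0) state$buffer <- buffer_push(state$buffer, -value,
                                                 p$buffer_size)
    } else {
      if (value > 0) {
        state$buffer <- buffer_push(state$buffer, value, p$buffer_size)
      } else if (value < 0) {
        state$buffer_negative <- buffer_push(state$buffer_negative, -value,
                                             p$buffer_size)
      }
    }
  }

  qp <- if (length(state$buffer) >= p$min_fill) {
    percentile_threshold(state$buffer, p$percentile)
  } else NA_real_
  qn <- if (mode == "bidirectional" &&
            length(state$buffer_negative) >= p$min_fill) {
    percentile_threshold(state$buffer_negative, p$percentile)
  } else NA_real_

  threshold_pos <- threshold_neg <- NA_real_
  if (mode == "negative_only") {
    threshold_neg <- if (is.na(qp)) NA_real_ else -qp
  } else {
    threshold_pos <- qp
    if (mode == "bidirectional") {
      threshold_neg <- if (is.na(qn)) NA_real_ else -qn
    }
  }

  isi_ok <- is.na(state$last_trigger_time) ||
    (time - state$last_trigger_time >= p$min_isi - 1e-9)
  event <- NULL
  snapshot <- NULL
  if (state$movement_initiated && supra_minimum && isi_ok) {
    fire <- FALSE
    thr_signed <- cmpv <- NA_real_
    dir <- "positive"
    gov <- NULL
    if (mode == "both") {
      if (!is.na(qp) && value > qp) {
        fire <- TRUE; thr_signed <- qp; cmpv <- value
        dir <- if (value >= 0) "positive" else "negative"
        gov <- state$buffer
      }
    } else if (mode == "positive_only") {
      if (!is.na(qp) && value > 0 && value > qp) {
        fire <- TRUE; thr_signed <- qp; cmpv <- value; gov <- state$buffer
      }
    } else if (mode == "negative_only") {
      if (!is.na(qp) && value < 0 && -value > qp) {
        fire <- TRUE; thr_signed <- -qp; cmpv <- -value; dir <- "negative"
        gov <- state$buffer
      }
    } else {
      if (!is.na(qp) && value > 0 && value > qp) {
        fire <- TRUE; thr_signed <- qp; cmpv <- value; gov <- state$buffer
      } else if (!is.na(qn) && value < 0 && -value > qn) {
        fire <- TRUE; thr_signed <- -qn; cmpv <- -value; dir <- "negative"
        gov <- state$buffer_negative
      }
    }
    if (fire) {
      state$last_trigger_time <- time
      snapshot <- sort(gov)
      event <- trigger_events(time = time, paired_value = value,
                              threshold = thr_signed, algorithm = "dynamic",
                              direction = dir,
                              buffer_rank = inv_quantile_rank_r(snapshot,
                                                                cmpv))
    }
  }

  list(state = state, event = event, threshold_pos = threshold_pos,
       threshold_neg = threshold_neg, snapshot = snapshot)
}

buffer_push <- function(buffer, value, capacity) {
  if (length(buffer) == capacity) buffer <- buffer[-1L]
  c(buffer, value)
}

#' Run the dynamic rolling-percentile algorithm over a session
#'
#' Batch equivalent of folding [dynamic_step()] over the gated
#' rate-of-change stream (implemented in C++ for speed; the equivalence is
#' exact). The rolling buffer holds up to `buffer_size` recent samples;
#' at every sample the threshold is recomputed as the configured
#' percentile of the buffer, and a trigger fires when the incoming value
#' strictly exceeds it, subject to movement initiation and the
#' inter-stimulus-interval gate.
#'
#' @param roc A gated [roc_signal()] (see [gate_noise()]); if ungated, all
#'   samples are treated as supra-minimum.
#' @param params A [dynamic_params()] object.
#' @param keep_snapshots Keep the sorted buffer snapshot at each trigger
#'   (needed by [selectivity_recent_percentile()]; default `TRUE`).
#'
#' @return An object of class `dynamic_run`: list with `events` (trigger
#'   data frame: time, paired_value, threshold, algorithm, direction,
#'   buffer_rank), `thresholds` (per-sample threshold trace with columns
#'   `time`, `threshold_pos`, `threshold_neg`), `snapshots` (list of
#'   sorted buffer snapshots, one per trigger; magnitudes for
#'   negative-direction triggers), and `params`.
#' @export
run_dynamic <- function(roc, params = dynamic_params(),
                        keep_snapshots = TRUE) {
  stopifnot(inherits(roc, "roc_signal"), inherits(params, "dynamic_params"))
  n <- length(roc$values)
  if (n < 1L) stop("signal is empty", call. = FALSE)
  supra <- roc$supra_minimum %||% rep(TRUE, n)
  res <- run_dynamic_cpp(roc$timestamps, roc$values, supra,
                         params$percentile, params$buffer_size,
                         params$min_isi,
                         DIRECTION_MODES[[params$directionality]],
                         params$min_fill, params$include_subminimum,
                         keep_snapshots)
  events <- trigger_events(
    time = res$time, paired_value = res$paired_value,
    threshold = res$threshold, algorithm = rep("dynamic", length(res$time)),
    direction = ifelse(res$direction > 0, "positive", "negative"),
    buffer_rank = res$buffer_rank
  )
  thresholds <- data.frame(time = roc$timestamps,
                           threshold_pos = res$threshold_pos,
                           threshold_neg = res$threshold_neg)
  structure(list(events = events, thresholds = thresholds,
                 snapshots = if (keep_snapshots) res$snapshots else NULL,
                 params = params),
            class = "dynamic_run")
}

#' @export
print.dynamic_run <- function(x, ...) {
  cat(sprintf(
    "<dynamic_run> p%g, buffer %d, min ISI %g s: %d trigger(s)\n",
    x$params$percentile, x$params$buffer_size, x$params$min_isi,
    nrow(x$events)))
  invisible(x)
}

#' Run the static threshold algorithm over a session
#'
#' Triggers whenever the rate of change strictly exceeds
#' `multiplier * movement_minimum` in an allowed direction and the
#' inter-stimulus-interval gate passes. During a sustained supra-threshold
#' plateau the algorithm retriggers every `min_isi` seconds by default
#' (`retrigger = FALSE` restricts triggers to upward crossings).
#'
#' @param roc A [roc_signal()].
#' @param params A [static_params()] object; its `movement_minimum` must be
#'   positive, otherwise the multiplier-based threshold degenerates to 0.
#'
#' @return Trigger data frame with the same columns as
#'   `run_dynamic()$events` (`threshold` is signed toward the trigger
#'   direction; `buffer_rank` is `NA`).
#' @export
run_static <- function(roc, params) {
  stopifnot(inherits(roc, "roc_signal"), inherits(params, "static_params"))
  if (params$movement_minimum <= 0) {
    stop("`movement_minimum` must be > 0 for the static algorithm",
         call. = FALSE)
  }
  n <- length(roc$values)
  if (n < 1L) stop("signal is empty", call. = FALSE)
  thr <- params$multiplier * params$movement_minimum
  v <- roc$values
  t <- roc$timestamps
  exceed <- switch(params$directionality,
                   positive_only = v > thr,
                   negative_only = v < -thr,
                   abs(v) > thr)
  idx <- which(exceed)
  if (!params$retrigger && length(idx)) {
    onset <- c(TRUE, !exceed[idx[-1L] - 1L])
    idx <- idx[onset]
  }
  keep <- integer(0)
  last <- -Inf
  for (i in idx) {
    if (t[i] - last >= params$min_isi - 1e-9) {
      keep <- c(keep, i)
      last <- t[i]
    }
  }
  trigger_events(
    time = t[keep], paired_value = v[keep],
    threshold = sign(v[keep]) * thr,
    algorithm = rep("static", length(keep)),
    direction = ifelse(v[keep] >= 0, "positive", "negative"),
    buffer_rank = rep(NA_real_, length(keep))
  )
}

#' Run the periodic algorithm over a session span
#'
#' Signal-agnostic countdown timer: triggers at `start + k * interval` for
#' k = 1, 2, ... up to and including the end of the span. A 60 s session
#' with a 12 s interval yields 5 triggers (5 per minute).
#'
#' @param session_span Numeric `c(start, end)` in seconds, or a
#'   [roc_signal()]/[raw_signal()] whose timestamp range is used.
#' @param params A [periodic_params()] object.
#'
#' @return Trigger data frame; `paired_value` is `NA` until
#'   [pair_triggers_with_signal()] supplies a movement signal.
#' @export
run_periodic <- function(session_span, params = periodic_params()) {
  stopifnot(inherits(params, "periodic_params"))
  if (inherits(session_span, c("roc_signal", "raw_signal"))) {
    session_span <- range(session_span$timestamps)
  }
  start <- session_span[1]
  end <- session_span[2]
  if (!(end > start)) {
    stop("session span must have `end > start`", call. = FALSE)
  }
  k <- floor((end - start) / params$interval + 1e-9)
  times <- start + params$interval * seq_len(k)
  trigger_events(
    time = times, paired_value = rep(NA_real_, k),
    threshold = rep(NA_real_, k), algorithm = rep("periodic", k),
    direction = rep("n/a", k), buffer_rank = rep(NA_real_, k)
  )
}
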