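#' Triggering rate
#'
#' @param triggers Trigger data frame (see [run_dynamic()]).
#' @param duration Session duration in seconds (> 0).
#'
#' @return Triggers per minute.
#' @export
triggering_rate <- function(triggers, duration) {
  stop_if_not_scalar_number(duration, "duration", 0, strict = TRUE)
  nrow(triggers) / (duration / 60)
}

#' Pair triggers with movement values
#'
#' Fills (or overwrites) `paired_value` for each trigger: with
#' `pairing_window = 0` the value of the sample nearest in time to the
#' trigger; otherwise the signed value of the sample with the largest
#' absolute value within `+/- pairing_window` seconds (the paired movement
#' peak).
#'
#' @param triggers Trigger data frame.
#' @param roc A [roc_signal()] spanning all trigger times.
#' @param pairing_window Half-width of the peak search window in seconds.
#'
#' @return The trigger data frame with `paired_value` filled.
#' @export
pair_triggers_with_signal <- function(triggers, roc, pairing_window = 0) {
  stopifnot(inherits(roc, "roc_signal"))
  stop_if_not_scalar_number(pairing_window, "pairing_window", 0)
  if (nrow(triggers) == 0L) return(triggers)
  t <- roc$timestamps
  v <- roc$values
  if (any(triggers$time < t[1] - 1e-9) ||
      any(triggers$time > t[length(t)] + 1e-9)) {
    stop("trigger times fall outside the signal span", call. = FALSE)
  }
  triggers$paired_value <- vapply(triggers$time, function(tt) {
    if (pairing_window == 0) {
      i <- findInterval(tt, t)
      if (i < 1L) i <- 1L
      if (i < length(t) && (t[i + 1L] - tt) < (tt - t[i])) i <- i + 1L
      v[i]
    } else {
      sel <- which(t >= tt - pairing_window & t <= tt + pairing_window)
      v[sel[which.max(abs(v[sel]))]]
    }
  }, numeric(1))
  triggers
}

#' Selectivity as percent of the session's maximum movement
#'
#' Each trigger's paired movement is expressed as a percentage of the
#' session-wide maximum absolute rate of change; the session value is the
#' median across triggers. Invariant to positive rescaling of the signal.
#'
#' @param triggers Paired trigger data frame (no `NA` in `paired_value`).
#' @param roc The session's [roc_signal()].
#' @param per_trigger Return the per-trigger percentages instead of the
#'   session median.
#'
#' @return Percent in `[0, 100]` (or a vector when `per_trigger = TRUE`).
#' @export
selectivity_pct_of_max <- function(triggers, roc, per_trigger = FALSE) {
  stopifnot(inherits(roc, "roc_signal"))
  if (nrow(triggers) < 1L) {
    stop("selectivity requires at least one trigger", call. = FALSE)
  }
  if (anyNA(triggers$paired_value)) {
    stop("triggers must be paired with the signal first; see ",
         "pair_triggers_with_signal()", call. = FALSE)
  }
  mx <- max(abs(roc$values))
  if (mx <= 0) stop("signal maximum is zero; selectivity undefined",
                    call. = FALSE)
  pct <- abs(triggers$paired_value) / mx * 100
  if (per_trigger) pct else stats::median(pct)
}

#' Selectivity as within-buffer percentile rank
#'
#' For each dynamic trigger, the percentile rank of the paired movement
#' value within the buffer snapshot at the trigger instant (the inverse of
#' the interpolated quantile, so a value strictly above the p-th percentile
#' threshold always ranks above p). The session value is the median across
#' triggers.
#'
#' @param run A `dynamic_run` from [run_dynamic()], or a trigger data frame
#'   that carries a `buffer_rank` column.
#' @param per_trigger Return per-trigger ranks instead of the median.
#'
#' @return Percentile rank(s) in `[0, 100]`.
#' @export
selectivity_recent_percentile <- function(run, per_trigger = FALSE) {
  events <- if (inherits(run, "dynamic_run")) run$events else run
  if (is.null(events$buffer_rank) || nrow(events) < 1L) {
    stop("need at least one dynamic trigger with recorded buffer ranks",
         call. = FALSE)
  }
  if (per_trigger) events$buffer_rank else stats::median(events$buffer_rank)
}

#' Inter-stimulus-interval statistics
#'
#' @param triggers Trigger data frame.
#'
#' @return List with `intervals` (successive trigger-time differences, in
#'   seconds; empty with fewer than 2 triggers), `mean`, and `sem`.
#' @export
isi_stats <- function(triggers) {
  times <- sort(triggers$time)
  if (length(times) < 2L) {
    return(list(intervals = numeric(0), mean = NA_real_, sem = NA_real_))
  }
  iv <- diff(times)
  list(intervals = iv, mean = mean(iv),
       sem = if (length(iv) > 1L) stats::sd(iv) / sqrt(length(iv))
             else NA_real_)
}

#' Periodic-baseline peak normalisation
#'
#' Per-session normalisation constant for comparing trigger policies'
#' paired peak sizes: lay a periodic grid (default every 12 s) over the
#' session, take the maximum absolute rate of change within
#' `+/- peak_window` seconds of each grid point, average over grid points,
#' and then average over all grid phase offsets (stepped at the sampling
#' period across one full interval by default, i.e. every possible
#' placement of the 2-second windows).
#'
#' @param roc The session's [roc_signal()].
#' @param grid_interval Grid spacing in seconds (default 12).
#' @param peak_window Half-width of each peak window in seconds (default 1).
#' @param n_offsets Number of equally spaced phase offsets to average over;
#'   `NULL` (default) uses one offset per sampling period. `n_offsets = 1`
#'   gives the single-phase variant.
#'
#' @return Baseline peak size in rate-of-change units.
#' @export
periodic_baseline_peak <- function(roc, grid_interval = 12, peak_window = 1,
                                   n_offsets = NULL) {
  stopifnot(inherits(roc, "roc_signal"))
  stop_if_not_scalar_number(grid_interval, "grid_interval", 0, strict = TRUE)
  stop_if_not_scalar_number(peak_window, "peak_window", 0, strict = TRUE)
  t <- roc$timestamps
  v <- roc$values
  start <- t[1]
  end <- t[length(t)]
  if (end - start <= grid_interval) {
    stop("session must be longer than `grid_interval`", call. = FALSE)
  }
  dt <- stats::median(diff(t))
  offsets <- if (is.null(n_offsets)) {
    seq(0, grid_interval - dt / 2, by = dt)
  } else {
    seq(0, grid_interval, length.out = n_offsets + 1)[seq_len(n_offsets)]
  }
  per_offset <- vapply(offsets, function(phi) {
    centers <- seq(start + phi, end, by = grid_interval)
    peaks <- window_abs_max_cpp(t, v, centers, peak_window)
    mean(peaks[!is.na(peaks)])
  }, numeric(1))
  mean(per_offset)
}

#' Percent improvement of paired peaks over the periodic baseline
#'
#' @param triggers Paired trigger data frame.
#' @param baseline Positive baseline from [periodic_baseline_peak()].
#'
#' @return List with per-trigger `values`
#'   (`(|paired| - baseline) / baseline * 100`), their `mean`, and `sem`.
#' @export
percent_improvement_over_baseline <- function(triggers, baseline) {
  stop_if_not_scalar_number(baseline, "baseline", 0, strict = TRUE)
  if (nrow(triggers) < 1L || anyNA(triggers$paired_value)) {
    stop("triggers must be non-empty and paired", call. = FALSE)
  }
  vals <- (abs(triggers$paired_value) - baseline) / baseline * 100
  list(values = vals, mean = mean(vals),
       sem = if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals))
             else NA_real_)
}

#' Cohort summary statistics
#'
#' Median with interquartile range, mean with standard error, Tukey
#' whiskers (`Q1 - 1.5 IQR`, `Q3 + 1.5 IQR`) and the boxplot-notch 90%-ish
#' confidence interval of the median (`median +/- 1.58 IQR / sqrt(n)`).
#' Quartiles use linear interpolation (`quantile` type 7).
#'
#' @param values Numeric vector, at least one value.
#'
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohort <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1L) stop("need at least one value", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  notch <- 1.58 * iqr / sqrt(n)
  structure(
    list(median = q[2], iqr = iqr, mean = mean(values),
         sem = if (n > 1L) stats::sd(values) / sqrt(n) else NA_real_,
         whisker_low = q[1] - 1.5 * iqr, whisker_high = q[3] + 1.5 * iqr,
         median_ci_low = q[2] - notch, median_ci_high = q[2] + notch,
         n = n),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "<cohort_summary> n = %d\n  median %.4g (IQR %.4g), mean %.4g +/- %.4g SEM\n  whiskers [%.4g, %.4g]\n",
    x$n, x$median, x$iqr, x$mean, x$sem, x$whisker_low, x$whisker_high))
  invisible(x)
}

#' Two-tailed t-test comparison between groups
#'
#' Thin wrapper around `t.test()` used for cohort comparisons: paired for
#' within-session algorithm contrasts, unpaired for movement-pairing
#' contrasts; always two-tailed, significance at P < .05. Degenerate inputs
#' are guarded: identical paired groups give `statistic = 0, p = 1`; a
#' constant non-zero difference (zero variance) is an error rather than a
#' spurious infinity.
#'
#' @param values_a,values_b Numeric vectors (equal length when paired;
#'   n >= 2 per group).
#' @param paired Paired test?
#'
#' @return An object of class `comparison_result`: list with `statistic`,
#'   `p_value`, `test` (`"paired_t"` or `"unpaired_t"`), `tails = 2`.
#' @export
compare_groups <- function(values_a, values_b, paired = FALSE) {
  a <- values_a
  b <- values_b
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (paired && length(a) != length(b)) {
    stop("paired comparison requires equal-length groups", call. = FALSE)
  }
  degenerate <- if (paired) stats::sd(a - b) == 0 else
    (stats::sd(a) == 0 && stats::sd(b) == 0)
  if (degenerate) {
    if (paired && all(a == b)) {
      res <- list(statistic = 0, p_value = 1)
    } else if (!paired && mean(a) == mean(b)) {
      res <- list(statistic = 0, p_value = 1)
    } else {
      stop("zero variance with non-zero difference; t-test undefined",
           call. = FALSE)
    }
  } else {
    tt <- stats::t.test(a, b, paired = paired, var.equal = FALSE,
                        alternative = "two.sided")
    res <- list(statistic = unname(tt$statistic), p_value = tt$p.value)
  }
  structure(
    list(statistic = res$statistic, p_value = res$p_value,
         test = if (paired) "paired_t" else "unpaired_t", tails = 2L),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: t = %.4g, P = %.4g (2-tailed)\n",
              x$test, x$statistic, x$p_value))
  invisible(x)
}

#' Per-session metric summary
#'
#' @param session_id Session identifier.
#' @param triggers Trigger data frame for one algorithm on this session.
#' @param roc The session's [roc_signal()]. Unpaired triggers are paired
#'   with the nearest sample automatically.
#'
#' @return One-row data frame with `session_id`, `algorithm`,
#'   `n_triggers`, `triggers_per_minute`, `selectivity_pct_of_max`,
#'   `selectivity_recent_percentile` (dynamic runs only), `isi_mean`,
#'   `isi_sem`. Selectivity fields are `NA` for sessions with no triggers;
#'   such sessions still contribute a rate of zero.
#' @export
session_metrics <- function(session_id, triggers, roc) {
  stopifnot(inherits(roc, "roc_signal"))
  if (inherits(triggers, "dynamic_run")) triggers <- triggers$events
  duration <- diff(range(roc$timestamps))
  n <- nrow(triggers)
  sel_max <- sel_pct <- NA_real_
  if (n >= 1L) {
    if (anyNA(triggers$paired_value)) {
      triggers <- pair_triggers_with_signal(triggers, roc)
    }
    sel_max <- selectivity_pct_of_max(triggers, roc)
    if (!is.null(triggers$buffer_rank) && !anyNA(triggers$buffer_rank)) {
      sel_pct <- stats::median(triggers$buffer_rank)
    }
  }
  isi <- isi_stats(triggers)
  data.frame(
    session_id = as.character(session_id),
    algorithm = if (n >= 1L) triggers$algorithm[1] else NA_character_,
    n_triggers = n,
    triggers_per_minute = triggering_rate(triggers, duration),
    selectivity_pct_of_max = sel_max,
    selectivity_recent_percentile = sel_pct,
    isi_mean = isi$mean, isi_sem = isi$sem,
    stringsAsFactors = FALSE
  )
}
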