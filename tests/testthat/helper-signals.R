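# Small deterministic fixtures built in code.

make_raw <- function(values, rate = 60, ...) {
  n <- length(values)
  raw_signal((0:(n - 1)) / rate, values, sampling_rate = rate, ...)
}

make_roc <- function(values, rate = 60, ...) {
  n <- length(values)
  roc_signal((0:(n - 1)) / rate, values, sampling_rate = rate, ...)
}

# A linear ramp y = slope * t lasting `dur` seconds.
make_ramp <- function(slope, dur = 10, rate = 60) {
  t <- seq(0, dur, by = 1 / rate)
  raw_signal(t, slope * t, sampling_rate = rate)
}

# iid-noise roc signal for randomized property tests.
random_roc <- function(n, rate = 60, sd = 1) {
  make_roc(rnorm(n, 0, sd), rate = rate)
}

# Fold dynamic_step over a gated signal; mirrors run_dynamic()'s contract.
fold_dynamic <- function(roc, params) {
  st <- dynamic_state(params)
  supra <- roc$supra_minimum
  if (is.null(supra)) supra <- rep(TRUE, length(roc$values))
  events <- list()
  tp <- tn <- numeric(length(roc$values))
  for (i in seq_along(roc$values)) {
    res <- dynamic_step(st, roc$timestamps[i], roc$values[i], supra[i])
    st <- res$state
    tp[i] <- res$threshold_pos
    tn[i] <- res$threshold_neg
    if (!is.null(res$event)) events[[length(events) + 1L]] <- res$event
  }
  empty <- data.frame(time = numeric(0), paired_value = numeric(0),
                      threshold = numeric(0), algorithm = character(0),
                      direction = character(0), buffer_rank = numeric(0),
                      stringsAsFactors = FALSE)
  list(events = if (length(events)) do.call(rbind, events) else empty,
       thresholds = data.frame(time = roc$timestamps, threshold_pos = tp,
                               threshold_neg = tn))
}
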