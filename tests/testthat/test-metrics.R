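test_that("triggering rate is per-minute count over duration", {
  ev <- run_periodic(c(0, 120), periodic_params(12))
  expect_equal(triggering_rate(ev, 120), 5)
  expect_equal(triggering_rate(ev[0, ], 120), 0)
  expect_equal(triggering_rate(run_periodic(c(0, 60), periodic_params(12)),
                               60), 5)
  expect_error(triggering_rate(ev, 0), "duration")
})

test_that("pairing picks the nearest sample or the windowed peak", {
  roc <- make_roc(c(0, 1, 2, 7, 2, 1, 0), rate = 1)  # 1 Hz for clarity
  ev <- run_periodic(c(0, 6), periodic_params(3))    # t = 3, 6
  got <- pair_triggers_with_signal(ev, roc)
  expect_equal(got$paired_value, c(7, 0))
  # between samples: the nearer neighbour wins
  ev2 <- data.frame(time = 3.4, paired_value = NA_real_, threshold = NA,
                    algorithm = "manual", direction = "n/a",
                    buffer_rank = NA_real_)
  expect_equal(pair_triggers_with_signal(ev2, roc)$paired_value, 7)
  ev2$time <- 3.6
  expect_equal(pair_triggers_with_signal(ev2, roc)$paired_value, 2)
  # windowed pairing returns the +/-1 s peak
  ev2$time <- 4
  expect_equal(pair_triggers_with_signal(ev2, roc, 1)$paired_value, 7)
  ev2$time <- 99
  expect_error(pair_triggers_with_signal(ev2, roc), "outside")
})

test_that("percent-of-max selectivity is a median and scale-invariant", {
  roc <- make_roc(c(0, 10, -6, 8, 2))
  ev <- data.frame(time = c(1, 3) / 60, paired_value = c(8, 6),
                   threshold = NA, algorithm = "static",
                   direction = "positive", buffer_rank = NA_real_)
  expect_equal(selectivity_pct_of_max(ev, roc), 70)
  expect_equal(selectivity_pct_of_max(ev, roc, per_trigger = TRUE),
               c(80, 60))
  # single trigger at the maximum scores 100%
  ev1 <- ev[1, ]; ev1$paired_value <- 10
  expect_equal(selectivity_pct_of_max(ev1, roc), 100)
  # positive rescaling changes nothing
  roc3 <- make_roc(3 * c(0, 10, -6, 8, 2))
  ev3 <- ev; ev3$paired_value <- 3 * ev$paired_value
  expect_equal(selectivity_pct_of_max(ev3, roc3), 70)
  expect_error(selectivity_pct_of_max(ev, make_roc(rep(0, 5))), "zero")
})

test_that("buffer percentile ranks invert the quantile convention", {
  # rank of the median element of an odd-length buffer is 50%
  set.seed(121)
  roc <- gate_noise(random_roc(2000), 0.3)
  run <- run_dynamic(roc, dynamic_params(60, min_isi = 1, min_fill = 31))
  expect_gt(nrow(run$events), 2)
  expect_true(all(selectivity_recent_percentile(run, per_trigger = TRUE) > 60))
  # consistency oracle: quantile at the reported rank recovers the value
  for (i in seq_len(nrow(run$events))) {
    s <- run$snapshots[[i]]
    v <- run$events$paired_value[i]
    r <- run$events$buffer_rank[i]
    recovered <- unname(quantile(s, r / 100, type = 7))
    expect_equal(recovered, min(max(v, min(s)), max(s)), tolerance = 1e-9)
  }
  expect_equal(selectivity_recent_percentile(run),
               median(run$events$buffer_rank))
})

test_that("ISI statistics summarise successive trigger gaps", {
  ev <- data.frame(time = c(5, 12, 30))
  got <- isi_stats(ev)
  expect_equal(got$intervals, c(7, 18))
  expect_equal(got$mean, 12.5)
  expect_equal(got$sem, sd(c(7, 18)) / sqrt(2))
  per <- run_periodic(c(0, 120), periodic_params(12))
  expect_true(all(abs(isi_stats(per)$intervals - 12) < 1e-9))
  expect_length(isi_stats(ev[1, , drop = FALSE])$intervals, 0)
})

test_that("the periodic baseline matches a brute-force enumeration", {
  # constant |signal| pins the baseline at that constant
  expect_equal(periodic_baseline_peak(make_roc(rep(2.5, 20 * 60 + 1)),
                                      grid_interval = 12), 2.5)
  expect_equal(periodic_baseline_peak(make_roc(rep(0, 20 * 60 + 1)),
                                      grid_interval = 12), 0)
  # a single rectangular burst, checked against exhaustive enumeration
  # (window edges offset from the sample grid so float ties cannot occur)
  rate <- 10
  t <- (0:150) / rate
  v <- ifelse(t > 6.01 & t < 7.01, 5, 0)
  roc <- roc_signal(t, v, sampling_rate = rate)
  got <- periodic_baseline_peak(roc, grid_interval = 6, peak_window = 1.05)
  dt <- 1 / rate
  offsets <- seq(0, 6 - dt / 2, by = dt)
  oracle <- mean(vapply(offsets, function(phi) {
    centers <- seq(phi, 15, by = 6)
    peaks <- vapply(centers, function(g) {
      sel <- which(t >= g - 1.05 & t <= g + 1.05)
      if (!length(sel)) return(NA_real_)
      max(abs(v[sel]))
    }, numeric(1))
    mean(peaks, na.rm = TRUE)
  }, numeric(1)))
  expect_equal(got, oracle, tolerance = 1e-9)
  # bounded by the signal maximum
  set.seed(131)
  roc <- random_roc(20 * 60)
  expect_lte(periodic_baseline_peak(roc), max(abs(roc$values)))
  expect_error(periodic_baseline_peak(make_roc(rep(1, 60)), 12), "longer")
})

test_that("improvement over baseline is elementary arithmetic with guards", {
  ev <- data.frame(time = 1:3, paired_value = c(1, 1, 1))
  expect_equal(percent_improvement_over_baseline(ev, 1)$mean, 0)
  ev$paired_value <- c(1.7, 1.7, 1.7)
  expect_equal(percent_improvement_over_baseline(ev, 1)$mean, 70)
  expect_error(percent_improvement_over_baseline(ev, 0), "baseline")
})

test_that("cohort summaries agree with hand-computed quartiles", {
  s <- summarize_cohort(1:5)
  expect_equal(s$median, 3)
  expect_equal(s$iqr, 2)
  expect_equal(s$mean, 3)
  expect_equal(s$whisker_low, -1)   # Q1 - 1.5 IQR = 2 - 3
  expect_equal(s$whisker_high, 7)
  expect_equal(s$sem, sd(1:5) / sqrt(5))
  s1 <- summarize_cohort(4.2)
  expect_equal(s1$median, 4.2)
  expect_equal(s1$iqr, 0)
  expect_identical(s1$n, 1L)
  # brute-force quartile oracle on random samples
  set.seed(141)
  for (i in 1:50) {
    x <- rnorm(sample(3:40, 1))
    s <- summarize_cohort(x)
    srt <- sort(x)
    n <- length(srt)
    qs <- vapply(c(0.25, 0.75), function(p) {
      h <- (n - 1) * p
      lo <- floor(h)
      srt[lo + 1] + (h - lo) * (srt[min(n, lo + 2)] - srt[lo + 1])
    }, numeric(1))
    expect_equal(s$iqr, qs[2] - qs[1], tolerance = 1e-12)
    expect_equal(s$whisker_high, qs[2] + 1.5 * (qs[2] - qs[1]),
                 tolerance = 1e-12)
  }
})

test_that("group comparisons guard degenerate variance", {
  a <- c(1, 2, 3, 4)
  same <- compare_groups(a, a, paired = TRUE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_groups(a, a + 2, paired = TRUE), "zero variance")
  got <- compare_groups(c(1, 2, 3), c(1.5, 2.5, 3.5, 4), paired = FALSE)
  expect_equal(got$tails, 2L)
  expect_true(got$p_value >= 0 && got$p_value <= 1)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("the t-test detects a unit shift in most seeded replicates", {
  hits <- 0L
  for (s in 1:200) {
    set.seed(s)
    a <- rnorm(50, 0)
    b <- rnorm(50, 1)
    if (compare_groups(a, b)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 190)
})

test_that("session metrics assemble per-session rows", {
  set.seed(151)
  sess <- generate_session(synth_config(seed = 3))
  roc <- preprocess_signal(sess$signal, 300, 4.7)
  run <- run_dynamic(roc, dynamic_params(95))
  m <- session_metrics("s3", run, roc)
  expect_identical(nrow(m), 1L)
  expect_identical(m$n_triggers, nrow(run$events))
  expect_equal(m$triggers_per_minute,
               nrow(run$events) / (diff(range(roc$timestamps)) / 60))
  expect_gt(m$selectivity_recent_percentile, 95)
  # a zero-trigger session keeps the rate but drops selectivity
  m0 <- session_metrics("empty", run$events[0, ], roc)
  expect_equal(m0$triggers_per_minute, 0)
  expect_true(is.na(m0$selectivity_pct_of_max))
})
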