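test_that("percentile_threshold interpolates order statistics linearly", {
  expect_equal(percentile_threshold(1:100, 95), 95.05)
  expect_equal(percentile_threshold(c(0, 10), 50), 5)
  expect_equal(percentile_threshold(rep(4.2, 50), 77), 4.2)
  expect_error(percentile_threshold(1, 50), "at least 2")
  expect_error(percentile_threshold(1:10, 0), "strictly between")
  expect_error(percentile_threshold(1:10, 100), "strictly between")
})

test_that("percentile_threshold matches an independent quantile oracle", {
  set.seed(41)
  for (i in 1:200) {
    v <- rnorm(sample(2:400, 1))
    p <- runif(1, 1, 99)
    expect_equal(percentile_threshold(v, p),
                 unname(quantile(v, p / 100, type = 7)),
                 tolerance = 1e-12)
  }
})

test_that("dynamic stepping obeys tie, maximum and ISI rules", {
  p <- dynamic_params(percentile = 95, buffer_size = 100, min_isi = 5,
                      min_fill = 5)
  # constant stream never strictly exceeds its own percentile
  run <- run_dynamic(make_roc(rep(2, 200)), p)
  expect_identical(nrow(run$events), 0L)
  # a single value above everything buffered triggers exactly once
  v <- c(rep(0.1, 100), 5, rep(0.1, 50))
  run <- run_dynamic(make_roc(v), p)
  expect_identical(nrow(run$events), 1L)
  expect_equal(run$events$paired_value, 5)
  # two supra-threshold peaks 2 s apart: second suppressed by the gate
  v <- rep(0.1, 601)
  v[c(241, 361)] <- 5  # t = 4 s and 6 s
  run <- run_dynamic(gate_noise(make_roc(v), 0), p)
  expect_identical(nrow(run$events), 1L)
  expect_equal(run$events$time, 4)
})

test_that("no dynamic trigger precedes movement initiation", {
  # sub-minimum samples can exceed the threshold numerically but cannot
  # trigger; the first supra-minimum sample flips initiation permanently
  v <- c(rep(0.5, 100), rep(3, 50))
  roc <- gate_noise(make_roc(v), 1)
  p <- dynamic_params(percentile = 50, buffer_size = 100, min_isi = 0,
                      min_fill = 5, include_subminimum = TRUE)
  run <- run_dynamic(roc, p)
  expect_true(all(run$events$time >= 100 / 60))
  expect_gt(nrow(run$events), 0)
})

test_that("dynamic triggers strictly exceed their governing threshold", {
  set.seed(51)
  roc <- gate_noise(random_roc(3000), 0.5)
  run <- run_dynamic(roc, dynamic_params(85, min_fill = 30))
  expect_gt(nrow(run$events), 0)
  expect_true(all(abs(run$events$paired_value) > abs(run$events$threshold)))
  expect_true(all(run$events$buffer_rank > 85))
  # the recorded snapshot reproduces the decision: value > p85 of snapshot
  ok <- mapply(function(s, v) v > percentile_threshold(s, 85),
               run$snapshots, run$events$paired_value)
  expect_true(all(ok))
})

test_that("out-of-order timestamps are rejected", {
  p <- dynamic_params()
  st <- dynamic_state(p)
  st <- dynamic_step(st, 1, 0.5)$state
  expect_error(dynamic_step(st, 0.5, 0.7), "strictly increasing")
  bad <- make_roc(1:10)
  bad$timestamps[5] <- bad$timestamps[3]
  expect_error(run_dynamic(bad, p), "strictly increasing")
})

test_that("buffer occupancy is bounded and fills exactly at capacity", {
  p <- dynamic_params(percentile = 95, buffer_size = 300, min_fill = 5,
                      min_isi = 0)
  st <- dynamic_state(p)
  set.seed(61)
  v <- rnorm(400)
  for (i in seq_along(v)) {
    st <- dynamic_step(st, i / 60, v[i], TRUE)$state
    expect_lte(length(st$buffer), 300)
    if (i >= 300) expect_identical(length(st$buffer), 300L)
  }
  expect_true(st$movement_initiated)
})

test_that("dynamic trigger count is non-increasing in the percentile", {
  set.seed(71)
  roc <- gate_noise(random_roc(5000), 0.2)
  counts <- vapply(c(45, 65, 85, 95), function(pc) {
    nrow(run_dynamic(roc, dynamic_params(pc, min_isi = 1),
                     keep_snapshots = FALSE)$events)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("static thresholding handles plateaus, misses and retriggers", {
  p32 <- static_params(multiplier = 32, movement_minimum = 1, min_isi = 5)
  expect_identical(nrow(run_static(make_roc(rep(10, 100)), p32)), 0L)
  v <- rep(0, 1200); v[300:310] <- 40
  expect_identical(nrow(run_static(make_roc(v), p32)), 1L)
  # sustained 12 s plateau: onset trigger then one per 5 s while above
  t <- seq(0, 20, by = 1 / 60)
  v <- ifelse(t >= 2 & t < 14, 40, 0)
  ev <- run_static(roc_signal(t, v), p32)
  expect_equal(ev$time, c(2, 7, 12))
  # crossing-only mode collapses the plateau to a single trigger
  ponce <- static_params(32, 1, min_isi = 5, retrigger = FALSE)
  expect_identical(nrow(run_static(roc_signal(t, v), ponce)), 1L)
  expect_error(run_static(make_roc(1:5), static_params(2, 0)),
               "must be > 0")
})

test_that("static trigger count is non-increasing in the multiplier", {
  set.seed(81)
  roc <- random_roc(5000)
  counts <- vapply(c(1, 2, 4, 8, 16, 32), function(m) {
    nrow(run_static(roc, static_params(m, 0.1, min_isi = 1)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("periodic triggers tile the session span", {
  ev <- run_periodic(c(0, 60), periodic_params(12))
  expect_equal(ev$time, c(12, 24, 36, 48, 60))
  expect_identical(nrow(run_periodic(c(0, 30), periodic_params(12))), 2L)
  expect_identical(nrow(run_periodic(c(0, 11.9), periodic_params(12))), 0L)
  expect_error(run_periodic(c(10, 10), periodic_params(12)), "end > start")
  # a signal object works as a span and survives float grids
  roc <- make_roc(rep(0, 60 * 60 + 1))
  expect_identical(nrow(run_periodic(roc, periodic_params(12))), 5L)
})

test_that("ISI gate holds for dynamic and static runs", {
  set.seed(91)
  roc <- gate_noise(random_roc(6000), 0.2)
  dur <- diff(range(roc$timestamps))
  for (ev in list(run_dynamic(roc, dynamic_params(75, min_isi = 3),
                              keep_snapshots = FALSE)$events,
                  run_static(roc, static_params(1, 0.2, min_isi = 3)))) {
    expect_gt(nrow(ev), 1)
    expect_true(all(diff(ev$time) >= 3 - 1e-9))
    expect_lte(nrow(ev), floor(dur / 3) + 1)
  }
})

test_that("directionality modes restrict trigger signs", {
  set.seed(101)
  cfg <- synth_config(seed = 7, asymmetry = 0.7)
  sess <- generate_session(cfg)
  roc <- preprocess_signal(sess$signal, 300, 4.7)
  pos <- run_dynamic(roc, dynamic_params(75, directionality = "positive_only",
                                         min_isi = 1), keep_snapshots = FALSE)
  expect_gt(nrow(pos$events), 0)
  expect_true(all(pos$events$paired_value > 0))
  neg <- run_dynamic(roc, dynamic_params(75, directionality = "negative_only",
                                         min_isi = 1), keep_snapshots = FALSE)
  expect_gt(nrow(neg$events), 0)
  expect_true(all(neg$events$paired_value < 0))
  expect_true(all(neg$events$direction == "negative"))
  bid <- run_dynamic(roc, dynamic_params(75, directionality = "bidirectional",
                                         min_isi = 1), keep_snapshots = FALSE)
  expect_setequal(unique(bid$events$direction), c("positive", "negative"))
  # each direction's trigger beats its own signed threshold
  pe <- bid$events[bid$events$direction == "positive", ]
  ne <- bid$events[bid$events$direction == "negative", ]
  expect_true(all(pe$paired_value > pe$threshold))
  expect_true(all(ne$paired_value < ne$threshold))
  # the two thresholds move independently (disjoint value sets)
  tr <- bid$thresholds
  both <- !is.na(tr$threshold_pos) & !is.na(tr$threshold_neg)
  expect_false(isTRUE(all.equal(tr$threshold_pos[both],
                                -tr$threshold_neg[both])))
})

test_that("a stationary stream fires at about the complementary rate", {
  # iid noise, percentile 95, no ISI gate: the fraction of samples beating
  # the running threshold converges to ~5%
  set.seed(111)
  n <- 50000
  roc <- gate_noise(make_roc(rnorm(n)), 0)
  run <- run_dynamic(roc, dynamic_params(95, min_isi = 0, min_fill = 30),
                     keep_snapshots = FALSE)
  frac <- nrow(run$events) / n
  expect_gt(frac, 0.044)
  expect_lt(frac, 0.056)
})
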