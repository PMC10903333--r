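test_that("mean/SEM aggregation matches hand computation", {
  ser <- data.frame(track_id = rep(1:2, each = 2), time_s = rep(c(0, 15), 2),
                    v = c(0.9, 0.9, 1.1, 1.1))
  agg <- aggregate_mean_sem(ser)
  expect_equal(agg$mean, c(1, 1))
  expect_equal(agg$sem, c(0.1, 0.1)) # sd(c(.9, 1.1))/sqrt(2)
  expect_equal(agg$n, c(2, 2))

  identical_ser <- data.frame(track_id = rep(1:3, each = 2),
                              time_s = rep(c(0, 15), 3), v = 1)
  expect_true(all(aggregate_mean_sem(identical_ser)$sem == 0))
  expect_error(aggregate_mean_sem(ser[1:2, ]), "two overlapping")
})

test_that("SEM scales as 1/sqrt(n) for unit-variance series", {
  set.seed(21)
  n <- 1000
  ser <- data.frame(track_id = rep(seq_len(n), each = 2),
                    time_s = rep(c(0, 15), n),
                    v = rnorm(2 * n, 10, 1))
  agg <- aggregate_mean_sem(ser)
  expect_lt(abs(agg$sem[1] - 1 / sqrt(n)) / (1 / sqrt(n)), 0.1)
})

test_that("partial tracks are excluded from aggregation", {
  ser <- rbind(data.frame(track_id = 1L, time_s = seq(0, 135, 15), v = 1),
               data.frame(track_id = 2L, time_s = seq(0, 135, 15), v = 2),
               data.frame(track_id = 3L, time_s = c(0, 15), v = 50))
  agg <- aggregate_mean_sem(ser, min_frac = 0.8)
  expect_equal(unique(agg$mean), 1.5) # the short noisy track is dropped
})

test_that("loess smoothing reproduces lines and constants exactly", {
  t <- seq(0, 480, 15)
  line <- 0.5 + 0.002 * t
  sm <- smooth_series(t, line, span = 0.5)
  expect_lt(max(abs(sm$fit - (0.5 + 0.002 * sm$time_s))), 1e-10)
  smc <- smooth_series(t, rep(2, length(t)), span = 0.5)
  expect_lt(max(abs(smc$fit - 2)), 1e-12)
  expect_true(all(sm$hi >= sm$fit & sm$lo <= sm$fit))
  expect_error(smooth_series(1:4, 1:4), "at least 5")
  expect_error(smooth_series(t, line, span = 0), "span")
})

test_that("loess recovers a noisy exponential within the noise level", {
  set.seed(14)
  t <- seq(0, 480, 5)
  truth <- 1 - 0.5 * exp(-t / 120)
  obs <- truth + rnorm(length(t), 0, 0.02)
  sm <- smooth_series(t, obs, span = 0.3)
  interior <- sm$time_s > 48 & sm$time_s < 432
  want <- 1 - 0.5 * exp(-sm$time_s / 120)
  expect_lt(max(abs(sm$fit - want)[interior]), 0.02)
})

test_that("equilibration time matches the analytic exponential value", {
  t <- seq(0, 2000, 2)
  tau <- 150
  v <- 1 + 0.5 * exp(-t / tau)
  teq <- equilibration_time(t, v, epsilon = 0.05)
  ## 0.5 exp(-t/tau) = 0.05 * plateau -> t = tau log10 (plateau ~ 1)
  expect_lt(abs(teq - tau * log(10)) / (tau * log(10)), 0.03)
  expect_equal(equilibration_time(t, rep(3, length(t))), 0)
  ## a still-drifting series is reported as not equilibrated
  expect_true(is.na(equilibration_time(seq(0, 100, 10), seq(1, 3, length.out = 11),
                                       epsilon = 0.01)))
})

test_that("equilibration equals the exhaustive suffix scan on jagged traces", {
  set.seed(30)
  for (rep in 1:25) {
    t <- seq(0, 480, 15)
    v <- 1 + cumsum(rnorm(length(t), 0, 0.05))
    v <- abs(v) + 0.2
    expect_identical(equilibration_time(t, v),
                     suffix_scan_teq(t, v))
  }
})

test_that("equilibration is invariant to time shifts and volume rescaling", {
  set.seed(31)
  t <- seq(0, 480, 15)
  v <- 1 - 0.4 * exp(-t / 90) + rnorm(length(t), 0, 0.01)
  a <- equilibration_time(t, v)
  b <- equilibration_time(t + 1000, v, perturbation_time = 1000) - 1000
  expect_equal(a, b)
  expect_equal(equilibration_time(t, 7 * v), a)
})

test_that("shrink-swell metrics behave at the extremes", {
  t <- seq(0, 300, 15)
  mono <- exp(-t / 80)
  m1 <- shrink_swell_metrics(t, mono)
  expect_equal(m1$recovery_fraction, 0) # monotone decay never recovers
  full <- c(1, 0.6, 0.4, 0.6, 0.8, 1, rep(1, length(t) - 6))
  m2 <- shrink_swell_metrics(t, full)
  expect_equal(m2$recovery_fraction, 1)
  expect_equal(m2$v_min, 0.4)
  expect_equal(m2$t_min, 30)
})

test_that("despiking removes isolated glitches but keeps smooth change", {
  t <- seq(0, 480, 15)
  v <- 1 - 0.4 * exp(-t / 100)
  vg <- v
  vg[10] <- vg[10] * 2 # a one-frame segmentation merge
  ser <- rbind(data.frame(track_id = 1L, time_s = t, v = v),
               data.frame(track_id = 2L, time_s = t, v = vg))
  out <- despike_volume_series(ser)
  expect_equal(nrow(out[out$track_id == 1L, ]), length(t))
  expect_equal(nrow(out[out$track_id == 2L, ]), length(t) - 1L)
  expect_false(t[10] %in% out$time_s[out$track_id == 2L])
})

test_that("track-level QC drops merge-jump series", {
  t <- seq(0, 480, 15)
  good <- data.frame(track_id = 1L, time_s = t, v = 1 - 0.3 * exp(-t / 100))
  bad <- data.frame(track_id = 2L, time_s = t,
                    v = c(rep(1, 16), rep(2.2, 17)))
  out <- filter_volume_series(rbind(good, bad), max_step_frac = 0.8)
  expect_equal(unique(out$track_id), 1L)
})

test_that("normalization divides by the last pre-switch volume", {
  cells <- data.frame(track_id = rep(1L, 4), time_s = c(-30, -15, 0, 15),
                      volume_um3 = c(180, 190, 200, 100))
  ser <- normalize_volume_series(cells, switch_time = 0)
  expect_equal(ser$v, c(0.9, 0.95, 1, 0.5))
})
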