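test_that("pre/post deltas reproduce the printed worked examples", {
  # anesthetized females, mHR: 269.5 -> 264.5 is a -5 bpm change
  d1 <- epoch_delta(269.5, 264.5, "absolute")
  expect_equal(d1$delta, -5)
  expect_equal(report_delta(d1$delta), -5)
  # anesthetized females, RespHRV: 3.8 -> 5.8 is +52.6%, reported +53%
  d2 <- epoch_delta(3.8, 5.8, "percent")
  expect_equal(d2$delta, 100 * 2 / 3.8)
  expect_equal(report_delta(d2$delta), 53)
  # no change
  expect_equal(epoch_delta(7, 7, "percent")$delta, 0)
  expect_error(epoch_delta(0, 5, "percent"),
               class = "resphrv_invalid_argument")
})

test_that("percent deltas are invariant to rescaling pre and post", {
  set.seed(1)
  for (i in 1:20) {
    pre <- runif(1, 1, 100); post <- runif(1, 1, 100); c0 <- runif(1, 0.1, 10)
    expect_equal(epoch_delta(pre, post, "percent")$delta,
                 epoch_delta(c0 * pre, c0 * post, "percent")$delta,
                 tolerance = 1e-12)
  }
})

test_that("group effects honor both conventions", {
  d <- data.frame(pre = c(10, 10), post = c(11, 13))
  g <- group_effect(d, "per_subject_mean", "percent")
  expect_equal(g$delta, 20)
  expect_equal(g$n, 2)
  # identical subjects: conventions coincide
  d2 <- data.frame(pre = c(5, 5, 5), post = c(6, 6, 6))
  expect_equal(group_effect(d2, "per_subject_mean", "percent")$delta,
               group_effect(d2, "group_mean_delta", "percent")$delta)
  # shared pre value: conventions coincide exactly even with varying post
  d3 <- data.frame(pre = rep(8, 4), post = c(9, 10, 7, 12))
  expect_equal(group_effect(d3, "per_subject_mean", "percent")$delta,
               group_effect(d3, "group_mean_delta", "percent")$delta,
               tolerance = 1e-12)
  expect_error(group_effect(data.frame(pre = 1, post = 2)),
               class = "resphrv_invalid_argument")
  expect_error(group_effect(data.frame(pre = c(1, NA), post = c(2, 3))),
               class = "resphrv_invalid_argument")
})

test_that("per-subject group deltas match a brute-force loop", {
  set.seed(42)
  d <- data.frame(pre = runif(12, 5, 20), post = runif(12, 5, 20))
  g <- group_effect(d, "per_subject_mean", "percent")
  acc <- 0
  for (i in seq_len(nrow(d))) {
    acc <- acc + 100 * (d$post[i] - d$pre[i]) / d$pre[i]
  }
  expect_equal(g$delta, acc / nrow(d), tolerance = 1e-12)
  gm <- group_effect(d, "group_mean_delta", "absolute")
  expect_equal(gm$delta, mean(d$post) - mean(d$pre), tolerance = 1e-12)
})

test_that("pearson regression is exact on deterministic lines", {
  d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
  f <- pearson_regression(d, x, y)
  expect_equal(f$r, 1, tolerance = 1e-12)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  f2 <- pearson_regression(data.frame(a = 1:5, b = -(1:5)), a, b)
  expect_equal(f2$r, -1, tolerance = 1e-12)
  expect_error(pearson_regression(data.frame(x = c(1, 1, 1), y = 1:3), x, y),
               class = "resphrv_invalid_argument")
  expect_error(pearson_regression(data.frame(x = 1:2, y = 1:2), x, y),
               class = "resphrv_invalid_argument")
})

test_that("pearson r, p and line match brute-force formulas to 1e-12", {
  set.seed(7)
  d <- data.frame(x = rnorm(10), y = rnorm(10))
  f <- pearson_regression(d, x, y)
  r0 <- brute_pearson_r(d$x, d$y)
  expect_equal(f$r, r0, tolerance = 1e-12)
  t0 <- r0 * sqrt((10 - 2) / (1 - r0^2))
  expect_equal(f$p_two_sided, 2 * stats::pt(-abs(t0), 10 - 2),
               tolerance = 1e-12)
  b <- sum((d$x - mean(d$x)) * (d$y - mean(d$y))) / sum((d$x - mean(d$x))^2)
  expect_equal(f$slope, b, tolerance = 1e-12)
  expect_equal(f$intercept, mean(d$y) - b * mean(d$x), tolerance = 1e-12)
  # r^2 identity against the fitted slope
  expect_equal(f$r^2, f$slope * (sd(d$x) / sd(d$y)) * f$r, tolerance = 1e-12)
  expect_equal(glance(f)$r_squared, f$r^2)
})

test_that("recovery kinetics pick the first bin inside the band", {
  bins <- data.frame(label = c("b1", "b2", "b3"), value = c(5, 9.8, 10))
  r <- recovery_kinetics(10, bins, criterion_band = 10)
  expect_equal(r$recovery_bin, "b2")
  expect_equal(tidy(r)$delta_percent, c(-50, -2, 0))
  r2 <- recovery_kinetics(10, data.frame(label = "b1", value = 5))
  expect_true(is.na(r2$recovery_bin))
  expect_error(recovery_kinetics(NULL, bins),
               class = "resphrv_invalid_argument")
  expect_error(recovery_kinetics(0, bins),
               class = "resphrv_invalid_argument")
})
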