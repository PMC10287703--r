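test_that("the naive residual SD is the sample SD of first differences", {
  expect_equal(naive_residual_sd(rep(5, 10)), 0)
  expect_equal(naive_residual_sd(c(1, 2, 3, 4)), 0)  # residuals all 1
  expect_error(naive_residual_sd(c(1, 2)), "at least 3")
  # seeded random walk with innovation SD 100: estimate within 15%
  set.seed(123)
  walk <- cumsum(rnorm(200, 0, 100))
  expect_lt(abs(naive_residual_sd(walk) - 100) / 100, 0.15)
  # trailing window restricts the residual sample
  s <- c(rep(0, 50), cumsum(rnorm(50, 0, 10)))
  expect_equal(naive_residual_sd(s, window = 50),
               sd(diff(tail(s, 50))))
})

test_that("interval bounds use half-up rounding around the point", {
  p1 <- prediction_interval(3520, 1.28, 1271)
  expect_equal(c(p1$lower, p1$upper), c(1893, 5147))
  p2 <- prediction_interval(5171, 1.28, 1271)
  expect_equal(c(p2$lower, p2$upper), c(3544, 6798))
  d <- prediction_interval(4200, 1.28, 0)
  expect_equal(c(d$lower, d$upper), c(4200, 4200))  # degenerate
  expect_error(prediction_interval(100, 1.28, -1), "non-negative")
})

test_that("intervals are symmetric before rounding and widen monotonically", {
  set.seed(42)
  for (i in 1:50) {
    point <- runif(1, 0, 20000)
    cc <- runif(1, 0.5, 3)
    s <- runif(1, 0, 3000)
    gap <- cc * s
    expect_equal(point - (point - gap), (point + gap) - point)
  }
  widths_sigma <- vapply(seq(0, 2000, by = 100), function(s) {
    pi <- prediction_interval(5000, 1.28, s)
    pi$upper - pi$lower
  }, 0)
  expect_true(all(diff(widths_sigma) >= 0))
  widths_c <- vapply(c(1.28, 1.645, 1.96), function(cc) {
    pi <- prediction_interval(5000, cc, 1000)
    pi$upper - pi$lower
  }, 0)
  expect_true(all(diff(widths_c) > 0))
})

test_that("coverage constants are looked up, not extrapolated", {
  expect_equal(coverage_constant(0.80), 1.28)
  expect_equal(coverage_constant(0.90), 1.645)
  expect_equal(coverage_constant(0.95), 1.96)
  expect_error(coverage_constant(0.5), "unsupported")
})

test_that("the weekly interval table reports 7 rows and the mean point", {
  pts <- c(3520, 5171, 4855, 4979, 5071, 4508, 3928)
  tab <- weekly_interval_table(pts, 1.28, 1271)
  expect_equal(nrow(tab), 7)
  expect_equal(attr(tab, "mean_point"), 4576.0)
  expect_error(weekly_interval_table(pts[1:6], 1.28, 1271), "length 7")
  # sigma 0: every interval degenerates to its point
  z <- weekly_interval_table(pts, 1.28, 0)
  expect_equal(z$lower, round_half_up(pts))
  expect_equal(z$upper, round_half_up(pts))
  # all-zero points without flooring are symmetric about 0
  zz <- weekly_interval_table(rep(0, 7), 1.28, 100)
  expect_equal(zz$lower, rep(-128, 7))
  expect_equal(zz$upper, rep(128, 7))
  expect_equal(attr(zz, "mean_point"), 0.0)
  zf <- weekly_interval_table(rep(0, 7), 1.28, 100, floor_at_zero = TRUE)
  expect_equal(zf$lower, rep(0, 7))
})

test_that("optional sqrt-h widening grows the gap with the horizon", {
  a <- prediction_interval(5000, 1.28, 500, h = 4, widen_sqrt_h = TRUE)
  b <- prediction_interval(5000, 1.28, 500, h = 1, widen_sqrt_h = TRUE)
  expect_equal(a$sigma_h, 1000)
  expect_gt(a$upper - a$lower, b$upper - b$lower)
})
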