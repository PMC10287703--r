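# independent oracle: literal transcription of the published rule disjuncts,
# evaluated level by level with maximum precedence
oracle_level <- function(step, mpa, vpa) {
  me <- (vpa * 2 + mpa) * 7
  hit <- c(
    (step < 5000 & me < 90 & TRUE) | (step < 5000),
    (step > 4999 & me >= 90 & me < 210) | (step > 4999 & step < 7500),
    (step > 4999 & me >= 210 & me < 300) | (step > 7499 & step < 10000),
    (step > 4999 & me >= 300 & me < 360) | (step > 9999 & step < 12500),
    (step > 4999 & me >= 360) | (step > 12499)
  )
  max(which(hit)) - 1L
}

test_that("moderate-equivalent weekly minutes follow 2xVPA + MPA over 7 days", {
  expect_equal(moderate_equivalent_weekly(10, 5), 140)
  expect_equal(moderate_equivalent_weekly(0, 0), 0)
  expect_equal(moderate_equivalent_weekly(30, 15), 420)
  expect_error(moderate_equivalent_weekly(-1, 0), "non-negative")
})

test_that("day classification matches the rule oracle on anchor cases", {
  expect_equal(classify_day(4000, 120, 120), 0L)   # < 5000 steps is sedentary
  expect_equal(classify_day(13000, 0, 0), 4L)
  expect_equal(classify_day(11000, 10, 5), 3L)     # step band beats ME band
  expect_equal(classify_day(5000, 30, 15), 4L)     # weekly ME 420 >= 360
  expect_error(classify_day(-1), "non-negative")
})

test_that("classification is total and agrees with the disjunct oracle on a grid", {
  steps <- seq(0, 20000, by = 500)
  mpa <- seq(0, 120, by = 15)
  vpa <- seq(0, 120, by = 15)
  grid <- expand.grid(steps = steps, mpa = mpa, vpa = vpa)
  got <- classify_day(grid$steps, grid$mpa, grid$vpa)
  expect_true(all(got %in% 0:4))                  # totality: exactly one level
  want <- mapply(oracle_level, grid$steps, grid$mpa, grid$vpa)
  expect_equal(got, as.integer(want))
})

test_that("classification is monotone in steps and in moderate-equivalent", {
  for (me_mpa in c(0, 20, 60)) {
    lv <- classify_day(seq(0, 20000, by = 250), me_mpa, 0)
    expect_true(all(diff(lv) >= 0))
  }
  for (s in c(5500, 9000, 12000)) {
    lv <- classify_day(rep(s, 121), seq(0, 120, 1), 0)
    expect_true(all(diff(lv) >= 0))
  }
})

test_that("IMA banding partitions the non-negative integers", {
  expect_equal(classify_ima(c(400, 401, 800, 801)),
               c("LPA", "MPA", "MPA", "VPA"))
  bands <- classify_ima(0:2000)
  expect_true(all(bands %in% c("LPA", "MPA", "VPA")))
  expect_equal(sum(bands == "LPA"), 401)   # 0..400
  expect_equal(sum(bands == "MPA"), 400)   # 401..800
  expect_error(classify_ima(-5), "non-negative")
  b <- ima_bands()
  expect_true(all(b$ima_low[-1] == b$ima_high[-3] + 1))  # no gaps/overlap
})

test_that("weight points are twice the level code", {
  expect_equal(level_weight(0:4), c(0, 2, 4, 6, 8))
  expect_equal(activity_levels()$weight_point, 2 * activity_levels()$code)
  expect_error(level_weight(5), "0-4")
})

test_that("weekly pattern vectors apply the day rules element-wise", {
  expect_equal(build_apv(make_days(rep(4000, 7))), rep(0L, 7))
  wk <- make_days(c(11000, 11000, 11000, 13000, 13000, 8000, 13000))
  expect_equal(build_apv(wk), c(3L, 3L, 3L, 4L, 4L, 2L, 4L))
  # definition: element-wise classify_day on a generated mixed week
  d <- synthesize_daily_cohort(cohort_spec(n_participants = 1, n_days = 14,
                                           seed = 4))
  wk2 <- d[1:7, ]
  expect_equal(build_apv(wk2),
               classify_day(wk2$steps, wk2$mpa_s / 60, wk2$vpa_s / 60))
  expect_error(build_apv(make_days(rep(4000, 6))), "7")
  bad <- make_days(rep(4000, 7))
  bad$date[3] <- bad$date[3] + 30
  expect_error(build_apv(bad), "consecutive")
})
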