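test_that("the generator is deterministic and honours the 60-second budget", {
  spec <- cohort_spec(n_participants = 2, n_days = 14, seed = 11,
                      minutes_per_day = 480)
  a <- synthesize_cohort(spec)
  b <- synthesize_cohort(spec)
  expect_identical(a, b)
  budget <- rowSums(a[c("weight_bearing_s", "sedentary_s", "standing_s",
                        "lpa_s", "mpa_s", "vpa_s")])
  expect_true(all(budget == 60))
  expect_true(all(a$ima >= 0) && all(a$steps >= 0))
})

test_that("synthetic days classify to their target level under the day rules", {
  # all mass on level 0: every day must classify sedentary
  spec0 <- cohort_spec(n_participants = 2, n_days = 14, seed = 5,
                       activity_mix = c(1, 0, 0, 0, 0),
                       minutes_per_day = 480)
  d0 <- aggregate_to_daily(synthesize_cohort(spec0))
  expect_true(all(classify_day(d0$steps, d0$mpa_s / 60, d0$vpa_s / 60) == 0))

  # mixed cohort: aggregated days match the recorded targets exactly
  spec <- cohort_spec(n_participants = 3, n_days = 15, seed = 21,
                      minutes_per_day = 480)
  m <- synthesize_cohort(spec)
  d <- aggregate_to_daily(m)
  tgt <- attr(m, "target_level")
  tgt <- tgt[order(tgt$participant, tgt$date), ]
  expect_equal(classify_day(d$steps, d$mpa_s / 60, d$vpa_s / 60), tgt$level)
})

test_that("cohort size and aggregation conservation hold", {
  spec <- cohort_spec(n_participants = 4, n_days = 30, seed = 2,
                      minutes_per_day = 360)
  m <- synthesize_cohort(spec)
  d <- aggregate_to_daily(m)
  expect_equal(nrow(d), 4 * 30)
  expect_equal(sum(d$steps), sum(m$steps))
  expect_equal(sum(d$mpa_s), sum(m$mpa_s))
})

test_that("empirical IMA stays in the dominant type's band almost surely", {
  spec <- cohort_spec(n_participants = 1, n_days = 14, seed = 9,
                      minutes_per_day = 600)
  m <- synthesize_cohort(spec)
  dominant <- apply(m[c("lpa_s", "mpa_s", "vpa_s")], 1, which.max)
  active <- m$lpa_s + m$mpa_s + m$vpa_s > 30
  expect_gt(sum(active), 1000)
  in_band <- classify_ima(m$ima[active]) ==
    c("LPA", "MPA", "VPA")[dominant[active]]
  expect_gte(mean(in_band), 0.99)
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(n_days = 7), "14")
  expect_error(cohort_spec(n_participants = 0), "positive")
  expect_error(cohort_spec(activity_mix = c(1, 1, 0, 0, 0)), "sum to 1")
})

test_that("the daily generator matches the minute generator's label contract", {
  d <- synthesize_daily_cohort(cohort_spec(n_participants = 5, n_days = 20,
                                           seed = 33))
  expect_equal(classify_day(d$steps, d$mpa_s / 60, d$vpa_s / 60), d$level)
  expect_true(all(table(d$level) > 0))  # all five levels present
})
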