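test_that("weekly feature means are plain arithmetic means", {
  wk <- make_days(rep(9000, 7), mpa_s = 1200, vpa_s = 60,
                  sedentary_s = 2000, lpa_s = 5000)
  m <- weekly_feature_means(wk)
  expect_equal(m$mean_steps, 9000)
  expect_equal(m$mean_mpa_s, 1200)
  wk2 <- make_days(c(10000, 12000, 11000, 13000, 12000, 11000, 12942))
  expect_equal(weekly_feature_means(wk2)$mean_steps, 11706)
  z <- make_days(rep(0, 7), sedentary_s = 0, lpa_s = 0)
  expect_true(all(unlist(weekly_feature_means(z)) == 0))
  expect_error(weekly_feature_means(wk[1:6, ]), "7")
})

test_that("similarity score is the APV sum minus the goal sum", {
  expect_equal(similarity_score(c(3, 3, 3, 4, 4, 2, 4), rep(3, 7)), 2L)
  expect_equal(similarity_score(c(0, 0, 0, 0, 0, 1, 0), rep(3, 7)), -20L)
  expect_equal(similarity_score(rep(2, 7), rep(2, 7)), 0L)
  # conservation: sc + sum(gs) == sum(apv)
  set.seed(3)
  for (i in 1:25) {
    apv <- sample(0:4, 7, replace = TRUE)
    gs <- sample(1:4, 7, replace = TRUE)
    expect_equal(similarity_score(apv, gs) + sum(gs), sum(apv))
  }
})

test_that("performance score sums level x weight with weights 0,2,4,6,8", {
  expect_equal(performance_score(c(3, 3, 3, 4, 4, 2, 4)), 158L)
  expect_equal(performance_score(c(1, 1, 3, 2, 1, 1, 1)), 36L)
  expect_equal(performance_score(rep(0, 7)), 0L)
  expect_equal(performance_score(rep(4, 7)), 224L)
  expect_error(performance_score(c(5, 0, 0, 0, 0, 0, 0)), "0-4")
  # algebraic identity oracle: S = 2 * sum(level^2)
  set.seed(8)
  for (i in 1:25) {
    apv <- sample(0:4, 7, replace = TRUE)
    expect_equal(performance_score(apv), as.integer(2 * sum(apv^2)))
  }
})

test_that("mean weekly performance divides by 7 with half-up display", {
  expect_equal(mean_performance(104), 14.9)
  expect_equal(mean_performance(2), 0.3)
  expect_equal(mean_performance(36), 5.1)
  expect_equal(mean_performance(0), 0.0)
  expect_equal(mean_performance(224), 32.0)  # all-level-4 upper bound
  expect_equal(mean_performance(158, digits = NULL), 158 / 7)
})

test_that("cumulative deviation reproduces the reference weekly report", {
  # population SD of the running displayed-mean list, error = sd/sqrt(n)
  expect_equal(cumulative_deviation(22.5), c(sd = 0.0, error = 0.0))
  expect_equal(cumulative_deviation(c(22.5, 14.9)),
               c(sd = 3.8, error = 2.7))
  expect_equal(cumulative_deviation(c(22.5, 14.9, 0.3)),
               c(sd = 9.2, error = 5.3))
  expect_equal(cumulative_deviation(c(22.5, 14.9, 0.3, 5.1)),
               c(sd = 8.6, error = 4.3))
  # permutation invariance and the constant-list degenerate case
  expect_equal(cumulative_deviation(c(0.3, 22.5, 14.9)),
               cumulative_deviation(c(22.5, 14.9, 0.3)))
  expect_equal(cumulative_deviation(rep(11.1, 5)), c(sd = 0, error = 0))
  expect_error(cumulative_deviation(numeric(0)), "non-empty")
})

test_that("weekly summaries assemble consistently", {
  wk <- week_for_apv(c(3, 3, 3, 4, 4, 2, 4))
  s <- weekly_summary(wk, goal_profile(), week_id = 1)
  expect_equal(s$apv, c(3, 3, 3, 4, 4, 2, 4))
  expect_equal(s$sc + sum(s$gs), sum(s$apv))
  expect_equal(s$s_total, 158L)
  expect_equal(s$mean_s, 22.6)  # 158/7 = 22.571, half-up display
  expect_equal(s$sd, 0)
  tab <- weekly_summary_table(list(s))
  expect_equal(tab$sc, 2L)
  expect_equal(tab$apv, "3,3,3,4,4,2,4")
})
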