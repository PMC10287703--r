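p1_day <- function() {
  list(steps = 4649, sedentary_s = 1305, mpa_s = 316, vpa_s = 0)
}

test_that("the catalog assigns every variable to exactly one category", {
  cat_tab <- message_catalog()
  expect_false(anyDuplicated(cat_tab$id) > 0)
  expect_equal(sum(startsWith(cat_tab$id, "A-")), 19)
  expect_true(all(table(cat_tab$category) >= 2))  # exclusive alternatives
  expect_true(all(is.na(cat_tab$template[cat_tab$category == "weather"])))
})

test_that("daily evaluation fires one variable per daily category", {
  goals <- goal_profile()
  expect_setequal(evaluate_daily(p1_day(), goals, level = 0L),
                  c("A-1", "A-7", "A-8", "A-10", "A-15"))
  expect_setequal(evaluate_daily(p1_day(), goals, level = 1L),
                  c("A-2", "A-7", "A-8", "A-10", "A-15"))
  # a day meeting the step, minute and sedentary goals (no sleep data)
  good <- list(steps = 12000, sedentary_s = 20000, mpa_s = 30 * 60,
               vpa_s = 10 * 60)
  fired <- evaluate_daily(good, goals)
  expect_true("A-14" %in% fired)
  expect_false("A-15" %in% fired)
  expect_setequal(fired, c("A-4", "A-7", "A-9", "A-11", "A-14"))
  # the level is computed from the day when not supplied
  expect_true("A-1" %in% evaluate_daily(p1_day(), goals))
  expect_error(evaluate_daily(p1_day(), list(daily_step_goal = 1)),
               "daily_sedentary_goal_s")
})

test_that("weekly evaluation reproduces the worked recommendation set", {
  goals <- goal_profile()
  cur <- list(sc = -20, sd = 9.2)
  prev <- list(sc = -7, sd = 3.8)
  totals <- list(steps = 7 * 4649, mpa_min = 7 * 316 / 60, vpa_min = 0,
                 sedentary_s = 7 * 1305)
  fired <- evaluate_weekly(cur, totals, goals, previous = prev,
                           forecast_steps = 32032)
  expect_setequal(fired, c("A-19", "A-17", "A-13"))
  # all goals met and deviation non-increasing
  good_tot <- list(steps = 80000, mpa_min = 200, vpa_min = 30,
                   sedentary_s = 7 * 20000)
  ok <- evaluate_weekly(list(sc = 2, sd = 1.0), good_tot, goals,
                        previous = list(sc = 1, sd = 2.0),
                        forecast_steps = 75000)
  expect_setequal(ok, c("A-18", "A-16", "A-12"))
  # cold start and missing forecast skip their categories explicitly
  cs <- evaluate_weekly(cur, totals, goals)
  expect_setequal(cs, "A-19")
  expect_setequal(names(attr(cs, "skipped")),
                  c("forecast_trend", "weekly_deviation"))
})

test_that("strict mode keeps the literal deviation operands", {
  goals <- goal_profile()
  totals <- list(steps = 0, mpa_min = 0, vpa_min = 0, sedentary_s = 0)
  # SC = -20 satisfies neither literal operand: no deviation variable fires
  fired <- evaluate_weekly(list(sc = -20, sd = 9.2), totals, goals,
                           previous = list(sc = -7, sd = 3.8),
                           strict = TRUE)
  expect_false(any(c("A-16", "A-17") %in% fired))
})

test_that("per-category exclusivity accepts valid states and names violations", {
  expect_true(check_exclusivity(c("A-1", "A-7", "A-8", "A-10", "A-15"))$ok)
  both <- check_exclusivity(c("A-1", "A-7", "A-8", "A-10", "A-14", "A-15"))
  expect_false(both$ok)
  expect_equal(both$violations, "daily_goal")
  allfalse <- check_exclusivity(character(0))
  expect_false(allfalse$ok)
  expect_true(length(allfalse$violations) >= 8)
  expect_error(check_exclusivity(c("A-1", "B-99")), "unknown")
})

test_that("flipping one goal dimension flips exactly that category", {
  goals <- goal_profile()
  base <- list(steps = 4000, sedentary_s = 40000, mpa_s = 0, vpa_s = 0)
  f0 <- evaluate_daily(base, goals)
  flips <- list(
    steps = list(steps = 12000, sedentary_s = 40000, mpa_s = 0, vpa_s = 0),
    sedentary = list(steps = 4000, sedentary_s = 1000, mpa_s = 0, vpa_s = 0),
    activity_minutes = list(steps = 4000, sedentary_s = 40000,
                            mpa_s = 3600, vpa_s = 0)
  )
  cat_tab <- message_catalog()
  for (nm in names(flips)) {
    f1 <- evaluate_daily(flips[[nm]], goals)
    changed <- cat_tab$category[match(union(setdiff(f0, f1),
                                            setdiff(f1, f0)), cat_tab$id)]
    expect_true(nm %in% changed)
    # only this category plus any dependent level/daily-goal change moved
    expect_true(all(changed %in% c(nm, "level", "daily_goal")))
  }
})

test_that("message rendering substitutes placeholders verbatim", {
  expect_match(render_message("A-8", list(x = 2000, x1 = 70000)),
               "continue 2000 steps more .* 70000 steps")
  expect_match(render_message("A-13", list(N = 3, XX = 1, XY = 2)),
               "Week-3 .* Week-1 and Week-2")
  expect_equal(render_message("A-18"),
               paste("Good work. Please keep it up next week.",
                     "You are active and completed the goal for this week"))
  expect_error(render_message("A-8", list(x = 2000)), "x1")
  expect_error(render_message("W-1"), "no message template")
  expect_error(render_message("A-99"), "unknown")
})
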