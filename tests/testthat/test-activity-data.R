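test_that("minute CSV round trip preserves records and time order", {
  df <- rbind(
    minute_row(time = "08:02:00", sedentary_s = 60, ima = 12),
    minute_row(time = "08:00:00", lpa_s = 60, ima = 300, steps = 40),
    minute_row(time = "08:01:00", mpa_s = 45, standing_s = 15, ima = 500,
               steps = 70)
  )
  path <- write_mox_fixture(df)
  rec <- read_mox_csv(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$time, c("08:00:00", "08:01:00", "08:02:00"))
  # round trip
  p2 <- tempfile(fileext = ".csv")
  write_mox_csv(rec, p2)
  rec2 <- read_mox_csv(p2)
  expect_equal(rec2, rec)
})

test_that("second-budget violations are reported with line numbers", {
  df <- rbind(minute_row(sedentary_s = 60),
              minute_row(time = "08:01:00", sedentary_s = 59))  # sums to 59
  path <- write_mox_fixture(df)
  expect_warning(read_mox_csv(path), "row\\(s\\): 3")
  # a fully sedentary minute passes the budget silently
  expect_silent(read_mox_csv(write_mox_fixture(
    minute_row(sedentary_s = 60))))
})

test_that("format errors name the column or the offending line", {
  df <- minute_row(sedentary_s = 60)
  path <- write_mox_fixture(df)
  txt <- readLines(path)
  writeLines(sub("^Date,", "Datum,", txt), path)
  expect_error(read_mox_csv(path), "Date")

  df2 <- rbind(minute_row(sedentary_s = 60),
               minute_row(time = "08:01:00", sedentary_s = 60))
  p2 <- write_mox_fixture(df2)
  txt <- readLines(p2)
  txt[3] <- sub(",60,", ",sixty,", txt[3])
  writeLines(txt, p2)
  expect_error(read_mox_csv(p2), "line\\(s\\): 3")
})

test_that("daily aggregation sums within dates and splits across dates", {
  two <- rbind(minute_row(time = "08:00:00", sedentary_s = 60, steps = 50),
               minute_row(time = "08:01:00", lpa_s = 60, steps = 70))
  d <- aggregate_to_daily(two)
  expect_equal(nrow(d), 1)
  expect_equal(d$steps, 120)

  spanning <- rbind(two, minute_row(date = "2023-01-02", lpa_s = 60))
  expect_equal(nrow(aggregate_to_daily(spanning)), 2)

  expect_equal(nrow(aggregate_to_daily(two[0, ])), 0)

  # 1440 minutes with lpa_s = 10 each: daily total equals the brute-force sum
  mins <- do.call(rbind, lapply(0:1439, function(i) {
    minute_row(time = sprintf("%02d:%02d:00", i %/% 60, i %% 60),
               lpa_s = 10, sedentary_s = 50)
  }))
  expect_equal(aggregate_to_daily(mins)$lpa_s, sum(rep(10, 1440)))
})

test_that("gap filling is backward for leading gaps, forward elsewhere", {
  expect_equal(fill_missing(c(5, NA, NA, 8)), c(5, 5, 5, 8))
  expect_equal(fill_missing(c(NA, 4, 6)), c(4, 4, 6))
  expect_equal(fill_missing(c(1, 2, 3)), c(1, 2, 3))
  expect_error(fill_missing(c(NA, NA)), "anchor")
  # calendar expansion: a missing day inside the span becomes a filled gap
  filled <- fill_missing(c(10, 30), dates = as.Date(c("2023-01-01",
                                                      "2023-01-03")))
  expect_equal(as.numeric(filled), c(10, 10, 30))
})

test_that("goal profiles read from flat YAML with unknown keys rejected", {
  path <- tempfile(fileext = ".yml")
  writeLines(c("daily_step_goal: 8000", "daily_goal_score: 2"), path)
  gp <- read_goal_profile(path)
  expect_equal(gp$daily_step_goal, 8000)
  expect_equal(gp$weekly_goal_vector, rep(2, 7))
  expect_equal(sum(gp$weekly_goal_vector), 7 * gp$daily_goal_score)
  writeLines("step_target: 1", path)
  expect_error(read_goal_profile(path), "step_target")
})
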