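# Propositional rule base: variables A-1..A-19 grouped into mutually
# exclusive categories, the daily and weekly rule evaluations, the
# per-category exactly-one satisfiability check, and message rendering.

#' Catalog of propositional variables and message templates
#'
#' Nineteen recommendation variables (A-1..A-19) plus the two weather
#' variables that are declared in the schema but never fired (no weather
#' input exists in the pipeline). Each variable belongs to exactly one
#' category; within a category at most one variable may be true at a time.
#' Templates carry `{placeholder}` slots substituted by [render_message()]:
#' `x` step deficit/surplus, `x1` weekly step goal or remainder, `z`
#' sedentary-hour difference, `m`/`n` activity-minute surplus/deficit, `n1`
#' weekly minute goal, `N` current week index, `XX`/`XY` best past weeks,
#' and `X`/`Y`/`Z`/`M`/`NN` the daily overview numbers.
#'
#' @return data.frame with columns `id`, `name`, `category`, `template`.
#' @export
message_catalog <- function() {
  rows <- list(
    c("A-1", "Sedentary", "level",
      "Please continue a light activity (e.g., sports 1-3 days/week, a walking goal of 5000 to 7499 steps/day)"),
    c("A-2", "Low_physically_active", "level",
      "Please continue more activity (e.g., sports 3-5 days/week, a walking goal of 7500-9999 steps/day) OR do a minimum 150-300 min (2.5-5.0 h) of moderate-intensity aerobic exercise or minimum 75-150 min of high-intensity aerobic exercise or do an equivalent combination of moderate and high-intensity activities in a week to stay physically active"),
    c("A-3", "Physically_active", "level",
      "Please continue the same or more activities based on your goal (e.g., sports 3-5 days/week, a walking goal of 7500 to 9000 steps/day)"),
    c("A-4", "Moderate_physically_active", "level",
      "Please continue the same or more activities based on your goal (e.g., sports 3-5 days/week, a walking goal of 10,000 to 12,499 steps/day)"),
    c("A-5", "Vigorous_physically_active", "level",
      "Please continue the same or more activities based on your goal (e.g., sports 5+ days/week, a walking goal of 12,500+ steps/day)"),
    c("A-6", "Sedentary_hour_negative", "sedentary",
      "Please be active for {z} h. more as today you were {z} h. more sedentary beyond your goal"),
    c("A-7", "Sedentary_hour_positive", "sedentary",
      "You were very active today and {z} hr. less sedentary; therefore, you can take that h. of rest tomorrow"),
    c("A-8", "Steps_negative", "steps",
      "Please continue {x} steps more tomorrow to achieve your weekly goal of {x1} steps"),
    c("A-9", "Steps_positive", "steps",
      "You have performed extra {x} steps today beyond your goal; therefore, you can do {x} steps less tomorrow or you can carry out the same pace. You are {x1} step behind to achieve your weekly goal (OR) congratulations! You have achieved your weekly target"),
    c("A-10", "Activity_minute_negative", "activity_minutes",
      "Please continue more activity of {n} min tomorrow to achieve {n1} min of a weekly goal"),
    c("A-11", "Activity_minute_positive", "activity_minutes",
      "You have performed extra {m} minutes of activity today beyond your goal; therefore, you can be {m} mins. of less highly active tomorrow or you can carry out the same pace. You are {n1} mins. behind to achieve your weekly goal (OR) congratulations! You have achieved your weekly target"),
    c("A-12", "Step_forecast_trend_postive", "forecast_trend",
      "Based on your weekly step forecast trend in this Week-{N} you can achieve the step goal"),
    c("A-13", "Step_forecast_trend_negative", "forecast_trend",
      "Based on your weekly step forecast trend in this Week-{N} you cannot achieve the step goal. On Week-{XX} and Week-{XY} weeks, you were very active. Please try to follow similar activity patterns"),
    c("A-14", "Daily_Goal_achieved", "daily_goal",
      "Good work. Please keep it up tomorrow. You are active and completed the goal for today. Overview: You have performed {X} steps today. You slept {Y} h. You were sedentary for {Z} h. You were {M} min medium active. You were {NN} min highly active"),
    c("A-15", "Daily_Goal_not_achieved", "daily_goal",
      "You must improve to meet the daily goal. Please stay active tomorrow. Overview: You have performed {X} steps today. You slept {Y} h. You were sedentary for {Z} h. You were {M} min medium active. You were {NN} minutes highly active"),
    c("A-16", "Weekly_performance_deviation_trend_positive", "weekly_deviation",
      "Congratulations! You have maintained a good weekly activity pattern"),
    c("A-17", "Weekly_performance_deviation_trend_negative", "weekly_deviation",
      "Your weekly activity pattern must be improved"),
    c("A-18", "Weekly_Goal_achieved", "weekly_goal",
      "Good work. Please keep it up next week. You are active and completed the goal for this week"),
    c("A-19", "Weekly_Goal_not_achieved", "weekly_goal",
      "You must improve to meet the weekly goal. Please stay active next week and try to overcome the shortcomings of this week. On Week-{XX} and Week-{XY} weeks, you were very active. Please try to follow similar activity patterns"),
    c("W-1", "Good_weather", "weather", NA),
    c("W-2", "Bad_weather", "weather", NA)
  )
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("id", "name", "category", "template")
  out
}

DAILY_CATEGORIES <- c("level", "sedentary", "steps", "activity_minutes",
                      "daily_goal")
WEEKLY_CATEGORIES <- c("forecast_trend", "weekly_deviation", "weekly_goal")

#' Evaluate the daily rules
#'
#' Fires exactly one variable from each daily category:
#' * level: A-1..A-5 from the day's activity level;
#' * sedentary: A-6 when the sedentary total exceeds the daily goal, else A-7;
#' * steps: A-9 when steps reach the daily goal, else A-8;
#' * activity minutes: A-11 when the moderate minutes reach the daily
#'   moderate goal OR twice the vigorous minutes reach the vigorous goal,
#'   else A-10;
#' * daily goal: A-14 when the step, minute, sedentary and sleep goals all
#'   hold, else A-15. A missing sleep total (this sensor records none) is
#'   treated as satisfying the sleep goal.
#'
#' @param day one daily record: a list or 1-row data.frame with `steps`,
#'   `sedentary_s`, `mpa_s`, `vpa_s` and optionally `sleep_minutes`.
#' @param goals a [goal_profile()]; missing fields raise an error naming the
#'   field.
#' @param level the day's activity level; computed with [classify_day()] if
#'   `NULL`.
#' @return character vector of fired variable ids.
#' @export
evaluate_daily <- function(day, goals, level = NULL) {
  need <- c("daily_step_goal", "daily_sedentary_goal_s", "daily_mpa_goal_min",
            "daily_vpa_goal_min", "daily_sleep_goal_h")
  miss <- need[!need %in% names(goals)]
  if (length(miss)) {
    stop("goal profile is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  day <- as.list(day)
  if (is.null(level)) {
    level <- classify_day(day$steps, day$mpa_s / 60, day$vpa_s / 60)
  }
  mpa_min <- day$mpa_s / 60
  vpa_min <- day$vpa_s / 60

  fired <- sprintf("A-%d", level + 1L)
  fired <- c(fired, if (day$sedentary_s - goals$daily_sedentary_goal_s > 0)
    "A-6" else "A-7")
  steps_ok <- day$steps - goals$daily_step_goal >= 0
  fired <- c(fired, if (steps_ok) "A-9" else "A-8")
  minutes_ok <- (mpa_min - goals$daily_mpa_goal_min >= 0) ||
    (2 * vpa_min - goals$daily_vpa_goal_min >= 0)
  fired <- c(fired, if (minutes_ok) "A-11" else "A-10")
  sleep_ok <- is.null(day$sleep_minutes) || is.na(day$sleep_minutes) ||
    day$sleep_minutes >= goals$daily_sleep_goal_h * 60
  sed_ok <- day$sedentary_s - goals$daily_sedentary_goal_s <= 0
  fired <- c(fired, if (steps_ok && minutes_ok && sleep_ok && sed_ok)
    "A-14" else "A-15")
  fired
}

#' Evaluate the weekly rules
#'
#' Fires one variable from each applicable weekly category:
#' * forecast trend: A-12 when the predicted weekly steps (sum of the 7
#'   forecast points) reach the weekly step goal, else A-13; skipped when no
#'   forecast is supplied;
#' * deviation trend: A-17 when the cumulative deviation rose relative to
#'   the previous week AND the weekly goal was missed (`SC < 0`), else A-16.
#'   This is the minimal reading that reproduces the worked recommendation
#'   sets; the literal printed operand forms (`SC > 0` / `SC == 0`) are kept
#'   behind `strict = TRUE`, under which the category may legitimately fire
#'   nothing. Skipped (cold start) when no previous week exists;
#' * weekly goal: A-18 when the weekly step, minute, sedentary and sleep
#'   totals all meet the weekly goals, else A-19.
#'
#' @param current current-week [weekly_summary()] (needs `sc`, `sd`).
#' @param totals list of weekly totals: `steps`, `mpa_min`, `vpa_min`,
#'   `sedentary_s`, optionally `sleep_minutes`.
#' @param goals a [goal_profile()].
#' @param previous previous-week summary or `NULL` (cold start).
#' @param forecast_steps predicted steps for the coming week (sum of 7
#'   points) or `NULL`.
#' @param strict use the literal printed deviation-rule operands.
#' @return character vector of fired ids; skipped categories are recorded in
#'   the `"skipped"` attribute (`"cold_start"` / `"no_forecast"`).
#' @export
evaluate_weekly <- function(current, totals, goals, previous = NULL,
                            forecast_steps = NULL, strict = FALSE) {
  fired <- character(0)
  skipped <- character(0)

  if (is.null(forecast_steps)) {
    skipped <- c(skipped, forecast_trend = "no_forecast")
  } else {
    fired <- c(fired, if (forecast_steps - goals$weekly_step_goal >= 0)
      "A-12" else "A-13")
  }

  if (is.null(previous)) {
    skipped <- c(skipped, weekly_deviation = "cold_start")
  } else if (strict) {
    if (current$sd > previous$sd && current$sc > 0) fired <- c(fired, "A-17")
    if (current$sd <= previous$sd && current$sc == 0) {
      fired <- c(fired, "A-16")
    }
  } else {
    fired <- c(fired, if (current$sd > previous$sd && current$sc < 0)
      "A-17" else "A-16")
  }

  sleep_ok <- is.null(totals$sleep_minutes) ||
    totals$sleep_minutes >= goals$daily_sleep_goal_h * 60 * 7
  weekly_ok <- (totals$steps - goals$weekly_step_goal >= 0) &&
    ((totals$mpa_min - goals$weekly_mpa_goal_min >= 0) ||
       (2 * totals$vpa_min - goals$weekly_vpa_goal_min >= 0)) &&
    sleep_ok &&
    (totals$sedentary_s - 7 * goals$daily_sedentary_goal_s <= 0)
  fired <- c(fired, if (weekly_ok) "A-18" else "A-19")

  attr(fired, "skipped") <- skipped
  fired
}

#' Check per-category exclusivity of a propositional state
#'
#' The satisfiability guard over the rule base: within every applicable
#' category exactly one variable may be true, so no two "once a day" (or
#' once a week) messages of the same kind fire together. A category is
#' applicable when any of its variables is true; if nothing at all is true,
#' every non-weather category counts as violated.
#'
#' @param state either a character vector of fired variable ids or a named
#'   logical vector over variable ids.
#' @param categories optional character vector restricting the applicable
#'   categories.
#' @return list with `ok` (logical) and `violations` (offending category
#'   names).
#' @export
check_exclusivity <- function(state, categories = NULL) {
  cat_tab <- message_catalog()
  if (is.logical(state)) {
    ids <- names(state)[state]
    unknown <- setdiff(names(state), cat_tab$id)
  } else {
    ids <- as.character(state)
    unknown <- setdiff(ids, cat_tab$id)
  }
  if (length(unknown)) {
    stop("unknown propositional variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(cat_tab$category[match(ids, cat_tab$id)],
                         levels = unique(cat_tab$category)))
  if (is.null(categories)) {
    categories <- if (length(ids)) names(counts)[counts > 0] else
      setdiff(unique(cat_tab$category), "weather")
  }
  bad <- categories[counts[categories] != 1]
  list(ok = length(bad) == 0, violations = as.character(bad))
}

#' Render a recommendation message
#'
#' Substitutes the `{placeholder}` slots of a variable's template from a
#' named value list; numeric values are formatted as integers (half-up).
#' A placeholder with no supplied value raises an error naming it.
#'
#' @param id variable id (e.g. `"A-8"`).
#' @param values named list of placeholder values.
#' @return the rendered message text.
#' @examples
#' render_message("A-8", list(x = 2000, x1 = 70000))
#' @export
render_message <- function(id, values = list()) {
  cat_tab <- message_catalog()
  row <- match(id, cat_tab$id)
  if (is.na(row)) stop("unknown variable id: ", id, call. = FALSE)
  template <- cat_tab$template[row]
  if (is.na(template)) {
    stop("variable ", id, " has no message template", call. = FALSE)
  }
  slots <- unique(regmatches(template,
                             gregexpr("\\{[A-Za-z0-9]+\\}", template))[[1]])
  for (s in slots) {
    key <- substr(s, 2, nchar(s) - 1)
    if (!key %in% names(values)) {
      stop("missing value for placeholder '", key, "' in ", id,
           call. = FALSE)
    }
    v <- values[[key]]
    if (is.numeric(v)) v <- format(round_half_up(v), scientific = FALSE)
    template <- gsub(s, v, template, fixed = TRUE)
  }
  template
}
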