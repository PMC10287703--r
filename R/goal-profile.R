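# Goal profiles: per-person activity targets against which the rule base
# compares daily and weekly achievements. Defaults follow the WHO guidance
# for adults (150-300 min/week of moderate activity, one vigorous minute
# counting as two moderate minutes) and the common 10000 steps/day target.

#' Construct a goal profile
#'
#' Bundles the daily and weekly targets used by the recommendation rules.
#' Defaults are the documented WHO-style profile: 10000 steps/day (70000 per
#' week), 21.45 moderate minutes/day (150 per week divided over 7 days) with
#' the vigorous target at half that (moderate time = 2 x vigorous time),
#' 8 h/day sedentary budget, 8 h sleep, and a daily goal score of 3 giving a
#' uniform weekly goal vector.
#'
#' @param daily_step_goal steps per day.
#' @param weekly_step_goal steps per week.
#' @param daily_mpa_goal_min,daily_vpa_goal_min moderate / vigorous minutes
#'   per day.
#' @param weekly_mpa_goal_min,weekly_vpa_goal_min moderate / vigorous minutes
#'   per week (the moderate default must sit in the WHO 150-300 band).
#' @param daily_sedentary_goal_s sedentary budget per day, seconds.
#' @param daily_sleep_goal_h sleep target per day, hours.
#' @param daily_goal_score target activity-level score per day (default 3).
#' @param weekly_goal_vector 7 daily goal scores.
#' @return an object of class `goal_profile` (a named list).
#' @export
goal_profile <- function(daily_step_goal = 10000,
                         weekly_step_goal = 7 * daily_step_goal,
                         daily_mpa_goal_min = 21.45,
                         daily_vpa_goal_min = daily_mpa_goal_min / 2,
                         weekly_mpa_goal_min = 150,
                         weekly_vpa_goal_min = weekly_mpa_goal_min / 2,
                         daily_sedentary_goal_s = 8 * 3600,
                         daily_sleep_goal_h = 8,
                         daily_goal_score = 3,
                         weekly_goal_vector = rep(daily_goal_score, 7)) {
  check_length(weekly_goal_vector, 7, "weekly_goal_vector")
  for (f in c("daily_step_goal", "weekly_step_goal", "daily_mpa_goal_min",
              "daily_vpa_goal_min", "weekly_mpa_goal_min",
              "weekly_vpa_goal_min", "daily_sedentary_goal_s",
              "daily_sleep_goal_h", "daily_goal_score")) {
    check_nonneg(get(f), f)
  }
  structure(list(
    daily_step_goal = daily_step_goal,
    weekly_step_goal = weekly_step_goal,
    daily_mpa_goal_min = daily_mpa_goal_min,
    daily_vpa_goal_min = daily_vpa_goal_min,
    weekly_mpa_goal_min = weekly_mpa_goal_min,
    weekly_vpa_goal_min = weekly_vpa_goal_min,
    daily_sedentary_goal_s = daily_sedentary_goal_s,
    daily_sleep_goal_h = daily_sleep_goal_h,
    daily_goal_score = daily_goal_score,
    weekly_goal_vector = weekly_goal_vector
  ), class = "goal_profile")
}

#' Read a goal profile from a flat key:value YAML file
#'
#' Unknown keys raise an error naming the key; omitted keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return a `goal_profile`.
#' @export
read_goal_profile <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(goal_profile))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown goal profile key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(goal_profile, vals)
}

#' @export
print.goal_profile <- function(x, ...) {
  cat("Goal profile:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(x[[nm]], collapse = " ")))
  }
  invisible(x)
}
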