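# Bespoke weekly performance statistics: feature means, activity pattern
# vector (APV), similarity score, weighted performance score, weekly mean
# score, and the cumulative deviation of weekly means with its error.

#' Weekly means of the activity features
#'
#' Arithmetic means over a 7-day window of sedentary, LPA, MPA and VPA
#' seconds and of daily steps.
#'
#' @param week daily data.frame with exactly 7 rows.
#' @return named list: `mean_sedentary_s`, `mean_lpa_s`, `mean_mpa_s`,
#'   `mean_vpa_s`, `mean_steps`.
#' @export
weekly_feature_means <- function(week) {
  if (!is.data.frame(week) || nrow(week) != 7) {
    stop("`week` must contain exactly 7 daily records", call. = FALSE)
  }
  list(mean_sedentary_s = mean(week$sedentary_s),
       mean_lpa_s = mean(week$lpa_s),
       mean_mpa_s = mean(week$mpa_s),
       mean_vpa_s = mean(week$vpa_s),
       mean_steps = mean(week$steps))
}

#' Weekly similarity score
#'
#' `SC = sum(APV) - sum(goal scores)`; `SC >= 0` means the weekly goal was
#' achieved.
#'
#' @param apv 7 daily activity-level codes.
#' @param gs 7 daily goal scores.
#' @return integer similarity score.
#' @examples
#' similarity_score(c(3, 3, 3, 4, 4, 2, 4), rep(3, 7))  # +2
#' @export
similarity_score <- function(apv, gs) {
  check_length(apv, 7, "apv")
  check_length(gs, 7, "gs")
  as.integer(sum(apv) - sum(gs))
}

#' Weekly weighted performance score
#'
#' `S = sum over days of level x weight point`, with the non-negative weight
#' set \{0, 2, 4, 6, 8\} for levels 0-4 (weight = 2 x level, so
#' `S = 2 * sum(level^2)`). Range 0 (all-sedentary week) to 224 (all level 4).
#'
#' @param apv 7 daily level codes in 0-4.
#' @return integer performance score.
#' @examples
#' performance_score(c(3, 3, 3, 4, 4, 2, 4))  # 158
#' @export
performance_score <- function(apv) {
  check_length(apv, 7, "apv")
  as.integer(sum(apv * level_weight(apv)))
}

#' Weekly mean performance
#'
#' `S / 7`, displayed to one decimal with half-up rounding. Set
#' `digits = NULL` for the unrounded value.
#'
#' @param s_total weekly performance score (>= 0).
#' @param digits decimals for display rounding (default 1); `NULL` to skip.
#' @return mean weekly score (bounded by 32 for an all-level-4 week).
#' @export
mean_performance <- function(s_total, digits = 1) {
  check_nonneg(s_total, "s_total")
  m <- s_total / 7
  if (is.null(digits)) m else round_half_up(m, digits)
}

#' Cumulative deviation of weekly mean scores
#'
#' Population standard deviation of the weekly mean-score list accumulated
#' from week 1 up to the current week, with its error `sd / sqrt(n)`; both
#' are displayed to one decimal (half-up). Permutation-invariant in the list
#' and 0 for any constant list.
#'
#' @param mean_s_history numeric vector of weekly mean scores so far
#'   (non-empty).
#' @return named numeric vector `c(sd = ..., error = ...)`.
#' @examples
#' cumulative_deviation(c(22.5, 14.9))  # sd 3.8, error 2.7
#' @export
cumulative_deviation <- function(mean_s_history) {
  if (length(mean_s_history) == 0) {
    stop("`mean_s_history` must be non-empty", call. = FALSE)
  }
  x <- as.numeric(mean_s_history)
  s <- sqrt(mean((x - mean(x))^2))
  c(sd = round_half_up(s, 1),
    error = round_half_up(s / sqrt(length(x)), 1))
}

#' Summarise one week of daily activity
#'
#' Computes the full weekly summary row: feature means, APV, goal scores,
#' similarity score, performance score, weekly mean score and the cumulative
#' deviation over all weeks seen so far. The deviation is taken over the
#' one-decimal displayed weekly means, matching how the weekly report is
#' read.
#'
#' @param week daily data.frame with exactly 7 consecutive-date rows.
#' @param goals a [goal_profile()].
#' @param week_id week index (>= 1).
#' @param mean_s_history displayed mean scores of the preceding weeks
#'   (possibly empty).
#' @return a `weekly_summary` list.
#' @export
weekly_summary <- function(week, goals = goal_profile(), week_id = 1,
                           mean_s_history = numeric(0)) {
  apv <- build_apv(week)
  gs <- goals$weekly_goal_vector
  s_total <- performance_score(apv)
  mean_s <- mean_performance(s_total)
  dev <- cumulative_deviation(c(mean_s_history, mean_s))
  structure(c(
    list(week_id = week_id),
    weekly_feature_means(week),
    list(apv = apv, gs = gs,
         sc = similarity_score(apv, gs),
         s_total = s_total, mean_s = mean_s,
         sd = unname(dev["sd"]), sd_error = unname(dev["error"]))
  ), class = "weekly_summary")
}

#' @export
print.weekly_summary <- function(x, ...) {
  cat(sprintf("Week %d\n", x$week_id))
  cat(sprintf("  mean sedentary %.1f s, LPA %.1f s, MPA %.1f s, VPA %.1f s, steps %.0f\n",
              x$mean_sedentary_s, x$mean_lpa_s, x$mean_mpa_s, x$mean_vpa_s,
              x$mean_steps))
  cat("  APV [", paste(x$apv, collapse = ", "), "]  GS [",
      paste(x$gs, collapse = ", "), "]\n")
  cat(sprintf("  SC %+d  S %d  mean S %.1f  SD %.1f (Error: +/- %.1f)\n",
              x$sc, x$s_total, x$mean_s, x$sd, x$sd_error))
  invisible(x)
}

#' Serialise weekly summaries to a data.frame / CSV row set
#'
#' @param summaries list of `weekly_summary` objects.
#' @return data.frame with one row per week (APV and GS as comma-joined
#'   strings).
#' @export
weekly_summary_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(week_id = s$week_id,
               mean_sedentary_s = s$mean_sedentary_s,
               mean_lpa_s = s$mean_lpa_s, mean_mpa_s = s$mean_mpa_s,
               mean_vpa_s = s$mean_vpa_s, mean_steps = s$mean_steps,
               apv = paste(s$apv, collapse = ","),
               gs = paste(s$gs, collapse = ","),
               sc = s$sc, s_total = s$s_total, mean_s = s$mean_s,
               sd = s$sd, sd_error = s$sd_error,
               stringsAsFactors = FALSE)
  }))
}
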