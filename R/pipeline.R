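# End-to-end orchestration: for every participant and day, classify and fire
# the daily rules; at every week boundary past the two-week cold start,
# compute the weekly statistics, retrain the step forecaster on the full
# history, build the interval table, fire the weekly rules, and annotate
# everything into the knowledge base. The week-boundary pass re-reads the
# whole history accumulated so far (statistics, forecaster training and
# best-week search all scan it), so total work grows quadratically with the
# number of recorded days.

daily_placeholders <- function(day, goals) {
  day <- as.list(day)
  mpa_min <- day$mpa_s / 60
  vpa_min <- day$vpa_s / 60
  sleep_h <- if (is.null(day$sleep_minutes) || is.na(day$sleep_minutes)) 0
    else day$sleep_minutes / 60
  list(
    x = abs(day$steps - goals$daily_step_goal),
    x1 = goals$weekly_step_goal,
    z = abs(day$sedentary_s - goals$daily_sedentary_goal_s) / 3600,
    m = max(mpa_min - goals$daily_mpa_goal_min,
            2 * vpa_min - goals$daily_vpa_goal_min, 0),
    n = max(goals$daily_mpa_goal_min - mpa_min, 0),
    n1 = goals$weekly_mpa_goal_min,
    X = day$steps, Y = sleep_h, Z = day$sedentary_s / 3600,
    M = mpa_min, NN = vpa_min
  )
}

weekly_placeholders <- function(week_id, best_weeks, goals) {
  list(N = week_id,
       XX = if (length(best_weeks) >= 1) best_weeks[1] else week_id,
       XY = if (length(best_weeks) >= 2) best_weeks[2] else week_id,
       x1 = goals$weekly_step_goal, n1 = goals$weekly_mpa_goal_min)
}

#' Run the full recommendation pipeline
#'
#' Orchestrates classification, weekly statistics, forecasting, interval
#' prediction and rule evaluation over a cohort of daily records.
#' Participants with fewer than 14 days are skipped with a logged reason
#' (two observed weeks are required before model-driven recommendations
#' start); weekly rule evaluation therefore begins at week 3, while weekly
#' statistics accumulate from week 1.
#'
#' @param daily cohort daily data.frame (`participant`, `date`, `steps`,
#'   `sedentary_s`, `lpa_s`, `mpa_s`, `vpa_s`, optional `sleep_minutes`);
#'   a missing `participant` column is treated as one participant.
#' @param goals a [goal_profile()].
#' @param forecaster `"cnn"` for the convolutional forecaster or `"naive"`
#'   for the last-value forecast (useful for quick runs).
#' @param fc_config a [forecaster_config()] (used when `forecaster="cnn"`).
#' @param coverage interval coverage level (see [coverage_constant()]).
#' @param seed integer seed controlling forecaster training.
#' @param strict literal deviation-rule operands (see [evaluate_weekly()]).
#' @return list with `daily_log`, `weekly_log` (data.frames of fired
#'   variables and rendered messages), `weekly_summaries`, `intervals`,
#'   `skipped`, `kb` (the populated knowledge base) and `pairwise_ops`
#'   (history-scan work counter).
#' @export
run_pipeline <- function(daily, goals = goal_profile(),
                         forecaster = c("cnn", "naive"),
                         fc_config = forecaster_config(),
                         coverage = 0.80, seed = 1, strict = FALSE) {
  forecaster <- match.arg(forecaster)
  if (!"participant" %in% names(daily)) daily$participant <- "P-1"
  cc <- coverage_constant(coverage)
  kb <- kb_new()
  daily_log <- list()
  weekly_log <- list()
  summaries <- list()
  intervals <- list()
  skipped <- list()
  pairwise_ops <- 0

  for (p in unique(daily$participant)) {
    d <- daily[daily$participant == p, , drop = FALSE]
    d <- d[order(as.Date(d$date)), , drop = FALSE]
    if (nrow(d) < 14) {
      skipped[[p]] <- sprintf("%s: only %d day(s) of data (need >= 14)",
                              p, nrow(d))
      next
    }
    kb <- kb_add_participant(kb, p)

    # daily pass
    lvls <- classify_day(d$steps, d$mpa_s / 60, d$vpa_s / 60)
    for (i in seq_len(nrow(d))) {
      day <- d[i, ]
      fired <- evaluate_daily(day, goals, level = lvls[i])
      ph <- daily_placeholders(day, goals)
      kb <- kb_add_level(kb, p, day$date, lvls[i])
      for (v in fired) {
        msg <- render_message(v, ph)
        kb <- kb_add_recommendation(kb, p, day$date, v, msg)
        daily_log[[length(daily_log) + 1]] <- data.frame(
          participant = p, date = as.Date(day$date), level = lvls[i],
          variable = v, message = msg, stringsAsFactors = FALSE)
      }
    }

    # weekly pass
    n_weeks <- nrow(d) %/% 7
    hist_means <- numeric(0)
    psum <- vector("list", n_weeks)
    for (w in seq_len(n_weeks)) {
      week <- d[((w - 1) * 7 + 1):(w * 7), ]
      psum[[w]] <- weekly_summary(week, goals, week_id = w,
                                  mean_s_history = hist_means)
      hist_means <- c(hist_means, psum[[w]]$mean_s)
      for (nm in c("sc", "s_total", "mean_s", "sd")) {
        kb <- kb_add_stat(kb, p, w, nm, psum[[w]][[nm]])
      }
      if (w < 3) next  # cold start: two observed weeks first

      history <- d$steps[seq_len(w * 7)]
      pairwise_ops <- pairwise_ops + length(history) + (w - 1)
      points <- if (forecaster == "cnn") {
        model <- train_forecaster(history, fc_config, seed = seed)
        forecast_horizon(model, history, 7)
      } else {
        rep(tail(history, 1), 7)
      }
      sig <- naive_residual_sd(history)
      tab <- weekly_interval_table(points, cc, sig)
      tab$participant <- p
      tab$week <- w
      intervals[[length(intervals) + 1]] <- tab
      wk_date <- as.Date(d$date[w * 7])
      for (r in seq_len(7)) {
        kb <- kb_add_prediction(kb, p, wk_date, r, tab$point[r],
                                tab$lower[r], tab$upper[r])
      }

      totals <- list(steps = sum(week$steps),
                     mpa_min = sum(week$mpa_s) / 60,
                     vpa_min = sum(week$vpa_s) / 60,
                     sedentary_s = sum(week$sedentary_s),
                     sleep_minutes = if ("sleep_minutes" %in% names(week))
                       sum(week$sleep_minutes) else NULL)
      best <- order(vapply(psum[seq_len(w)], `[[`, 0, "mean_s"),
                    decreasing = TRUE)
      fired <- evaluate_weekly(psum[[w]], totals, goals,
                               previous = psum[[w - 1]],
                               forecast_steps = sum(points),
                               strict = strict)
      ph <- weekly_placeholders(w, setdiff(best, w)[1:2], goals)
      for (v in fired) {
        msg <- render_message(v, ph)
        kb <- kb_add_recommendation(kb, p, wk_date, v, msg)
        weekly_log[[length(weekly_log) + 1]] <- data.frame(
          participant = p, week = w, date = wk_date, variable = v,
          message = msg, stringsAsFactors = FALSE)
      }
    }
    summaries[[p]] <- psum
  }

  list(daily_log = do.call(rbind, daily_log),
       weekly_log = do.call(rbind, weekly_log),
       weekly_summaries = summaries,
       intervals = if (length(intervals)) do.call(rbind, intervals),
       skipped = unlist(skipped),
       kb = kb,
       pairwise_ops = pairwise_ops)
}

#' Write a recommendation log as JSON lines
#'
#' One JSON object per fired message: participant, date, variable id and the
#' rendered text.
#'
#' @param log `daily_log` or `weekly_log` from [run_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recommendation_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}
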