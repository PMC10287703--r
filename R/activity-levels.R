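#' Activity-level codes, labels and weight points
#'
#' The five WHO-derived daily activity levels. Each level code carries a
#' non-negative weight point used by the weekly performance score; the weight
#' is always twice the code.
#'
#' @return a data.frame with columns `code` (0-4), `label`, `weight_point`
#'   (0, 2, 4, 6, 8).
#' @export
activity_levels <- function() {
  data.frame(
    code = 0:4,
    label = c("Sedentary", "Low physical active", "Active",
              "Medium physical active", "High physical active"),
    weight_point = seq(0, 8, by = 2),
    stringsAsFactors = FALSE
  )
}

#' Weight point of an activity level
#'
#' @param code integer vector of level codes in 0-4.
#' @return weight points (2 x code).
#' @export
level_weight <- function(code) {
  if (any(is.na(code)) || any(code != as.integer(code)) ||
      any(code < 0 | code > 4)) {
    stop("level codes must be integers in 0-4", call. = FALSE)
  }
  2 * as.integer(code)
}

#' Weekly moderate-equivalent minutes
#'
#' Converts daily moderate (MPA) and vigorous (VPA) activity minutes to the
#' weekly moderate-equivalent total used by the level rules: one vigorous
#' minute counts as two moderate minutes, and the daily equivalent is scaled
#' to a week, i.e. `(2 * vpa_min + mpa_min) * 7`.
#'
#' @param mpa_min daily moderate-activity minutes (>= 0).
#' @param vpa_min daily vigorous-activity minutes (>= 0).
#' @return weekly moderate-equivalent minutes.
#' @examples
#' moderate_equivalent_weekly(10, 5)  # 140
#' @export
moderate_equivalent_weekly <- function(mpa_min, vpa_min) {
  check_nonneg(mpa_min, "mpa_min")
  check_nonneg(vpa_min, "vpa_min")
  (2 * vpa_min + mpa_min) * 7
}

#' Classify a day into an activity level
#'
#' Deterministic WHO-derived classification of a day from its step count and
#' moderate/vigorous minutes. Each level is defined by a step band or a weekly
#' moderate-equivalent (ME) band (the ME disjuncts apply only when steps
#' exceed 4999):
#'
#' | level | step band       | weekly ME band |
#' |-------|-----------------|----------------|
#' | 0     | < 5000          | (any)          |
#' | 1     | 5000-7499       | 90-209         |
#' | 2     | 7500-9999       | 210-299        |
#' | 3     | 10000-12499     | 300-359        |
#' | 4     | >= 12500        | >= 360         |
#'
#' The step and ME bands can disagree (e.g. 11000 steps with ME 140 satisfies
#' the level-3 step band and the level-1 ME band); the classifier returns the
#' highest attained level, which keeps it total, deterministic and monotone in
#' both steps and ME.
#'
#' @param steps daily step count (>= 0).
#' @param mpa_min daily moderate-activity minutes.
#' @param vpa_min daily vigorous-activity minutes.
#' @return integer level codes in 0-4 (vectorised).
#' @examples
#' classify_day(4000, 60, 30)    # 0: under 5000 steps is always sedentary
#' classify_day(11000, 10, 5)    # 3: step band wins over the ME band
#' classify_day(5000, 30, 15)    # 4: weekly ME 420 >= 360
#' @export
classify_day <- function(steps, mpa_min = 0, vpa_min = 0) {
  check_nonneg(steps, "steps")
  n <- max(length(steps), length(mpa_min), length(vpa_min))
  steps <- rep_len(steps, n)
  mpa_min <- rep_len(mpa_min, n)
  vpa_min <- rep_len(vpa_min, n)
  me <- moderate_equivalent_weekly(mpa_min, vpa_min)
  lvl_step <- findInterval(steps, c(5000, 7500, 10000, 12500))
  lvl_me <- findInterval(me, c(90, 210, 300, 360))
  lvl_me[steps <= 4999] <- 0L
  as.integer(pmax(lvl_step, lvl_me))
}

#' Band a per-minute activity intensity (IMA) into an activity type
#'
#' The sensor's per-minute activity-intensity count partitions into low
#' (0-400), moderate (401-800) and vigorous (>= 801) physical activity.
#'
#' @param ima non-negative integer intensity counts.
#' @return character vector in `c("LPA", "MPA", "VPA")`.
#' @examples
#' classify_ima(c(400, 401, 801))
#' @export
classify_ima <- function(ima) {
  check_nonneg(ima, "ima")
  c("LPA", "MPA", "VPA")[findInterval(ima, c(401, 801)) + 1L]
}

#' IMA bands per activity type
#'
#' @return data.frame with columns `type`, `ima_low`, `ima_high`
#'   (`Inf` for the unbounded vigorous band).
#' @export
ima_bands <- function() {
  data.frame(type = c("LPA", "MPA", "VPA"),
             ima_low = c(0, 401, 801),
             ima_high = c(400, 800, Inf),
             stringsAsFactors = FALSE)
}

#' Build a weekly activity pattern vector (APV)
#'
#' Applies [classify_day()] to each of seven consecutive daily records,
#' preserving order.
#'
#' @param week a daily-activity data.frame (as from [aggregate_to_daily()])
#'   with exactly 7 rows on consecutive dates; seconds columns are converted
#'   to minutes at this boundary.
#' @return integer vector of 7 level codes.
#' @export
build_apv <- function(week) {
  if (!is.data.frame(week) || nrow(week) != 7) {
    stop("`week` must be a data.frame with exactly 7 daily records",
         call. = FALSE)
  }
  d <- as.Date(week$date)
  if (any(diff(d) != 1)) {
    stop("`week` dates must be consecutive calendar days", call. = FALSE)
  }
  classify_day(week$steps, week$mpa_s / 60, week$vpa_s / 60)
}
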