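# Seeded synthetic cohort generator. Emulates minute-epoch output of a
# MOX2-5-class accelerometer: every minute's six second-budget fields sum to
# 60 s, per-minute IMA is drawn from the intensity band of the minute's
# dominant activity type (with a small documented boundary-noise
# probability), and each synthetic day is constructed to classify exactly to
# its target activity level under the deterministic day rules.

#' Specify a synthetic cohort
#'
#' @param n_participants number of participants (> 0).
#' @param n_days days of recording per participant (>= 14; the pipeline's
#'   cold-start window is two weeks).
#' @param seed integer random seed; the same spec generates byte-identical
#'   output.
#' @param activity_mix length-5 probability vector over target daily activity
#'   levels 0-4 (must sum to 1).
#' @param minutes_per_day recorded minutes per day (300-1440).
#' @param lpa_minutes_range length-2 integer range of daily light-activity
#'   minutes.
#' @param ima_jitter probability that an active minute's IMA is drawn just
#'   outside its nominal band, emulating sensor boundary noise.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 16, n_days = 30, seed = 1,
                        activity_mix = c(0.35, 0.25, 0.15, 0.15, 0.10),
                        minutes_per_day = 1440,
                        lpa_minutes_range = c(40, 150),
                        ima_jitter = 0.005) {
  if (n_participants < 1 || n_days < 1) {
    stop("`n_participants` and `n_days` must be positive", call. = FALSE)
  }
  if (n_days < 14) {
    stop("`n_days` must be >= 14 (two-week cold-start window)", call. = FALSE)
  }
  check_length(activity_mix, 5, "activity_mix")
  check_nonneg(activity_mix, "activity_mix")
  if (abs(sum(activity_mix) - 1) > 1e-8) {
    stop("`activity_mix` weights must sum to 1", call. = FALSE)
  }
  if (minutes_per_day < 300 || minutes_per_day > 1440) {
    stop("`minutes_per_day` must lie in [300, 1440]", call. = FALSE)
  }
  structure(list(n_participants = as.integer(n_participants),
                 n_days = as.integer(n_days), seed = as.integer(seed),
                 activity_mix = activity_mix,
                 minutes_per_day = as.integer(minutes_per_day),
                 lpa_minutes_range = as.integer(lpa_minutes_range),
                 ima_jitter = ima_jitter),
            class = "cohort_spec")
}

#' Read a cohort spec from a flat key:value YAML file
#'
#' @param path YAML file path.
#' @return a `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cohort_spec))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown cohort spec key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(cohort_spec, vals)
}

# step bands (per level) and daily moderate-equivalent bands such that the
# weekly moderate-equivalent (daily x 7) falls strictly inside the level's
# rule band even after integer arithmetic
.step_bands <- list(c(800L, 4999L), c(5000L, 7499L), c(7500L, 9999L),
                    c(10000L, 12499L), c(12500L, 17500L))
.me_daily_bands <- list(0:12, 13:29, 30:42, 43:51, 52:70)

# draw the day-level quantities for one day at a target level
draw_day <- function(lvl, spec) {
  sb <- .step_bands[[lvl + 1L]]
  steps <- sample(sb[1]:sb[2], 1L)
  me_lvl <- sample.int(lvl + 1L, 1L) - 1L     # ME band never above target
  d <- .me_daily_bands[[me_lvl + 1L]]
  d <- if (length(d) == 1L) d else sample(d, 1L)
  vpa_min <- sample.int(d %/% 3L + 1L, 1L) - 1L
  mpa_min <- d - 2L * vpa_min
  r <- spec$lpa_minutes_range
  lpa_min <- sample(r[1]:r[2], 1L)
  list(steps = steps, mpa_min = mpa_min, vpa_min = vpa_min,
       lpa_min = lpa_min)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic minute-level cohort
#'
#' For every participant and day a target activity level is drawn from
#' `activity_mix`; daily steps and moderate/vigorous minutes are then drawn
#' inside that level's rule bands (so the aggregated day classifies exactly to
#' its target under [classify_day()]), and expanded into minute records.
#' Active minutes carry 60 s of their own type; sedentary minutes split their
#' budget between sitting and standing so mixed second budgets occur. Daily
#' steps are distributed over minutes by a multinomial draw whose rates scale
#' with the minute's active intensity, which conserves the daily total
#' exactly.
#'
#' @param spec a [cohort_spec()].
#' @return a minute-record data.frame with a leading `participant` column and
#'   a `target_level` attribute (data.frame of participant, date, level).
#' @export
synthesize_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    days <- synthesize_daily_plan(spec)
    chunks <- vector("list", nrow(days))
    for (i in seq_len(nrow(days))) {
      chunks[[i]] <- expand_day_minutes(days[i, ], spec)
    }
    out <- do.call(rbind, chunks)
    rownames(out) <- NULL
    attr(out, "target_level") <-
      days[c("participant", "date", "level")]
    out
  })
}

# day-level plan shared by the minute and daily generators (RNG already seeded)
synthesize_daily_plan <- function(spec) {
  grid <- expand.grid(day = seq_len(spec$n_days),
                      participant = seq_len(spec$n_participants))
  n <- nrow(grid)
  lvl <- sample(0:4, n, replace = TRUE, prob = spec$activity_mix)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    q <- draw_day(lvl[i], spec)
    rows[[i]] <- data.frame(
      participant = sprintf("P-%d", grid$participant[i]),
      date = as.Date("2023-01-01") + grid$day[i] - 1L,
      level = lvl[i], steps = q$steps, mpa_min = q$mpa_min,
      vpa_min = q$vpa_min, lpa_min = q$lpa_min,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# expand one planned day into minute records (RNG already seeded)
expand_day_minutes <- function(day, spec) {
  mpd <- spec$minutes_per_day
  active <- day$vpa_min + day$mpa_min + day$lpa_min
  rest <- mpd - active
  split <- rmultinom(1, rest, c(sedentary = 0.80, standing = 0.12,
                                weight_bearing = 0.08))[, 1]
  type <- sample(rep(c("VPA", "MPA", "LPA", "sedentary", "standing",
                       "weight_bearing"),
                     c(day$vpa_min, day$mpa_min, day$lpa_min, split)))
  n <- length(type)
  sec <- matrix(0, n, 6,
                dimnames = list(NULL, c("weight_bearing_s", "sedentary_s",
                                        "standing_s", "lpa_s", "mpa_s",
                                        "vpa_s")))
  sec[type == "VPA", "vpa_s"] <- 60
  sec[type == "MPA", "mpa_s"] <- 60
  sec[type == "LPA", "lpa_s"] <- 60
  sec[type == "standing", "standing_s"] <- 60
  sec[type == "weight_bearing", "weight_bearing_s"] <- 60
  is_sed <- type == "sedentary"
  if (any(is_sed)) {
    sed <- sample(45:60, sum(is_sed), replace = TRUE)
    sec[is_sed, "sedentary_s"] <- sed
    sec[is_sed, "standing_s"] <- 60 - sed
  }

  ima <- draw_ima(type, spec$ima_jitter)
  w <- c(VPA = 6, MPA = 4, LPA = 2, standing = 0.3, weight_bearing = 0.3,
         sedentary = 0.02)[type]
  steps_min <- as.integer(rmultinom(1, day$steps, w)[, 1])
  start <- if (mpd == 1440L) 0L else min(420L, 1440L - mpd)
  idx <- start + seq_len(n) - 1L
  data.frame(
    participant = day$participant,
    date = day$date,
    time = sprintf("%02d:%02d:00", idx %/% 60L, idx %% 60L),
    upload_status = sample(c("H", "L"), n, replace = TRUE,
                           prob = c(0.98, 0.02)),
    ima = ima,
    weight_bearing_s = sec[, "weight_bearing_s"],
    sedentary_s = sec[, "sedentary_s"],
    standing_s = sec[, "standing_s"],
    lpa_s = sec[, "lpa_s"],
    mpa_s = sec[, "mpa_s"],
    vpa_s = sec[, "vpa_s"],
    steps = steps_min,
    stringsAsFactors = FALSE)
}

# IMA draw per minute: in the dominant type's band, with probability
# `jitter` an active minute lands just across a band boundary
draw_ima <- function(type, jitter) {
  n <- length(type)
  ima <- integer(n)
  ima[type == "LPA"] <- sample(30:400, sum(type == "LPA"), replace = TRUE)
  ima[type == "MPA"] <- sample(401:800, sum(type == "MPA"), replace = TRUE)
  ima[type == "VPA"] <- sample(801:1500, sum(type == "VPA"), replace = TRUE)
  ima[type == "sedentary"] <- sample(0:30, sum(type == "sedentary"),
                                     replace = TRUE)
  other <- type %in% c("standing", "weight_bearing")
  ima[other] <- sample(0:80, sum(other), replace = TRUE)
  act <- which(type %in% c("LPA", "MPA", "VPA"))
  if (length(act) && jitter > 0) {
    flip <- act[runif(length(act)) < jitter]
    for (i in flip) {
      ima[i] <- switch(type[i],
                       LPA = 401L + sample.int(20L, 1L),
                       MPA = if (runif(1) < 0.5) 400L - sample.int(20L, 1L)
                             else 800L + sample.int(20L, 1L),
                       VPA = 800L - sample.int(20L, 1L))
    }
  }
  ima
}

#' Generate a synthetic daily-level cohort
#'
#' Same day-level generative process as [synthesize_cohort()] without the
#' minute expansion; useful for training the daily classifier at scale. The
#' `level` column is the construction target and equals
#' `classify_day(steps, mpa_s/60, vpa_s/60)` by design.
#'
#' @param spec a [cohort_spec()].
#' @return daily data.frame with columns `participant`, `date`, `level`,
#'   `steps`, `sedentary_s`, `lpa_s`, `mpa_s`, `vpa_s`.
#' @export
synthesize_daily_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    plan <- synthesize_daily_plan(spec)
    active <- plan$vpa_min + plan$mpa_min + plan$lpa_min
    sed_min <- round((spec$minutes_per_day - active) *
                       runif(nrow(plan), 0.7, 0.9))
    data.frame(participant = plan$participant, date = plan$date,
               level = plan$level, steps = plan$steps,
               sedentary_s = 60 * sed_min, lpa_s = 60 * plan$lpa_min,
               mpa_s = 60 * plan$mpa_min, vpa_s = 60 * plan$vpa_min,
               stringsAsFactors = FALSE)
  })
}
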