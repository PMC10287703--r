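# Naive probabilistic prediction intervals around point step forecasts:
# Yhat_{T+h} +/- c * sigma_h, with sigma_h the residual standard deviation of
# the one-step naive ("tomorrow equals today") forecast.

#' Coverage constant for a prediction interval
#'
#' Normal-quantile constants for the supported coverage levels: 80% -> 1.28,
#' 90% -> 1.645, 95% -> 1.96.
#'
#' @param coverage one of 0.80, 0.90, 0.95.
#' @return the constant `c`.
#' @export
coverage_constant <- function(coverage = 0.80) {
  tab <- c("0.8" = 1.28, "0.9" = 1.645, "0.95" = 1.96)
  key <- as.character(coverage)
  if (!key %in% names(tab)) {
    stop("unsupported coverage level; use 0.80, 0.90 or 0.95", call. = FALSE)
  }
  unname(tab[key])
}

#' Residual standard deviation of the naive forecast
#'
#' The naive method predicts each value by its predecessor, so the residuals
#' are the first differences `y_t - y_{t-1}`; their sample standard deviation
#' (n-1 denominator) estimates sigma_h, assumed constant across the horizon.
#' By default the full history is used; a trailing `window` can be given.
#'
#' @param series numeric daily step counts, length >= 3.
#' @param window optional trailing window length over which residuals are
#'   taken.
#' @return sigma_h in steps.
#' @examples
#' naive_residual_sd(c(1, 2, 3, 4))  # residuals all 1 -> 0
#' @export
naive_residual_sd <- function(series, window = NULL) {
  series <- as.numeric(series)
  if (!is.null(window)) series <- tail(series, window)
  if (length(series) < 3) {
    stop("need at least 3 observations to estimate the residual SD",
         call. = FALSE)
  }
  sd(diff(series))
}

#' Build a prediction interval around a point forecast
#'
#' Bounds are `round(point -/+ c * sigma_h)` with half-up integer rounding
#' (so 1893.12 -> 1893 and 5146.88 -> 5147); before rounding the interval is
#' exactly symmetric about the point. With `floor_at_zero` the lower bound is
#' clamped at 0.
#'
#' @param point point forecast in steps.
#' @param c coverage constant (see [coverage_constant()]).
#' @param sigma_h residual standard deviation in steps (>= 0).
#' @param h horizon step index (>= 1), carried for reporting.
#' @param floor_at_zero clamp the lower bound at zero.
#' @param widen_sqrt_h multiply sigma_h by `sqrt(h)` (off by default; the
#'   naive sigma is held constant across the week).
#' @return a `prediction_interval` list with `h`, `point`, `c`, `sigma_h`,
#'   `lower`, `upper`.
#' @examples
#' prediction_interval(3520, 1.28, 1271)  # [1893, 5147]
#' @export
prediction_interval <- function(point, c = 1.28, sigma_h, h = 1,
                                floor_at_zero = FALSE,
                                widen_sqrt_h = FALSE) {
  if (!is.finite(sigma_h) || sigma_h < 0) {
    stop("`sigma_h` must be non-negative", call. = FALSE)
  }
  if (h < 1) stop("`h` must be >= 1", call. = FALSE)
  s <- if (widen_sqrt_h) sigma_h * sqrt(h) else sigma_h
  lower <- round_half_up(point - c * s)
  upper <- round_half_up(point + c * s)
  if (floor_at_zero) lower <- max(0, lower)
  structure(list(h = h, point = point, c = c, sigma_h = s,
                 lower = lower, upper = upper),
            class = "prediction_interval")
}

#' @export
print.prediction_interval <- function(x, ...) {
  cat(sprintf("day %d: %.1f  [%d, %d]  (c=%.3g, sigma=%.1f)\n",
              x$h, x$point, x$lower, x$upper, x$c, x$sigma_h))
  invisible(x)
}

#' Weekly interval table from 7 point forecasts
#'
#' Applies [prediction_interval()] to each of seven daily point forecasts
#' with a constant sigma_h and reports the weekly mean point forecast to one
#' decimal.
#'
#' @param points exactly 7 point forecasts in steps.
#' @param c coverage constant.
#' @param sigma_h residual standard deviation in steps.
#' @param floor_at_zero clamp lower bounds at zero.
#' @return a data.frame with columns `day`, `point`, `lower`, `upper` and a
#'   `mean_point` attribute.
#' @export
weekly_interval_table <- function(points, c = 1.28, sigma_h,
                                  floor_at_zero = FALSE) {
  check_length(points, 7, "points")
  rows <- lapply(seq_len(7), function(h) {
    pi <- prediction_interval(points[h], c, sigma_h, h = h,
                              floor_at_zero = floor_at_zero)
    data.frame(day = h, point = pi$point, lower = pi$lower,
               upper = pi$upper)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_point") <- round_half_up(mean(points), 1)
  out
}
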