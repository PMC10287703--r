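# Univariate daily-step forecaster: two 1-D convolutions (kernel 3, ReLU),
# 1-D max pooling, flatten, and a single dense output, trained on
# min-max-scaled sliding windows with MSE loss under ADAM.

#' Configuration for the step forecaster
#'
#' Two 1-D convolution layers (kernel size 3, ReLU; filter counts default
#' 64 then 32), one max-pooling layer (pool size 2), a flatten layer and a
#' dense output of size 1. Series are min-max scaled to \[0, 1\] before
#' training and forecasts are returned on the original step scale.
#'
#' @param n_steps sliding-window length (default 7 days, one week).
#' @param filters filter counts for the two convolution layers.
#' @param kernel_size convolution kernel size.
#' @param pool_size max-pooling window.
#' @param epochs training epochs (default 200).
#' @param batch_size minibatch size (default 50).
#' @param lr,beta1,beta2,eps ADAM parameters (standard configuration).
#' @param validation_split trailing fraction of windows monitored by the
#'   plateau schedule.
#' @param patience,lr_factor,min_lr reduce-on-plateau schedule.
#' @return a `forecaster_config` list.
#' @export
forecaster_config <- function(n_steps = 7, filters = c(64, 32),
                              kernel_size = 3, pool_size = 2, epochs = 200,
                              batch_size = 50, lr = 0.001, beta1 = 0.9,
                              beta2 = 0.999, eps = 1e-8,
                              validation_split = 0.05, patience = 10,
                              lr_factor = 0.5, min_lr = 1e-5) {
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  structure(as.list(environment()), class = "forecaster_config")
}

# sliding supervised windows: rows of n_steps inputs and the next value
make_windows <- function(series, n_steps) {
  n <- length(series) - n_steps
  x <- t(vapply(seq_len(n), function(i) series[i:(i + n_steps - 1)],
                numeric(n_steps)))
  list(x = x, y = series[(n_steps + 1):length(series)])
}

#' Train the univariate step forecaster
#'
#' Builds sliding windows of length `n_steps` over the min-max-scaled series
#' and fits the convolutional network with MSE loss. Deterministic under a
#' fixed seed.
#'
#' @param series numeric vector of daily step counts, length >
#'   `n_steps + 1`.
#' @param config a [forecaster_config()].
#' @param seed integer seed.
#' @return a fitted `step_forecaster`.
#' @export
train_forecaster <- function(series, config = forecaster_config(), seed = 1) {
  series <- as.numeric(series)
  if (any(!is.finite(series))) {
    stop("`series` must be finite", call. = FALSE)
  }
  if (length(series) <= config$n_steps + 1) {
    stop("series too short to window: need length > n_steps + 1 = ",
         config$n_steps + 1, call. = FALSE)
  }
  scaler <- minmax_fit(matrix(series, ncol = 1))
  ss <- drop(minmax_apply(scaler, matrix(series, ncol = 1)))
  win <- make_windows(ss, config$n_steps)

  with_seed(seed, {
    params <- cnn_init(config$n_steps, config$filters, config$kernel_size)
    st <- adam_state(params)
    n <- nrow(win$x)
    n_val <- max(1L, floor(n * config$validation_split))
    idx_val <- (n - n_val + 1L):n
    idx_tr <- if (n > n_val) seq_len(n - n_val) else seq_len(n)
    sched <- list(lr = config$lr, best = Inf, wait = 0L,
                  patience = config$patience, factor = config$lr_factor,
                  min_lr = config$min_lr)
    history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(idx_tr)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (b in batches) {
        xb <- array(win$x[b, , drop = FALSE],
                    c(length(b), config$n_steps, 1))
        fw <- cnn_forward(params, xb, config$pool_size)
        gr <- cnn_backward(params, fw, xb, win$y[b], config$pool_size)
        upd <- adam_step(params, gr, st, sched$lr, config$beta1,
                         config$beta2, config$eps)
        params <- upd$params
        st <- upd$state
      }
      xv <- array(win$x[idx_val, , drop = FALSE],
                  c(length(idx_val), config$n_steps, 1))
      vloss <- mean((cnn_forward(params, xv, config$pool_size)$yhat -
                       win$y[idx_val])^2)
      history[epoch] <- vloss
      sched <- plateau_update(sched, vloss)
    }
    structure(list(params = params, scaler = scaler, config = config,
                   seed = seed, val_history = history),
              class = "step_forecaster")
  })
}

#' One-step forecasts from trailing windows
#'
#' @param object a fitted `step_forecaster`.
#' @param newdata numeric vector (or matrix of rows) of length `n_steps` on
#'   the original step scale.
#' @param ... unused.
#' @return point forecasts on the step scale.
#' @export
predict.step_forecaster <- function(object, newdata, ...) {
  cfg <- object$config
  x <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  if (ncol(x) != cfg$n_steps) {
    stop("each input window must have length n_steps = ", cfg$n_steps,
         call. = FALSE)
  }
  xs <- t(apply(x, 1, function(r) {
    drop(minmax_apply(object$scaler, matrix(r, ncol = 1)))
  }))
  if (nrow(x) == 1) xs <- matrix(xs, nrow = 1)
  fw <- cnn_forward(object$params,
                    array(xs, c(nrow(xs), cfg$n_steps, 1)), cfg$pool_size)
  drop(minmax_invert(object$scaler, matrix(fw$yhat, ncol = 1)))
}

#' Recursive multi-step step forecast
#'
#' Forecasts `horizon` days ahead by feeding each one-step prediction back
#' into the input window (recursive strategy). Outputs are clamped at zero:
#' step counts cannot be negative.
#'
#' @param model a fitted `step_forecaster`.
#' @param series observed daily steps; the trailing `n_steps` values seed the
#'   first window.
#' @param horizon number of days ahead (default 7).
#' @return numeric vector of `horizon` point forecasts.
#' @export
forecast_horizon <- function(model, series, horizon = 7) {
  if (horizon < 1) stop("`horizon` must be >= 1", call. = FALSE)
  n_steps <- model$config$n_steps
  if (length(series) < n_steps) {
    stop("series must contain at least n_steps = ", n_steps, " values",
         call. = FALSE)
  }
  window <- tail(as.numeric(series), n_steps)
  out <- numeric(horizon)
  for (h in seq_len(horizon)) {
    out[h] <- max(0, predict(model, window))
    window <- c(window[-1], out[h])
  }
  out
}

#' @export
print.step_forecaster <- function(x, ...) {
  cat("CNN1D step forecaster\n")
  cat("  n_steps:", x$config$n_steps, " filters:",
      paste(x$config$filters, collapse = "/"), "\n")
  cat("  final validation MSE (scaled):",
      signif(tail(x$val_history, 1), 4), "\n")
  invisible(x)
}
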