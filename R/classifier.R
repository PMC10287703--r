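# Feed-forward daily activity-level classifier: six dense layers
# (32-32-16-16-16-5), ReLU hidden activations, softmax output, categorical
# cross-entropy, ADAM with the standard configuration, reduce-LR-on-plateau.

#' Configuration for the activity-level classifier
#'
#' Defaults mirror the reference architecture: six fully connected layers of
#' widths 32, 32, 16, 16, 16 and 5 over the five daily features
#' (steps, sedentary, LPA, MPA, VPA seconds), ReLU hidden activations and a
#' softmax head, trained with categorical cross-entropy under ADAM
#' (alpha 0.001, beta1 0.9, beta2 0.999, epsilon 1e-8, no decay), a 0.05
#' validation split and a reduce-on-plateau learning-rate schedule.
#'
#' @param layer_widths integer vector of dense-layer widths; the last entry
#'   must equal the number of activity levels (5).
#' @param input_dim number of input features.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr,beta1,beta2,eps ADAM parameters.
#' @param validation_split fraction of rows (the trailing block) monitored
#'   for the plateau schedule.
#' @param patience epochs without validation improvement before the learning
#'   rate is halved.
#' @param lr_factor,min_lr plateau schedule factor and floor.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(layer_widths = c(32, 32, 16, 16, 16, 5),
                              input_dim = 5, epochs = 200, batch_size = 32,
                              lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                              eps = 1e-8, validation_split = 0.05,
                              patience = 10, lr_factor = 0.5,
                              min_lr = 1e-5) {
  if (tail(layer_widths, 1) != 5) {
    stop("the output layer width must equal the number of levels (5)",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "classifier_config")
}

#' Train the daily activity-level classifier
#'
#' @param features data.frame or matrix with columns `steps`, `sedentary_s`,
#'   `lpa_s`, `mpa_s`, `vpa_s` (or any 5 numeric columns in that role).
#' @param labels integer level codes 0-4, one per row; at least two classes
#'   must be present.
#' @param config a [classifier_config()].
#' @param seed integer seed; training is deterministic given the seed (single
#'   threaded).
#' @return a fitted `step_classifier` with a [predict()] method returning
#'   per-class probabilities (summing to 1) or hard classes.
#' @export
train_classifier <- function(features, labels, config = classifier_config(),
                             seed = 1) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) {
    stop("`features` must be finite (no NaN/NA)", call. = FALSE)
  }
  if (ncol(x) != config$input_dim) {
    stop("expected ", config$input_dim, " feature columns, got ", ncol(x),
         call. = FALSE)
  }
  labels <- as.integer(labels)
  check_length(labels, nrow(x), "labels")
  if (length(unique(labels)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  if (any(labels < 0 | labels > 4)) {
    stop("labels must be level codes in 0-4", call. = FALSE)
  }

  scaler <- minmax_fit(x)
  xs <- minmax_apply(scaler, x)
  y <- matrix(0, nrow(xs), 5)
  y[cbind(seq_len(nrow(xs)), labels + 1L)] <- 1

  with_seed(seed, {
    params <- mlp_init(config$input_dim, config$layer_widths)
    st <- adam_state(params)
    n <- nrow(xs)
    n_val <- max(1L, floor(n * config$validation_split))
    idx_val <- (n - n_val + 1L):n
    idx_tr <- setdiff(seq_len(n), idx_val)
    sched <- list(lr = config$lr, best = Inf, wait = 0L,
                  patience = config$patience, factor = config$lr_factor,
                  min_lr = config$min_lr)
    history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(idx_tr)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (b in batches) {
        fw <- mlp_forward(params, xs[b, , drop = FALSE])
        gr <- mlp_backward(params, fw, y[b, , drop = FALSE])
        upd <- adam_step(params, gr, st, sched$lr, config$beta1,
                         config$beta2, config$eps)
        params <- upd$params
        st <- upd$state
      }
      val <- mlp_forward(params, xs[idx_val, , drop = FALSE])
      vloss <- cross_entropy(val$acts[[length(val$acts)]],
                             y[idx_val, , drop = FALSE])
      history[epoch] <- vloss
      sched <- plateau_update(sched, vloss)
    }
    structure(list(params = params, scaler = scaler, config = config,
                   levels = 0:4, seed = seed, val_history = history),
              class = "step_classifier")
  })
}

#' Predict activity levels
#'
#' @param object a fitted `step_classifier`.
#' @param newdata feature rows as in [train_classifier()].
#' @param type `"prob"` for a matrix of per-class probabilities (rows sum to
#'   1) or `"class"` for hard level codes.
#' @param ... unused.
#' @return probability matrix or integer vector.
#' @export
predict.step_classifier <- function(object, newdata,
                                    type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- minmax_apply(object$scaler, as.matrix(newdata))
  fw <- mlp_forward(object$params, x)
  probs <- fw$acts[[length(fw$acts)]]
  colnames(probs) <- as.character(object$levels)
  if (type == "prob") return(probs)
  object$levels[max.col(probs, ties.method = "first")]
}

#' @export
print.step_classifier <- function(x, ...) {
  cat("Feed-forward activity-level classifier\n")
  cat("  layers:", paste(x$config$layer_widths, collapse = "-"),
      " input_dim:", x$config$input_dim, "\n")
  cat("  final validation loss:", signif(tail(x$val_history, 1), 4), "\n")
  invisible(x)
}
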