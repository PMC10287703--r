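# Classification and forecasting evaluation metrics.

#' Evaluate multi-class classification
#'
#' Computes the confusion matrix and precision, recall, accuracy, F1 and the
#' Matthews correlation coefficient. Precision, recall and F1 are weighted
#' averages over classes (one-vs-rest per class, weighted by class support);
#' accuracy is the confusion-matrix trace over n. The MCC uses the
#' multi-category (Gorodkin) form, which reduces to
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` for two classes and
#' does not depend on which class is called positive.
#'
#' @param true,predicted equal-length vectors of class labels (level codes).
#' @return a list of class `classification_metrics`: `precision`, `recall`,
#'   `accuracy`, `f1`, `mcc`, `confusion` (table), `per_class` (data.frame).
#' @export
evaluate_classification <- function(true, predicted) {
  if (length(true) != length(predicted) || length(true) == 0) {
    stop("`true` and `predicted` must be equal-length and non-empty",
         call. = FALSE)
  }
  classes <- sort(unique(c(true, predicted)))
  tt <- factor(true, levels = classes)
  pp <- factor(predicted, levels = classes)
  cm <- table(true = tt, predicted = pp)
  n <- sum(cm)
  support <- rowSums(cm)
  tp <- diag(cm)
  prec_c <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec_c <- ifelse(support > 0, tp / support, 0)
  f1_c <- ifelse(prec_c + rec_c > 0,
                 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  w <- support / n
  structure(list(
    precision = sum(w * prec_c),
    recall = sum(w * rec_c),
    accuracy = sum(tp) / n,
    f1 = sum(w * f1_c),
    mcc = mcc_from_confusion(cm),
    confusion = cm,
    per_class = data.frame(class = classes, support = as.integer(support),
                           precision = as.numeric(prec_c),
                           recall = as.numeric(rec_c),
                           f1 = as.numeric(f1_c))
  ), class = "classification_metrics")
}

# multi-category Matthews correlation (Gorodkin); equals the familiar binary
# formula on a 2x2 table
mcc_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  correct <- sum(diag(cm))
  tk <- rowSums(cm)   # true occurrences per class
  pk <- colSums(cm)   # predicted occurrences per class
  num <- correct * n - sum(tk * pk)
  den <- sqrt(n^2 - sum(pk^2)) * sqrt(n^2 - sum(tk^2))
  if (den == 0) return(0)
  num / den
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "precision %.3f  recall %.3f  accuracy %.3f  f1 %.3f  mcc %.3f\n",
    x$precision, x$recall, x$accuracy, x$f1, x$mcc))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a step forecast
#'
#' Root-mean-squared error `sqrt(mean((predicted - expected)^2))`, forecast
#' bias `fb = mean(expected - predicted)` (negative means overprediction,
#' positive underprediction), and the residual standard deviation `rsd`
#' (sample SD of the error series).
#'
#' @param predicted,expected equal-length numeric vectors of steps.
#' @return list of class `forecast_metrics`: `rmse`, `fb`, `rsd`.
#' @examples
#' evaluate_forecast(c(2, 4), c(1, 2))  # rmse sqrt(2.5), fb -1.5
#' @export
evaluate_forecast <- function(predicted, expected) {
  if (length(predicted) != length(expected) || length(predicted) == 0) {
    stop("`predicted` and `expected` must be equal-length and non-empty",
         call. = FALSE)
  }
  err <- expected - predicted
  structure(list(
    rmse = sqrt(mean(err^2)),
    fb = mean(err),
    rsd = if (length(err) > 1) sd(err) else 0
  ), class = "forecast_metrics")
}

#' @export
print.forecast_metrics <- function(x, ...) {
  cat(sprintf("rmse %.2f  fb %.2f  rsd %.2f\n", x$rmse, x$fb, x$rsd))
  invisible(x)
}
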