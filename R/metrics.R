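#' Matthews correlation coefficient from a confusion matrix
#'
#' For a 2x2 matrix the binary closed form
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` is used; larger
#' matrices use the generalized multiclass correlation form
#' `(c*s - sum(t_k p_k)) / sqrt((s^2 - sum(p_k^2)) (s^2 - sum(t_k^2)))`,
#' where `s` is the sample total, `c` the correctly classified count, and
#' `t_k` / `p_k` the true / predicted class totals. The two coincide on
#' 2x2 matrices. Any zero denominator (e.g. predictions independent of the
#' truth, all one class) yields 0 by convention.
#'
#' @param confusion square nonnegative count matrix, rows = truth,
#'   columns = prediction, total > 0.
#' @param method `"auto"` (closed form when 2x2, else generalized),
#'   `"binary"`, or `"generalized"`.
#' @return Scalar in `[-1, 1]`.
#' @examples
#' mcc(matrix(c(45, 10, 5, 40), 2, 2))
#' @export
mcc <- function(confusion, method = c("auto", "binary", "generalized")) {
  method <- match.arg(method)
  confusion <- unclass(as.matrix(confusion))
  if (length(confusion) == 0L || nrow(confusion) != ncol(confusion)) {
    stop("'confusion' must be a nonempty square matrix")
  }
  if (sum(confusion) <= 0) stop("'confusion' must have a positive total")
  if (method == "auto") {
    method <- if (nrow(confusion) == 2L) "binary" else "generalized"
  }
  if (method == "binary") {
    if (nrow(confusion) != 2L) stop("binary closed form needs a 2x2 matrix")
    tn <- confusion[1, 1]; fp <- confusion[1, 2]
    fn <- confusion[2, 1]; tp <- confusion[2, 2]
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) return(0)
    (tp * tn - fp * fn) / den
  } else {
    s <- sum(confusion)
    c0 <- sum(diag(confusion))
    t_k <- rowSums(confusion)
    p_k <- colSums(confusion)
    den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
    if (den == 0) return(0)
    (c0 * s - sum(t_k * p_k)) / den
  }
}

#' Classification metrics report
#'
#' Builds the full metrics set from true and predicted labels: accuracy,
#' macro-averaged precision/recall/F1 (zero-division cells contribute 0),
#' the confusion matrix (rows = truth, columns = prediction) and the MCC.
#'
#' @param truth,pred label vectors of equal positive length; `levels`
#'   optionally fixes the class set (defaults to the union observed).
#' @return Object of class `ddp_metrics`: list with `accuracy`,
#'   `precision`, `recall`, `f1` (macro), `per_class` (data frame),
#'   `confusion`, `mcc`, `n`.
#' @export
metrics_report <- function(truth, pred, levels = NULL) {
  if (length(truth) == 0L) stop("cannot evaluate an empty test set")
  if (length(truth) != length(pred)) stop("label length mismatch")
  if (is.null(levels)) levels <- sort(unique(c(as.character(truth),
                                               as.character(pred))))
  truth <- factor(as.character(truth), levels = levels)
  pred <- factor(as.character(pred), levels = levels)
  cm <- unclass(table(truth = truth, pred = pred))
  dg <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, dg / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, dg / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(
    accuracy = sum(dg) / sum(cm),
    precision = mean(prec),
    recall = mean(rec),
    f1 = mean(f1),
    per_class = data.frame(class = levels, precision = unname(prec),
                           recall = unname(rec), f1 = unname(f1)),
    confusion = cm,
    mcc = mcc(cm),
    n = sum(cm)
  ), class = "ddp_metrics")
}

#' @export
print.ddp_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f | macro precision %.3f recall %.3f F1 %.3f | MCC %.3f (n = %d)\n",
              x$accuracy, x$precision, x$recall, x$f1, x$mcc, x$n))
  cat("confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Aggregate per-modality MCC values
#'
#' Arithmetic mean and population standard deviation (denominator `n`) of
#' two or more MCC values, reported to three decimals — the convention used
#' when summarizing a classifier's stability across MRI modalities.
#'
#' @param values numeric vector of at least two MCC values.
#' @return Object of class `modality_aggregate`: list with `values`,
#'   `mean`, `sd` (both rounded to 3 decimals).
#' @examples
#' aggregate_mcc(c(0.934, 0.938, 0.981))
#' @export
aggregate_mcc <- function(values) {
  if (length(values) < 2L) stop("need at least two MCC values to aggregate")
  if (!all(is.finite(values))) stop("MCC values must be finite")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))   # population sd
  structure(list(values = values, mean = round(m, 3), sd = round(s, 3)),
            class = "modality_aggregate")
}

#' @export
print.modality_aggregate <- function(x, ...) {
  cat(sprintf("%s (%.3f ± %.3f)\n",
              paste(format(x$values), collapse = "/"), x$mean, x$sd))
  invisible(x)
}
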