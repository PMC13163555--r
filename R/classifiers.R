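#' Classifier specification
#'
#' The four reference classifiers with the hyperparameters used throughout:
#' \describe{
#'   \item{`svm_rbf`}{RBF-kernel SVM, `C = 10`, `gamma = "scale"` (i.e.
#'     `1 / (n_features * var(X))`, population variance over all feature
#'     entries), no feature rescaling.}
#'   \item{`knn`}{k-nearest neighbours, `k = 3`, distance weighting
#'     (`1/d`; a zero-distance neighbour dominates), Minkowski `p = 2`
#'     (Euclidean).}
#'   \item{`lda`}{linear discriminant analysis, SVD-based solver, no
#'     shrinkage, empirical priors.}
#'   \item{`logistic`}{L2-penalized logistic classifier, inverse penalty
#'     strength `C = 1` (ridge `lambda = 1/(C * n)`), multinomial for
#'     three or more classes.}
#' }
#' Any default can be overridden through `...`.
#'
#' @param kind one of `"svm_rbf"`, `"knn"`, `"lda"`, `"logistic"`.
#' @param ... hyperparameter overrides (`C`, `gamma`, `k`, `p`, ...).
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm_rbf", "knn", "lda", "logistic"),
                            ...) {
  kind <- match.arg(kind)
  hp <- switch(kind,
    svm_rbf  = list(C = 10, gamma = "scale"),
    knn      = list(k = 3L, weights = "distance", p = 2),
    lda      = list(solver = "svd"),
    logistic = list(C = 1)
  )
  dots <- list(...)
  hp[names(dots)] <- dots
  structure(list(kind = kind, hyperparams = hp), class = "classifier_spec")
}

#' Train a classifier on feature vectors
#'
#' Fits the model named by `spec` on a numeric feature matrix. Columns that
#' are constant in the training data (e.g. structurally empty histogram
#' bins) are dropped before fitting and the same columns are dropped at
#' prediction time. All four fits are deterministic given the data.
#'
#' @param x numeric feature matrix, one row per sample.
#' @param y label vector (coerced to factor); at least two classes must be
#'   present.
#' @param spec a [classifier_spec()].
#' @return Object of class `ddp_model` with a [predict.ddp_model()] method.
#' @export
train_classifier <- function(x, y, spec = classifier_spec("svm_rbf")) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("training labels contain a single class")
  if (nrow(x) != length(y)) stop("feature/label length mismatch")
  keep <- which(apply(x, 2L, function(col) max(col) > min(col)))
  if (length(keep) == 0L) stop("all feature columns are constant")
  xt <- x[, keep, drop = FALSE]
  hp <- spec$hyperparams
  fit <- switch(spec$kind,
    svm_rbf = {
      g <- hp$gamma
      if (identical(g, "scale")) {
        v <- mean((xt - mean(xt))^2)
        g <- if (v > 0) 1 / (ncol(xt) * v) else 1
      }
      e1071::svm(x = xt, y = y, type = "C-classification",
                 kernel = "radial", cost = hp$C, gamma = g, scale = FALSE)
    },
    knn = list(x = xt, y = y, k = hp$k, p = hp$p),
    lda = suppressWarnings(MASS::lda(xt, grouping = y)),
    logistic = {
      fam <- if (nlevels(y) == 2L) "binomial" else "multinomial"
      lam <- 1 / (hp$C * nrow(xt))
      glmnet::glmnet(xt, y, family = fam, alpha = 0, lambda = lam,
                     standardize = FALSE)
    }
  )
  structure(list(spec = spec, fit = fit, keep = keep, levels = levels(y)),
            class = "ddp_model")
}

#' Predict class labels
#'
#' @param object a `ddp_model` from [train_classifier()].
#' @param newdata numeric feature matrix with the training feature layout.
#' @param ... unused.
#' @return Factor of predicted labels with the training levels.
#' @export
predict.ddp_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, object$keep, drop = FALSE]
  out <- switch(object$spec$kind,
    svm_rbf = as.character(stats::predict(object$fit, x)),
    knn = knn_predict(object$fit, x),
    lda = as.character(stats::predict(object$fit, x)$class),
    logistic = {
      p <- stats::predict(object$fit, x, type = "class",
                          s = object$fit$lambda)
      as.character(p[, 1])
    }
  )
  factor(out, levels = object$levels)
}

# Distance-weighted kNN (Minkowski p). Weights are 1/d; if any neighbour
# sits at zero distance the vote is restricted to those exact matches.
# Ties between classes break toward the earlier factor level.
knn_predict <- function(fit, x) {
  xtr <- fit$x; ytr <- fit$y; k <- fit$k; p <- fit$p
  lev <- levels(ytr)
  out <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    d <- (rowSums(abs(xtr - matrix(x[i, ], nrow(xtr), ncol(xtr),
                                   byrow = TRUE))^p))^(1 / p)
    nn <- order(d)[seq_len(min(k, length(d)))]
    dd <- d[nn]
    w <- if (any(dd < 1e-12)) as.numeric(dd < 1e-12) else 1 / dd
    score <- vapply(lev, function(cl) sum(w[ytr[nn] == cl]), numeric(1))
    out[i] <- lev[which.max(score)]
  }
  out
}

#' Fit and evaluate in one call
#'
#' Convenience wrapper: predicts `x` with `model` and returns the full
#' [metrics_report()] against `y`.
#'
#' @param model a `ddp_model`.
#' @param x test feature matrix (nonempty).
#' @param y true labels.
#' @return A `ddp_metrics` object.
#' @export
evaluate_model <- function(model, x, y) {
  if (NROW(x) == 0L) stop("cannot evaluate an empty test set")
  metrics_report(y, predict(model, x), levels = model$levels)
}
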