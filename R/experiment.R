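#' Extract per-slice features for a whole dataset
#'
#' Runs [extract_slice_features()] over every slice of every subject and
#' returns a flat feature table suitable for the classification harness.
#'
#' @param subjects list of subject records ([generate_dataset()] or
#'   [read_dataset()]).
#' @param task `"binary"` or `"severity"`; selects which label column is
#'   attached.
#' @param ... passed to [extract_slice_features()] (`method`, `block_size`,
#'   `quantizer`, `n_bins`, `bin_on`, `normalization`).
#' @return Data frame with columns `subject_id`, `slice_idx`, `modality`,
#'   `label` and `f00` ... `f15` (or `n_bins` feature columns).
#' @export
extract_dataset_features <- function(subjects,
                                     task = c("binary", "severity"), ...) {
  task <- match.arg(task)
  rows <- lapply(subjects, function(s) {
    lab <- if (task == "binary") s$label_binary else s$label_severity
    if (is.na(lab)) {
      stop("subject ", s$subject_id, " has no ", task, " label")
    }
    ns <- dim(s$volume)[3]
    feats <- t(vapply(seq_len(ns),
                      function(k) as.numeric(
                        extract_slice_features(s$volume[, , k], ...)),
                      numeric(length(extract_slice_features(
                        s$volume[, , 1], ...)))))
    df <- data.frame(subject_id = s$subject_id, slice_idx = seq_len(ns),
                     modality = s$modality, label = lab,
                     stringsAsFactors = FALSE)
    cbind(df, as.data.frame(feats))
  })
  out <- do.call(rbind, rows)
  nf <- ncol(out) - 4L
  names(out)[-(1:4)] <- sprintf("f%02d", seq_len(nf) - 1L)
  rownames(out) <- NULL
  out
}

feature_matrix <- function(features) {
  as.matrix(features[, grep("^f[0-9]+$", names(features)), drop = FALSE])
}

#' Run a subject-wise cross-validated classification experiment
#'
#' The end-to-end harness: assigns whole subjects to folds with
#' [subject_stratified_split()], then for each of the `n_folds` rounds
#' trains on the training folds, reports metrics on the rotating dedicated
#' validation fold (no model selection is performed on it) and on the test
#' fold, and finally averages the per-round test metrics. Slices always
#' inherit their subject's fold, so train/validation/test subject sets are
#' disjoint in every round.
#'
#' @param features slice-level feature table from
#'   [extract_dataset_features()].
#' @param classifier a [classifier_spec()].
#' @param n_folds number of folds, default 5.
#' @param seed integer seed for the fold assignment.
#' @param pooling `"slice"` (classify each slice, default) or `"subject"`
#'   (average each subject's slice features into one descriptor and
#'   classify subjects).
#' @return Object of class `ddp_experiment`: per-round `test` and
#'   `validation` metrics, `mean` test metrics (accuracy, precision,
#'   recall, f1, mcc averaged over rounds), the pooled test `confusion`,
#'   and the experiment settings.
#' @examples
#' \donttest{
#' cfg <- phantom_config(slices_per_subject = 6L, seed = 7L)
#' ds <- generate_dataset(cfg, n_subjects_per_class = 5L, task = "binary")
#' fx <- extract_dataset_features(ds, task = "binary")
#' run_experiment(fx, classifier_spec("svm_rbf"), seed = 7L)
#' }
#' @export
run_experiment <- function(features,
                           classifier = classifier_spec("svm_rbf"),
                           n_folds = 5L, seed = 1L,
                           pooling = c("slice", "subject")) {
  pooling <- match.arg(pooling)
  if (pooling == "subject") {
    fm <- feature_matrix(features)
    agg <- stats::aggregate(fm, by = list(subject_id = features$subject_id),
                            FUN = mean)
    lab <- features$label[!duplicated(features$subject_id)]
    names(lab) <- features$subject_id[!duplicated(features$subject_id)]
    features <- cbind(
      data.frame(subject_id = agg$subject_id, slice_idx = 1L,
                 modality = features$modality[1],
                 label = unname(lab[agg$subject_id]),
                 stringsAsFactors = FALSE),
      agg[, -1, drop = FALSE])
  }
  subj <- unique(features[, c("subject_id", "label")])
  if (anyDuplicated(subj$subject_id)) {
    stop("a subject carries more than one label")
  }
  split <- subject_stratified_split(subj, n_folds = n_folds, seed = seed)
  x <- feature_matrix(features)
  lev <- sort(unique(features$label))
  rounds <- vector("list", n_folds)
  for (r in seq_len(n_folds)) {
    roles <- fold_roles(split, r)
    tr <- features$subject_id %in% roles$train
    va <- features$subject_id %in% roles$validation
    te <- features$subject_id %in% roles$test
    model <- train_classifier(x[tr, , drop = FALSE], features$label[tr],
                              classifier)
    rounds[[r]] <- list(
      roles = roles,
      validation = metrics_report(features$label[va],
                                  predict(model, x[va, , drop = FALSE]),
                                  levels = lev),
      test = metrics_report(features$label[te],
                            predict(model, x[te, , drop = FALSE]),
                            levels = lev)
    )
  }
  pick <- function(field) vapply(rounds, function(r) r$test[[field]],
                                 numeric(1))
  structure(list(
    rounds = rounds,
    mean = list(accuracy = mean(pick("accuracy")),
                precision = mean(pick("precision")),
                recall = mean(pick("recall")),
                f1 = mean(pick("f1")),
                mcc = mean(pick("mcc"))),
    confusion = Reduce(`+`, lapply(rounds, function(r) r$test$confusion)),
    classifier = classifier, n_folds = n_folds, seed = seed,
    pooling = pooling
  ), class = "ddp_experiment")
}

#' @export
print.ddp_experiment <- function(x, ...) {
  cat(sprintf("%d-fold subject-wise experiment (%s, seed %d, %s-level)\n",
              x$n_folds, x$classifier$kind, x$seed, x$pooling))
  with(x$mean, cat(sprintf(
    "mean test: accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f | MCC %.3f\n",
    accuracy, precision, recall, f1, mcc)))
  invisible(x)
}

#' @export
summary.ddp_experiment <- function(object, ...) {
  print(object)
  cat("pooled test confusion (rows = truth):\n")
  print(object$confusion)
  cat("per-round test accuracy:",
      paste(sprintf("%.3f", vapply(object$rounds,
                                   function(r) r$test$accuracy, numeric(1))),
            collapse = " "), "\n")
  invisible(object)
}

#' Permute subject labels
#'
#' Shuffles the subject-to-label assignment (slices keep their subject's
#' permuted label), preserving the overall class counts. Used to build the
#' permutation null distribution of a classifier's performance.
#'
#' @param features slice-level feature table.
#' @param seed integer seed for the permutation.
#' @return The feature table with permuted labels.
#' @export
permute_subject_labels <- function(features, seed = 1L) {
  subj <- unique(features[, c("subject_id", "label")])
  set.seed(seed)
  newlab <- sample(subj$label)
  names(newlab) <- subj$subject_id
  features$label <- unname(newlab[features$subject_id])
  features
}

#' Serialize an experiment report to JSON
#'
#' Writes per-round and mean metrics (confusions as integer matrices) plus
#' the experiment settings.
#'
#' @param experiment a `ddp_experiment`.
#' @param path destination JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(experiment, path) {
  strip <- function(m) list(accuracy = m$accuracy, precision = m$precision,
                            recall = m$recall, f1 = m$f1, mcc = m$mcc,
                            confusion = unclass(m$confusion))
  payload <- list(
    classifier = experiment$classifier$kind,
    hyperparams = experiment$classifier$hyperparams,
    n_folds = experiment$n_folds,
    seed = experiment$seed,
    pooling = experiment$pooling,
    mean = experiment$mean,
    rounds = lapply(experiment$rounds, function(r)
      list(test = strip(r$test), validation = strip(r$validation)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
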