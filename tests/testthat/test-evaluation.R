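make_blobs <- function(n_per_class = 15, classes = 2, sep = 10, d = 4,
                       seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(classes) - 1, function(k) {
    matrix(stats::rnorm(n_per_class * d, mean = k * sep), n_per_class, d)
  }))
  list(x = x, y = factor(rep(letters[seq_len(classes)], each = n_per_class)))
}

test_that("all four classifiers separate well-separated blobs perfectly", {
  blobs <- make_blobs()
  for (kind in c("svm_rbf", "knn", "lda", "logistic")) {
    model <- train_classifier(blobs$x, blobs$y, classifier_spec(kind))
    expect_equal(mean(predict(model, blobs$x) == blobs$y), 1,
                 info = kind)
  }
})

test_that("classifier fits are deterministic and reject degenerate input", {
  blobs <- make_blobs(classes = 3, seed = 2)
  for (kind in c("svm_rbf", "knn", "lda", "logistic")) {
    m1 <- train_classifier(blobs$x, blobs$y, classifier_spec(kind))
    m2 <- train_classifier(blobs$x, blobs$y, classifier_spec(kind))
    expect_identical(predict(m1, blobs$x), predict(m2, blobs$x))
  }
  expect_error(train_classifier(blobs$x, rep("a", nrow(blobs$x)),
                                classifier_spec("lda")), "single class")
})

test_that("zero-distance neighbours dominate the weighted kNN vote", {
  x <- rbind(c(0, 0), c(0.1, 0), c(5, 5), c(5.1, 5))
  y <- factor(c("a", "a", "b", "b"))
  model <- train_classifier(x, y, classifier_spec("knn"))
  # query identical to a 'b' training point: its 1/d weight is infinite
  expect_identical(as.character(predict(model, rbind(c(5, 5)))), "b")
  expect_identical(as.character(predict(model, rbind(c(0, 0)))), "a")
})

test_that("metrics report matches hand computation", {
  perfect <- metrics_report(c("a", "b", "a", "b"), c("a", "b", "a", "b"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$mcc, 1)
  expect_true(all(perfect$confusion[lower.tri(perfect$confusion) |
                                    upper.tri(perfect$confusion)] == 0))

  # all-one-class predictions on a balanced binary test set
  truth <- rep(c("neg", "pos"), each = 5)
  pred <- rep("neg", 10)
  m <- metrics_report(truth, pred, levels = c("neg", "pos"))
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$recall, 0.5)       # macro: (1 + 0) / 2
  expect_equal(m$precision, 0.25)   # macro: (0.5 + 0/0->0) / 2
  expect_equal(m$n, 10L)
  expect_equal(sum(m$confusion), 10L)
  expect_error(metrics_report(character(0), character(0)), "empty")
})

test_that("MCC closed form, generalized form and conventions agree", {
  cm <- matrix(c(45, 10, 5, 40), 2, 2)  # rows truth: (45,5 / 10,40)
  v_bin <- mcc(cm, method = "binary")
  v_gen <- mcc(cm, method = "generalized")
  expect_equal(v_bin, v_gen, tolerance = 1e-12)
  expect_equal(v_bin, (40 * 45 - 5 * 10) /
                 sqrt(45) / sqrt(50) / sqrt(50) / sqrt(55),
               tolerance = 1e-12)

  expect_equal(mcc(diag(c(7, 9, 4))), 1)
  # predictions independent of truth: rank-1 confusion, zero denominator
  expect_equal(mcc(matrix(c(6, 4, 0, 0), 2, 2)), 0)
  expect_equal(mcc(matrix(c(1, 1, 1, 1), 2, 2)), 0)
  expect_error(mcc(matrix(numeric(0), 0, 0)), "square")

  set.seed(31)
  for (i in 1:200) {
    cm <- matrix(stats::rpois(4, 8), 2, 2)
    if (sum(cm) == 0) next
    expect_equal(mcc(cm, method = "binary"),
                 mcc(cm, method = "generalized"), tolerance = 1e-10)
    v <- mcc(cm)
    expect_gte(v, -1); expect_lte(v, 1)
  }
})

test_that("MCC aggregation uses the population standard deviation", {
  same <- aggregate_mcc(c(0.4, 0.4, 0.4))
  expect_equal(same$mean, 0.4)
  expect_equal(same$sd, 0)
  two <- aggregate_mcc(c(0.2, 0.6))
  expect_equal(two$mean, 0.4)
  expect_equal(two$sd, 0.2)          # population sd, not sample sd (0.283)
  expect_error(aggregate_mcc(0.5), "two")
})

test_that("the experiment harness is reproducible and well-bounded", {
  cfg <- phantom_config(slices_per_subject = 4L, seed = 61L)
  ds <- generate_dataset(cfg, 5L, "binary")
  fx <- extract_dataset_features(ds, task = "binary")
  e1 <- run_experiment(fx, classifier_spec("svm_rbf"), seed = 61L)
  e2 <- run_experiment(fx, classifier_spec("svm_rbf"), seed = 61L)
  expect_identical(e1$mean, e2$mean)
  expect_identical(e1$confusion, e2$confusion)
  for (v in unlist(e1$mean[c("accuracy", "precision", "recall", "f1")])) {
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_gte(e1$mean$mcc, -1); expect_lte(e1$mean$mcc, 1)
  expect_equal(sum(e1$confusion), nrow(fx))  # every slice tested once

  # subject-level pooling collapses to one record per subject
  ep <- run_experiment(fx, classifier_spec("lda"), seed = 61L,
                       pooling = "subject")
  expect_equal(sum(ep$confusion), length(ds))

  f <- file.path(tempdir(), "report.json")
  write_report(e1, f)
  rep <- jsonlite::read_json(f)
  expect_equal(rep$mean$accuracy, e1$mean$accuracy)
  expect_length(rep$rounds, 5L)
})

test_that("label permutation preserves class counts but breaks the link", {
  cfg <- phantom_config(slices_per_subject = 3L, seed = 71L)
  ds <- generate_dataset(cfg, 5L, "binary")
  fx <- extract_dataset_features(ds, task = "binary")
  px <- permute_subject_labels(fx, seed = 4)
  expect_equal(table(px$label), table(fx$label))
  subj <- unique(px[, c("subject_id", "label")])
  expect_equal(nrow(subj), length(ds))   # still one label per subject
})
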