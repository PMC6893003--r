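# Dataset assembly, fold plans, metrics, ROC/AUC and cross-validation.

make_demo_dataset <- function(n_pos = 20, n_neg = 20, effect = 5, seed = 1,
                              scheme = NULL, spec = tuple_spec(2)) {
  if (is.null(scheme)) scheme <- get_scheme(curated_registry(), "wang", 5)
  sets <- generate_synthetic(synthetic_spec(
    n_pos = n_pos, n_neg = n_neg, effect = effect, seed = seed))
  dataset_from_sequences(sets$pos, sets$neg, scheme, spec)
}

test_that("datasets label positives +1 then negatives -1 in file order", {
  sets <- generate_synthetic(synthetic_spec(n_pos = 5, n_neg = 5, seed = 2))
  pos_path <- write_temp_fasta(sets$pos, name = "pos.fasta")
  neg_path <- write_temp_fasta(sets$neg, name = "neg.fasta")
  ds <- build_dataset(pos_path, neg_path,
                      get_scheme(curated_registry(), "wang", 5))
  expect_equal(ds$labels, c(rep(1L, 5), rep(-1L, 5)))
  expect_equal(rownames(ds$features$matrix),
               c(names(sets$pos), names(sets$neg)))
  # duplicate ids across classes are tolerated with a warning
  dup <- sets$neg
  names(dup)[1] <- names(sets$pos)[1]
  dup_path <- write_temp_fasta(dup, name = "dup.fasta")
  expect_warning(build_dataset(pos_path, dup_path,
                               get_scheme(curated_registry(), "wang", 5)),
                 "both classes")
})

test_that("fold plans stratify, respect LOO, and are seed-deterministic", {
  labels <- c(rep(1L, 5), rep(-1L, 5))
  plan <- make_folds(labels, n_folds = 5, seed = 1)
  for (f in 1:5) {
    idx <- which(plan$assignments == f)
    expect_length(idx, 2L)
    expect_equal(sum(labels[idx] > 0), 1L)  # 1 pos + 1 neg per fold
  }
  loo <- make_folds(labels, loo = TRUE)
  expect_equal(loo$n_folds, 10L)
  expect_equal(sort(loo$assignments), 1:10)
  expect_identical(make_folds(labels, 5, seed = 3)$assignments,
                   make_folds(labels, 5, seed = 3)$assignments)
  big <- c(rep(1L, 40), rep(-1L, 40))
  expect_false(identical(make_folds(big, 5, seed = 1)$assignments,
                         make_folds(big, 5, seed = 2)$assignments))
  expect_error(make_folds(labels, n_folds = 6), "leave-one-out")
  # stratification at uneven sizes: class counts differ by at most 1
  uneven <- c(rep(1L, 13), rep(-1L, 9))
  plan <- make_folds(uneven, 4, seed = 7)
  per_fold_pos <- table(plan$assignments[uneven > 0])
  expect_true(max(per_fold_pos) - min(per_fold_pos) <= 1)
})

test_that("confusion metrics reproduce the closed forms", {
  m <- confusion_metrics(TP = 40, FN = 10, TN = 35, FP = 15)
  expect_equal(m$Sn, 0.8)
  expect_equal(m$Sp, 0.7)
  expect_equal(m$Acc, 0.75)
  expect_equal(m$MCC,
               (40 * 35 - 15 * 10) / sqrt((40 + 15) * (40 + 10) * (35 + 15) * (35 + 10)))
  # degenerate denominator convention
  expect_equal(confusion_metrics(TP = 0, FN = 0, TN = 5, FP = 5)$MCC, 0)
  # |MCC| <= 1 over random confusion tables
  set.seed(17)
  for (i in 1:50) {
    counts <- sample(0:30, 4, replace = TRUE)
    if (sum(counts) == 0) next
    m <- confusion_metrics(counts[1], counts[2], counts[3], counts[4])
    expect_true(abs(m$MCC) <= 1 + 1e-12)
  }
})

test_that("AUC equals the Mann-Whitney statistic and the trapezoid integral", {
  expect_equal(roc_auc(c(3, 2, 1, 0), c(1, 1, -1, -1))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), c(1, 1, 1, -1, -1, -1))$auc, 0.5)
  trapezoid <- function(roc) {
    sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  }
  set.seed(23)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    scores <- sample(round(rnorm(n), 1))  # rounding forces ties
    labels <- sample(c(1, -1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    out <- roc_auc(scores, labels)
    expect_equal(out$auc, trapezoid(out$roc), tolerance = 1e-12)
    # curve shape: starts (0,0), ends (1,1), monotone in both coordinates
    expect_equal(out$roc$fpr[1], 0)
    expect_equal(out$roc$tpr[1], 0)
    expect_equal(utils::tail(out$roc$fpr, 1), 1)
    expect_equal(utils::tail(out$roc$tpr, 1), 1)
    expect_true(all(diff(out$roc$fpr) >= 0))
    expect_true(all(diff(out$roc$tpr) >= 0))
    # label swap maps AUC to its complement
    expect_equal(roc_auc(scores, -labels)$auc, 1 - out$auc,
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:10) {
    scores <- rnorm(30)
    labels <- sample(c(1, -1), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<", levels = c(-1, 1))))
    expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
  }
})

test_that("negating the true labels negates MCC and complements AUC", {
  ds <- make_demo_dataset(n_pos = 15, n_neg = 15, effect = 3, seed = 4)
  plan <- make_folds(ds$labels, 5, seed = 4)
  cv <- cross_validate(ds, plan, "svm")
  pred <- cv$predicted
  truth <- cv$labels
  m <- confusion_metrics(TP = sum(pred > 0 & truth > 0),
                         FN = sum(pred < 0 & truth > 0),
                         TN = sum(pred < 0 & truth < 0),
                         FP = sum(pred > 0 & truth < 0))
  # same predictions scored against the negated truth
  m_swap <- confusion_metrics(TP = sum(pred > 0 & truth < 0),
                              FN = sum(pred < 0 & truth < 0),
                              TN = sum(pred < 0 & truth > 0),
                              FP = sum(pred > 0 & truth > 0))
  expect_equal(m$MCC, cv$MCC)
  expect_equal(m_swap$MCC, -cv$MCC, tolerance = 1e-12)
  expect_equal(roc_auc(cv$scores, -truth)$auc, 1 - cv$auc,
               tolerance = 1e-12)
})

test_that("cross-validation pools every row exactly once across folds", {
  ds <- make_demo_dataset(n_pos = 20, n_neg = 20, effect = 2, seed = 6)
  plan <- make_folds(ds$labels, 5, seed = 6)
  for (clf in c("svm", "knn", "rf")) {
    cv <- cross_validate(ds, plan, clf)
    expect_equal(cv$TP + cv$FN + cv$TN + cv$FP, 40)
    expect_equal(sum(cv$per_fold$n), 40)
    expect_true(all(cv$predicted %in% c(-1L, 1L)))
    expect_true(cv$auc >= 0 && cv$auc <= 1)
    expect_true(abs(cv$MCC) <= 1)
  }
  expect_error(cross_validate(ds, plan, "mlp"), "svm.*knn.*rf")
})

test_that("a perfectly separable planted signal is classified perfectly", {
  # effect high enough that aromatic content separates the classes
  ds <- make_demo_dataset(n_pos = 25, n_neg = 25, effect = 30, seed = 8)
  cv <- cross_validate(ds, make_folds(ds$labels, 5, seed = 8), "svm")
  expect_equal(cv$Acc, 1)
  expect_equal(cv$MCC, 1)
  expect_equal(cv$auc, 1)
})

test_that("permuted labels yield chance-level AUC", {
  sets <- generate_synthetic(synthetic_spec(n_pos = 100, n_neg = 100,
                                            effect = 3, seed = 12))
  sch <- get_scheme(curated_registry(), "wang", 5)
  ds <- dataset_from_sequences(sets$pos, sets$neg, sch, tuple_spec(2))
  ds$labels <- local({
    set.seed(99)
    sample(ds$labels)
  })
  cv <- cross_validate(ds, make_folds(ds$labels, 5, seed = 99), "svm")
  expect_gt(cv$auc, 0.35)
  expect_lt(cv$auc, 0.65)
})

test_that("model save/load round-trips predictions and rejects tampering", {
  ds <- make_demo_dataset(n_pos = 10, n_neg = 10, effect = 5, seed = 10)
  for (clf in c("svm", "knn", "rf")) {
    model <- train_model(ds, clf, seed = 10)
    before <- predict(model, ds$features$matrix)
    path <- tempfile(fileext = ".rds")
    save_model(model, path)
    loaded <- load_model(path)
    after <- predict(loaded, ds$features$matrix)
    expect_identical(after$labels, before$labels)
    expect_equal(after$scores, before$scores, tolerance = 1e-15)
    expect_equal(loaded$scheme_key, ds$features$scheme_key)
  }
  # tampered payload fails the checksum
  path <- tempfile(fileext = ".rds")
  model <- train_model(ds, "svm", seed = 10)
  save_model(model, path)
  artifact <- readRDS(path)
  artifact$model$payload$gamma <- 99
  saveRDS(artifact, path, version = 2L)
  expect_error(load_model(path), "checksum")
  # version mismatch is an explicit error
  artifact <- readRDS(save_model(model, path))
  artifact$version <- "raackit-model-0"
  saveRDS(artifact, path, version = 2L)
  expect_error(load_model(path), "format")
  # column mismatch on predict
  wrong <- ds$features$matrix[, rev(seq_len(ncol(ds$features$matrix)))]
  expect_error(predict(model, wrong), "columns")
})

test_that("mean CV AUC increases with the planted effect size", {
  sch <- get_scheme(curated_registry(), "wang", 5)
  mean_auc <- vapply(c(1, 2, 5), function(eff) {
    aucs <- vapply(1:3, function(s) {
      sets <- generate_synthetic(synthetic_spec(n_pos = 40, n_neg = 40,
                                                effect = eff, seed = s))
      ds <- dataset_from_sequences(sets$pos, sets$neg, sch, tuple_spec(2))
      cross_validate(ds, make_folds(ds$labels, 5, seed = s), "svm")$auc
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  expect_true(all(diff(mean_auc) > 0))
})
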