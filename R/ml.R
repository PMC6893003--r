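# Binary protein classification on RAAC features: benchmark dataset ->
# feature formulation -> classifier -> cross-validation -> report.

# md5 of an R object's serialization (used for model integrity checks).
object_md5 <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  con <- file(tmp, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(tmp))
}

# Internal label convention: factor with levels c("pos", "neg") so the
# positive class is the reference level of every classifier backend.
as_label_factor <- function(labels) {
  factor(ifelse(labels > 0, "pos", "neg"), levels = c("pos", "neg"))
}

#' Build a labeled dataset from positive and negative FASTA files
#'
#' Extracts K-tuple RAAC features from both classes with a shared scheme
#' and tuple specification. Positives are labeled +1, negatives -1; rows
#' are all positives then all negatives, in file order. Sequences without
#' extractable windows are dropped (warned); an empty class after
#' rejection is an error. Duplicate ids across the two files are warned
#' (ids are not keys). A class imbalance beyond 3:1 triggers a warning.
#'
#' @param pos_fasta,neg_fasta paths to the positive / negative FASTA files.
#' @param scheme a [raac_scheme()].
#' @param spec a [tuple_spec()].
#' @param unknown_policy passed to [extract_features()].
#' @return a `raac_dataset`: list with `features` (`raac_features` over all
#'   kept rows), `labels` (+1/-1 integer vector), `provenance`.
#' @export
build_dataset <- function(pos_fasta, neg_fasta, scheme,
                          spec = tuple_spec(),
                          unknown_policy = c("mask", "drop", "error")) {
  unknown_policy <- match.arg(unknown_policy)
  pos <- read_fasta(pos_fasta)
  neg <- read_fasta(neg_fasta)
  dup <- intersect(names(pos), names(neg))
  if (length(dup) > 0L) {
    warning("ids present in both classes: ",
            paste(utils::head(dup, 5L), collapse = ", "),
            if (length(dup) > 5L) ", ..." else "", call. = FALSE)
  }
  dataset_from_sequences(pos, neg, scheme, spec, unknown_policy,
                         provenance = c(pos = pos_fasta, neg = neg_fasta))
}

#' Build a labeled dataset from in-memory sequence vectors
#'
#' Same contract as [build_dataset()] but taking named character vectors,
#' e.g. the output of [generate_synthetic()].
#'
#' @param pos,neg named character vectors of residue strings.
#' @inheritParams build_dataset
#' @param provenance optional character vector recording the input origin.
#' @return a `raac_dataset`.
#' @export
dataset_from_sequences <- function(pos, neg, scheme, spec = tuple_spec(),
                                   unknown_policy = "mask",
                                   provenance = c(pos = "<memory>",
                                                  neg = "<memory>")) {
  fp <- extract_features(pos, scheme, spec, unknown_policy)
  fn <- extract_features(neg, scheme, spec, unknown_policy)
  if (nrow(fp$matrix) == 0L || nrow(fn$matrix) == 0L) {
    stop("a class is empty after rejection", call. = FALSE)
  }
  mat <- rbind(fp$matrix, fn$matrix)
  feats <- structure(
    list(matrix = mat,
         row_ids = c(fp$row_ids, fn$row_ids),
         spec = spec,
         scheme_key = fp$scheme_key,
         window_counts = c(fp$window_counts, fn$window_counts),
         rejects = rbind(fp$rejects, fn$rejects)),
    class = "raac_features"
  )
  labels <- c(rep(1L, nrow(fp$matrix)), rep(-1L, nrow(fn$matrix)))
  ratio <- max(table(labels)) / min(table(labels))
  if (ratio > 3) {
    warning(sprintf("class imbalance %.1f:1 exceeds 3:1", ratio),
            call. = FALSE)
  }
  structure(list(features = feats, labels = labels, provenance = provenance),
            class = "raac_dataset")
}

#' @export
print.raac_dataset <- function(x, ...) {
  cat(sprintf("RAAC dataset: %d positives, %d negatives, %d feature(s)\n",
              sum(x$labels > 0), sum(x$labels < 0), ncol(x$features$matrix)))
  invisible(x)
}

#' Stratified cross-validation fold plan
#'
#' Assigns each row to one of `n_folds` folds such that per-fold class
#' counts differ by at most one from proportionality: within each class,
#' rows are shuffled (seeded) and folds assigned cyclically. With
#' `loo = TRUE` every row is its own fold.
#'
#' @param labels +1/-1 label vector (one per row).
#' @param n_folds number of folds (default 5).
#' @param loo logical; leave-one-out instead of k-fold.
#' @param seed integer seed driving the within-class shuffle.
#' @return a `fold_plan`: list with `n_folds`, `assignments` (integer per
#'   row), `loo`, `seed`.
#' @export
make_folds <- function(labels, n_folds = 5L, loo = FALSE, seed = 42L) {
  n <- length(labels)
  stopifnot(n >= 2L)
  if (loo) {
    return(structure(list(n_folds = n, assignments = seq_len(n),
                          loo = TRUE, seed = as.integer(seed)),
                     class = "fold_plan"))
  }
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  class_sizes <- table(labels)
  if (n_folds > min(class_sizes)) {
    stop("n_folds (", n_folds, ") exceeds the smallest class size (",
         min(class_sizes), "); consider leave-one-out (loo = TRUE)",
         call. = FALSE)
  }
  assignments <- integer(n)
  with_seed(seed, {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      idx <- sample(idx)
      assignments[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  structure(list(n_folds = n_folds, assignments = assignments, loo = FALSE,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

# Default hyperparameters per classifier, merged with user overrides.
default_hyperparams <- function(classifier, n_features) {
  defaults <- switch(classifier,
    svm = list(kernel = "radial", cost = 1, gamma = 1 / n_features),
    knn = list(k = 5L),
    rf = list(ntree = 100L),
    stop("unknown classifier '", classifier,
         "'; supported: svm, knn, rf", call. = FALSE)
  )
  defaults
}

merge_hyperparams <- function(classifier, n_features, hyperparams) {
  hp <- default_hyperparams(classifier, n_features)
  for (nm in names(hyperparams)) hp[[nm]] <- hyperparams[[nm]]
  hp
}

# Fits one classifier on (x, y) and returns a closure predicting labels
# (+1/-1) and continuous positive-class scores on new rows.
fit_classifier <- function(classifier, x, y, hp) {
  if (nlevels(droplevels(y)) < 2L) {
    stop("training partition contains a single class", call. = FALSE)
  }
  switch(classifier,
    svm = {
      fit <- e1071::svm(x, y, kernel = hp$kernel, cost = hp$cost,
                        gamma = hp$gamma, scale = FALSE)
      function(newx) {
        pr <- stats::predict(fit, newx, decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        s <- dv[, 1]
        # orient decision values so larger = more positive-class
        if (colnames(dv)[1] == "neg/pos") s <- -s
        list(labels = ifelse(pr == "pos", 1L, -1L), scores = unname(s),
             fit = fit)
      }
    },
    knn = {
      function(newx) {
        pr <- class::knn(x, newx, y, k = hp$k, prob = TRUE)
        win <- attr(pr, "prob")
        s <- ifelse(pr == "pos", win, 1 - win)
        list(labels = ifelse(pr == "pos", 1L, -1L), scores = unname(s))
      }
    },
    rf = {
      fit <- randomForest::randomForest(x, y, ntree = hp$ntree)
      function(newx) {
        lab <- stats::predict(fit, newx, type = "response")
        s <- stats::predict(fit, newx, type = "prob")[, "pos"]
        list(labels = ifelse(lab == "pos", 1L, -1L), scores = unname(s),
             fit = fit)
      }
    }
  )
}

#' Confusion-count performance statistics
#'
#' Sensitivity Sn = TP/(TP+FN), specificity Sp = TN/(TN+FP), accuracy
#' Acc = (TP+TN)/n and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), with the
#' convention MCC = 0 when the denominator vanishes.
#'
#' @param TP,FN,TN,FP confusion counts.
#' @return named list with `TP`, `FN`, `TN`, `FP`, `Sn`, `Sp`, `Acc`,
#'   `MCC`.
#' @examples
#' confusion_metrics(TP = 40, FN = 10, TN = 35, FP = 15)$Acc  # 0.75
#' @export
confusion_metrics <- function(TP, FN, TN, FP) {
  TP <- as.numeric(TP); FN <- as.numeric(FN)
  TN <- as.numeric(TN); FP <- as.numeric(FP)
  n <- TP + FN + TN + FP
  stopifnot(n > 0)
  denom <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  list(
    TP = TP, FN = FN, TN = TN, FP = FP,
    Sn = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    Sp = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
    Acc = (TP + TN) / n,
    MCC = if (denom > 0) (TP * TN - FP * FN) / denom else 0
  )
}

#' ROC curve and AUC from decision scores
#'
#' The AUC is the rank (Mann-Whitney) probability that a positive outscores
#' a negative, with half credit for ties. The ROC is the step curve over
#' unique score thresholds, starting at (0,0) and ending at (1,1); tied
#' scores are grouped at one threshold, so trapezoidal integration of the
#' curve equals the rank AUC.
#'
#' @param scores numeric decision values, larger = more positive.
#' @param labels +1/-1 (or logical) true labels.
#' @return list with `roc` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @examples
#' roc_auc(c(3, 2, 1, 0), c(1, 1, -1, -1))$auc  # 1
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels > 0
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  r <- rank(scores)  # average ranks handle ties => +0.5 per tie
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) sum(scores >= t & pos) / n_pos,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(scores >= t & !pos) / n_neg,
                numeric(1))
  roc <- data.frame(threshold = c(Inf, thresholds),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  list(roc = roc, auc = auc)
}

#' Cross-validated evaluation of a classifier on RAAC features
#'
#' For each fold, the classifier is fit on the complement and the held-out
#' rows receive predicted labels (at the classifier's native decision
#' boundary) and continuous scores. Predictions are pooled over all folds
#' before computing the confusion counts, Sn/Sp/Acc/MCC, the ROC curve
#' over pooled scores, and its AUC; per-fold metrics are also retained.
#' The fold plan's seed drives classifier randomness.
#'
#' @param dataset a `raac_dataset` from [build_dataset()] /
#'   [dataset_from_sequences()].
#' @param fold_plan a [make_folds()] plan for the same rows.
#' @param classifier `"svm"`, `"knn"` or `"rf"`.
#' @param hyperparams named list overriding the defaults (SVM: radial
#'   kernel, `cost = 1`, `gamma = 1/n_features`; KNN: `k = 5`; RF:
#'   `ntree = 100`).
#' @return a `raac_cv` evaluation report: pooled confusion counts and
#'   Sn/Sp/Acc/MCC, `roc` points and `auc`, `per_fold` data frame, pooled
#'   `scores`/`predicted`/`labels`, plus classifier name, hyperparameters,
#'   tuple spec, scheme key and seed.
#' @export
cross_validate <- function(dataset, fold_plan,
                           classifier = c("svm", "knn", "rf"),
                           hyperparams = list()) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(dataset, "raac_dataset"),
            inherits(fold_plan, "fold_plan"))
  x <- dataset$features$matrix
  n <- nrow(x)
  if (length(fold_plan$assignments) != n) {
    stop("fold plan covers ", length(fold_plan$assignments),
         " rows but dataset has ", n, call. = FALSE)
  }
  y <- as_label_factor(dataset$labels)
  hp <- merge_hyperparams(classifier, ncol(x), hyperparams)
  pred <- integer(n)
  scores <- numeric(n)
  per_fold <- vector("list", fold_plan$n_folds)
  with_seed(fold_plan$seed, {
    for (f in seq_len(fold_plan$n_folds)) {
      test <- which(fold_plan$assignments == f)
      train <- setdiff(seq_len(n), test)
      predictor <- fit_classifier(classifier, x[train, , drop = FALSE],
                                  y[train], hp)
      out <- predictor(x[test, , drop = FALSE])
      pred[test] <- out$labels
      scores[test] <- out$scores
      fold_truth <- dataset$labels[test]
      per_fold[[f]] <- data.frame(
        fold = f, n = length(test),
        TP = sum(out$labels > 0 & fold_truth > 0),
        FN = sum(out$labels < 0 & fold_truth > 0),
        TN = sum(out$labels < 0 & fold_truth < 0),
        FP = sum(out$labels > 0 & fold_truth < 0)
      )
    }
  })
  truth <- dataset$labels
  m <- confusion_metrics(TP = sum(pred > 0 & truth > 0),
                         FN = sum(pred < 0 & truth > 0),
                         TN = sum(pred < 0 & truth < 0),
                         FP = sum(pred > 0 & truth < 0))
  rocres <- roc_auc(scores, truth)
  per_fold <- do.call(rbind, per_fold)
  per_fold$Acc <- (per_fold$TP + per_fold$TN) / per_fold$n
  structure(
    c(m,
      list(roc = rocres$roc, auc = rocres$auc, per_fold = per_fold,
           scores = scores, predicted = pred, labels = truth,
           classifier = classifier, hyperparams = hp,
           spec = dataset$features$spec,
           scheme_key = dataset$features$scheme_key,
           n_folds = fold_plan$n_folds, loo = fold_plan$loo,
           seed = fold_plan$seed)),
    class = "raac_cv"
  )
}

#' @export
print.raac_cv <- function(x, ...) {
  cat(sprintf("%s, %s cross-validation (seed %d)\n",
              toupper(x$classifier),
              if (x$loo) "leave-one-out" else paste0(x$n_folds, "-fold"),
              x$seed))
  cat(sprintf("  TP=%d FN=%d TN=%d FP=%d\n", x$TP, x$FN, x$TN, x$FP))
  cat(sprintf("  Sn=%.4f Sp=%.4f Acc=%.4f MCC=%.4f AUC=%.4f\n",
              x$Sn, x$Sp, x$Acc, x$MCC, x$auc))
  invisible(x)
}

MODEL_FORMAT_VERSION <- "raackit-model-1"

#' Train a classifier on a full dataset
#'
#' Fits the chosen classifier on every row of the dataset (no held-out
#' data); use [cross_validate()] for performance estimates.
#'
#' @inheritParams cross_validate
#' @param seed integer seed for classifier randomness.
#' @return a `raac_model`: list with the fitted backend, classifier name,
#'   hyperparameters, scheme key, tuple spec, seed, feature column names
#'   and a format version string.
#' @export
train_model <- function(dataset, classifier = c("svm", "knn", "rf"),
                        hyperparams = list(), seed = 42L) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(dataset, "raac_dataset"))
  x <- dataset$features$matrix
  y <- as_label_factor(dataset$labels)
  hp <- merge_hyperparams(classifier, ncol(x), hyperparams)
  payload <- with_seed(seed, {
    switch(classifier,
      svm = e1071::svm(x, y, kernel = hp$kernel, cost = hp$cost,
                       gamma = hp$gamma, scale = FALSE),
      knn = list(train = x, cl = y),  # KNN is instance-based
      rf = randomForest::randomForest(x, y, ntree = hp$ntree)
    )
  })
  structure(
    list(version = MODEL_FORMAT_VERSION, classifier = classifier,
         hyperparams = hp, payload = payload,
         scheme_key = dataset$features$scheme_key,
         spec = dataset$features$spec, seed = as.integer(seed),
         columns = colnames(x)),
    class = "raac_model"
  )
}

#' Predict with a trained RAAC model
#'
#' @param object a `raac_model`.
#' @param newdata numeric feature matrix with the model's columns (e.g.
#'   `extract_features(...)$matrix`).
#' @param ... unused.
#' @return list with `labels` (+1/-1) and `scores` (positive-class
#'   decision values).
#' @export
predict.raac_model <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (!identical(colnames(newdata), object$columns)) {
    stop("feature columns do not match the model (expected ",
         length(object$columns), " columns in scheme order)", call. = FALSE)
  }
  hp <- object$hyperparams
  switch(object$classifier,
    svm = {
      pr <- stats::predict(object$payload, newdata, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      s <- dv[, 1]
      if (colnames(dv)[1] == "neg/pos") s <- -s
      list(labels = ifelse(pr == "pos", 1L, -1L), scores = unname(s))
    },
    knn = {
      pr <- class::knn(object$payload$train, newdata, object$payload$cl,
                       k = hp$k, prob = TRUE)
      win <- attr(pr, "prob")
      s <- ifelse(pr == "pos", win, 1 - win)
      list(labels = ifelse(pr == "pos", 1L, -1L), scores = unname(s))
    },
    rf = {
      lab <- stats::predict(object$payload, newdata, type = "response")
      s <- stats::predict(object$payload, newdata, type = "prob")[, "pos"]
      list(labels = ifelse(lab == "pos", 1L, -1L), scores = unname(s))
    }
  )
}

#' Save a trained model to disk
#'
#' The artifact stores the model together with its metadata (classifier,
#' hyperparameters, scheme key, tuple spec, seed, format version) and an
#' md5 checksum of the payload, verified on load.
#'
#' @param model a `raac_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "raac_model"))
  artifact <- list(version = model$version, model = model,
                   payload_md5 = object_md5(model$payload))
  saveRDS(artifact, path, version = 2L)
  invisible(path)
}

#' Load a trained model from disk
#'
#' Fails on format-version mismatch or payload checksum mismatch rather
#' than silently reinterpreting the artifact.
#'
#' @param path path written by [save_model()].
#' @return a `raac_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  artifact <- readRDS(path)
  if (!is.list(artifact) || !identical(artifact$version, MODEL_FORMAT_VERSION)) {
    stop("unsupported model format (expected ", MODEL_FORMAT_VERSION, ")",
         call. = FALSE)
  }
  if (!identical(object_md5(artifact$model$payload), artifact$payload_md5)) {
    stop("model payload checksum mismatch; file corrupted or tampered",
         call. = FALSE)
  }
  artifact$model
}
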