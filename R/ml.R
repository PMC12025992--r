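#' The six features significant in the univariate multiple-comparison tests
#'
#' The fixed comparison arm for the classifiers: SAI, the three
#' amplitude-asymmetry parameters and the two absolute phase differences.
#'
#' @return Character vector of six feature names.
#' @export
mct_features <- function() {
  c("SAI", "AmplAsymWeighted", "AmplAsymAvg", "AmplAsymAvg_2/3",
    "AbsPhaseDiffAvg", "AbsPhaseDiffWeighted")
}

#' Derive task labels from the three-class diagnosis
#'
#' @param labels factor with levels Norm/Benign/Malignant.
#' @param task `"3class"`, `"lesion_vs_norm"` or `"malignant_vs_benign"`.
#' @return A factor: the original three classes, `Norm`/`Lesion`, or
#'   `Benign`/`Malignant` (rows of other classes dropped upstream); the
#'   positive class is the last level.
#' @export
task_labels <- function(labels, task = c("3class", "lesion_vs_norm",
                                         "malignant_vs_benign")) {
  task <- match.arg(task)
  labels <- factor(labels)
  switch(task,
    "3class" = labels,
    "lesion_vs_norm" = factor(ifelse(labels == "Norm", "Norm", "Lesion"),
                              levels = c("Norm", "Lesion")),
    "malignant_vs_benign" = {
      keep <- labels %in% c("Benign", "Malignant")
      f <- factor(as.character(labels), levels = c("Benign", "Malignant"))
      f[!keep] <- NA
      f
    }
  )
}

#' Fit a feature standardizer (z-score) on training data
#'
#' Stores per-feature mean and standard deviation (sample convention by
#' default) so held-out data can be standardized with the training
#' parameters, never its own.
#'
#' @param data data frame of training rows.
#' @param features feature column names.
#' @param convention `"sample"` (n-1 denominator) or `"population"`.
#' @return An object of class `standardizer` (`center`, `scale`, `features`).
#' @export
fit_standardizer <- function(data, features, convention = c("sample",
                                                            "population")) {
  convention <- match.arg(convention)
  x <- as.matrix(data[, features, drop = FALSE])
  ctr <- colMeans(x)
  sc <- apply(x, 2, sd)
  if (convention == "population") sc <- sc * sqrt((nrow(x) - 1) / nrow(x))
  bad <- which(sc < .Machine$double.eps^0.5)
  if (length(bad))
    abort(paste("constant feature column(s):",
                paste(features[bad], collapse = ", ")))
  structure(list(center = ctr, scale = sc, features = features,
                 convention = convention),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param std a `standardizer` from [fit_standardizer()].
#' @param data data frame containing the standardizer's features.
#' @return `data` with the feature columns replaced by their z-scores.
#' @export
apply_standardizer <- function(std, data) {
  stopifnot(inherits(std, "standardizer"))
  for (f in std$features)
    data[[f]] <- (data[[f]] - std$center[[f]]) / std$scale[[f]]
  data
}

#' Standardize feature columns in place
#'
#' Convenience wrapper: fits on `data` and applies to `data`; the transform
#' parameters are attached as attribute `"standardizer"` so they can be
#' re-applied to held-out data.
#'
#' @inheritParams fit_standardizer
#' @return Standardized tibble with attribute `"standardizer"`.
#' @export
standardize_features <- function(data, features,
                                 convention = c("sample", "population")) {
  std <- fit_standardizer(data, features, match.arg(convention))
  out <- apply_standardizer(std, data)
  attr(out, "standardizer") <- std
  out
}

# stratified fold assignment, deterministic given seed
stratified_folds <- function(labels, k, seed) {
  labels <- factor(labels)
  if (any(table(labels) < k))
    abort(sprintf("every class needs >= %d members for %d-fold stratification.",
                  k, k))
  set.seed(seed)
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train an RBF-kernel SVM with class-membership probabilities
#'
#' Binary tasks use a single probability-calibrated SVM (sigmoid fit on the
#' decision values); the three-class task uses one-vs-rest binary models,
#' assigning each case to the class with the highest (renormalized)
#' membership probability.
#'
#' @param data data frame of (already standardized) training rows.
#' @param features feature column names.
#' @param label label column name.
#' @param cost SVM cost parameter `C`, default 1.
#' @param gamma RBF kernel width; default `1 / n_features` (the conventional
#'   `1 / (p * var)` with unit-variance standardized features).
#' @param kernel `"radial"` (default) or `"linear"`.
#' @return An object of class `vf_svm`.
#' @export
train_svm <- function(data, features, label = "label", cost = 1,
                      gamma = NULL, kernel = "radial") {
  y <- factor(data[[label]])
  y <- droplevels(y)
  if (nlevels(y) < 2L) abort("labels contain a single class.")
  x <- as.matrix(data[, features, drop = FALSE])
  colnames(x) <- make.names(features)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  fit_one <- function(yy) {
    e1071::svm(x, yy, kernel = kernel, cost = cost, gamma = gamma,
               probability = TRUE, scale = FALSE)
  }
  models <- if (nlevels(y) == 2L) {
    list(binary = fit_one(y))
  } else {
    ms <- lapply(levels(y), function(lv)
      fit_one(factor(ifelse(y == lv, lv, "rest"), levels = c("rest", lv))))
    names(ms) <- levels(y)
    ms
  }
  structure(list(models = models, levels = levels(y), features = features,
                 cost = cost, gamma = gamma, kernel = kernel),
            class = "vf_svm")
}

#' Class-membership probabilities from a fitted SVM
#'
#' @param object a `vf_svm`.
#' @param newdata data frame with the model's features (standardized with
#'   the training standardizer).
#' @param ... unused.
#' @return Tibble of per-class probabilities (columns = class levels, rows
#'   sum to 1) with attribute `"class"` (the argmax prediction factor).
#' @export
predict.vf_svm <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  colnames(x) <- make.names(object$features)
  lev <- object$levels
  if (length(object$models) == 1L) {
    pr <- attr(predict(object$models$binary, x, probability = TRUE),
               "probabilities")
    p <- cbind(pr[, lev[1]], pr[, lev[2]])
  } else {
    p <- vapply(lev, function(lv) {
      pr <- attr(predict(object$models[[lv]], x, probability = TRUE),
                 "probabilities")
      pr[, lv]
    }, numeric(nrow(x)))
    if (is.null(dim(p))) p <- matrix(p, nrow = 1)
    p <- p / rowSums(p)
  }
  colnames(p) <- lev
  out <- as_tibble(as.data.frame(p, check.names = FALSE))
  attr(out, "class_pred") <- factor(lev[max.col(p, ties.method = "first")],
                                    levels = lev)
  out
}

# balanced accuracy of predictions vs truth
balanced_accuracy <- function(truth, pred) {
  truth <- factor(truth)
  pred <- factor(pred, levels = levels(truth))
  rec <- vapply(levels(truth), function(lv) {
    n <- sum(truth == lv)
    if (n == 0) return(NA_real_)
    sum(pred == lv & truth == lv) / n
  }, numeric(1))
  mean(rec, na.rm = TRUE)
}

# wrapper criterion: mean balanced accuracy of an RBF SVM under internal
# stratified k-fold CV with per-fold standardization
svm_cv_criterion <- function(data, features, label, folds, cost = 1,
                             gamma = NULL) {
  k <- max(folds)
  truth <- factor(data[[label]])
  pred <- factor(rep(NA_character_, nrow(data)), levels = levels(truth))
  for (f in seq_len(k)) {
    tr <- data[folds != f, , drop = FALSE]
    te <- data[folds == f, , drop = FALSE]
    std <- fit_standardizer(tr, features)
    m <- train_svm(apply_standardizer(std, tr), features, label,
                   cost = cost, gamma = gamma)
    pr <- predict(m, apply_standardizer(std, te))
    pred[folds == f] <- attr(pr, "class_pred")
  }
  balanced_accuracy(truth, pred)
}

#' Sequential floating forward selection (SFFS) of features
#'
#' Classic SFFS wrapper: start from the single best feature, then repeat an
#' inclusion step (add the feature maximizing the criterion) followed by
#' conditional exclusion steps (remove a feature while doing so beats the
#' best subset previously seen at that size). The criterion is the mean
#' balanced accuracy of an RBF-kernel SVM under internal stratified k-fold
#' cross-validation (fixed folds drawn once from `seed`, so the search is
#' deterministic). The search stops when `max_size` is reached or when
#' `patience` consecutive inclusion passes fail to improve the best subset
#' seen overall; the best subset overall is returned.
#'
#' @param data data frame with feature columns and a label column.
#' @param features candidate feature names (p >= 1).
#' @param label label column name.
#' @param folds number of internal CV folds.
#' @param seed integer seed (folds).
#' @param max_size largest subset size explored; default `min(p, 10)`.
#' @param patience non-improving inclusion passes tolerated before stopping.
#' @param cost,gamma SVM hyperparameters (see [train_svm()]).
#' @return An object of class `sffs_trace`: list with `selected` (character),
#'   `criterion` (its criterion value), and `trace` (tibble: `step`,
#'   `action`, `feature`, `size`, `criterion`, `accepted`).
#' @export
sffs_select <- function(data, features, label = "label", folds = 5,
                        seed = 1L, max_size = NULL, patience = 2L,
                        cost = 1, gamma = NULL) {
  p <- length(features)
  if (p < 1L) abort("need at least one candidate feature.")
  if (is.null(max_size)) max_size <- min(p, 10L)
  fold_id <- stratified_folds(data[[label]], folds, seed)
  cache <- new.env(parent = emptyenv())
  crit <- function(subset) {
    key <- paste(sort(subset), collapse = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- svm_cv_criterion(data, subset, label, fold_id, cost, gamma)
    cache[[key]] <- v
    v
  }
  trace <- list()
  note <- function(step, action, feature, size, criterion, accepted) {
    trace[[length(trace) + 1L]] <<- tibble(
      step = step, action = action, feature = feature, size = size,
      criterion = criterion, accepted = accepted
    )
  }
  best_by_size <- rep(-Inf, max_size) # best criterion seen at each size
  best_subset_by_size <- vector("list", max_size)
  best_overall <- -Inf
  best_overall_subset <- character()
  current <- character()
  step <- 0L
  stale <- 0L
  while (length(current) < max_size) {
    # inclusion
    cand <- setdiff(features, current)
    if (!length(cand)) break
    vals <- vapply(cand, function(f) crit(c(current, f)), numeric(1))
    add <- cand[which.max(vals)]
    current <- c(current, add)
    v <- max(vals)
    step <- step + 1L
    k <- length(current)
    improved <- v > best_overall + 1e-12
    note(step, "add", add, k, v, improved)
    if (v > best_by_size[k]) {
      best_by_size[k] <- v
      best_subset_by_size[[k]] <- current
    }
    if (improved) {
      best_overall <- v
      best_overall_subset <- current
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
    # conditional exclusion
    while (length(current) > 2L) {
      vals_rm <- vapply(current, function(f)
        crit(setdiff(current, f)), numeric(1))
      drop_f <- current[which.max(vals_rm)]
      v_rm <- max(vals_rm)
      k1 <- length(current) - 1L
      if (v_rm > best_by_size[k1] + 1e-12 && drop_f != add) {
        current <- setdiff(current, drop_f)
        step <- step + 1L
        improved <- v_rm > best_overall + 1e-12
        note(step, "remove", drop_f, k1, v_rm, improved)
        best_by_size[k1] <- v_rm
        best_subset_by_size[[k1]] <- current
        if (improved) {
          best_overall <- v_rm
          best_overall_subset <- current
          stale <- 0L
        }
      } else break
    }
  }
  if (!length(best_overall_subset)) { # p == 1 or nothing improved
    vals <- vapply(features, function(f) crit(f), numeric(1))
    best_overall_subset <- features[which.max(vals)]
    best_overall <- max(vals)
  }
  structure(
    list(selected = best_overall_subset, criterion = best_overall,
         trace = dplyr::bind_rows(trace), folds = folds, seed = seed),
    class = "sffs_trace"
  )
}

#' @export
print.sffs_trace <- function(x, ...) {
  cat(sprintf("<sffs_trace> %d feature(s) selected (criterion %.3f):\n  %s\n",
              length(x$selected), x$criterion,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' @describeIn sffs_select the search trace as a tibble.
#' @param x an `sffs_trace`.
#' @param ... unused.
#' @method tidy sffs_trace
#' @export
tidy.sffs_trace <- function(x, ...) x$trace

#' Cross-validated evaluation of the SVM classifier
#'
#' Stratified k-fold cross-validation for one of the three diagnostic tasks.
#' Inside every fold the standardizer is fitted on the training part only
#' (and, with `select = "sffs"`, so is the feature search); out-of-fold
#' predictions are pooled into the confusion matrix and per-class recalls,
#' and for binary tasks each fold's out-of-fold ROC AUC is recorded.
#'
#' @param data cohort tibble with feature columns and a `label` column
#'   (levels Norm/Benign/Malignant).
#' @param features feature names used (ignored rows with `select = "sffs"`
#'   pick their own inside each fold, from this candidate set).
#' @param task see [task_labels()].
#' @param k number of folds, default 5.
#' @param seed integer seed (fold assignment and SFFS).
#' @param select `"none"` (fixed `features`) or `"sffs"`.
#' @param cost,gamma SVM hyperparameters.
#' @return An object of class `classifier_report`: confusion matrix (counts
#'   and row-normalized %), per-class recall, balanced accuracy, per-fold and
#'   mean AUC (binary tasks), pooled out-of-fold probabilities, the scheme
#'   (k, seed, hyperparameters, feature arm).
#' @export
evaluate_cv <- function(data, features, task = "3class", k = 5, seed = 1L,
                        select = c("none", "sffs"), cost = 1, gamma = NULL) {
  select <- match.arg(select)
  y <- task_labels(data$label, task)
  keep <- !is.na(y)
  data <- data[keep, , drop = FALSE]
  y <- droplevels(y[keep])
  data$.task_label <- y
  fold_id <- stratified_folds(y, k, seed)
  lev <- levels(y)
  prob <- matrix(NA_real_, nrow(data), length(lev),
                 dimnames = list(NULL, lev))
  pred <- factor(rep(NA_character_, nrow(data)), levels = lev)
  fold_auc <- rep(NA_real_, k)
  fold_features <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- data[fold_id != f, , drop = FALSE]
    te <- data[fold_id == f, , drop = FALSE]
    feats <- features
    if (select == "sffs") {
      feats <- sffs_select(tr, features, label = ".task_label",
                           folds = min(5, k), seed = seed + f,
                           cost = cost, gamma = gamma)$selected
    }
    std <- fit_standardizer(tr, feats)
    m <- train_svm(apply_standardizer(std, tr), feats,
                   label = ".task_label", cost = cost, gamma = gamma)
    pr <- predict(m, apply_standardizer(std, te))
    prob[fold_id == f, ] <- as.matrix(pr)
    pred[fold_id == f] <- attr(pr, "class_pred")
    fold_features[[f]] <- feats
    if (length(lev) == 2L) {
      te_y <- y[fold_id == f]
      if (length(unique(te_y)) == 2L) {
        fold_auc[f] <- empirical_roc(as.matrix(pr)[, lev[2]],
                                     te_y == lev[2])$auc
      }
    }
  }
  cm <- table(truth = y, predicted = pred)
  recall <- diag(cm) / rowSums(cm)
  report <- list(
    task = task, confusion = cm,
    confusion_pct = 100 * sweep(cm, 1, rowSums(cm), "/"),
    recall = recall, balanced_accuracy = mean(recall),
    fold_auc = fold_auc,
    mean_auc = if (length(lev) == 2L) mean(fold_auc, na.rm = TRUE) else NA_real_,
    pooled_auc = if (length(lev) == 2L)
      empirical_roc(prob[, lev[2]], y == lev[2])$auc else NA_real_,
    probabilities = prob, predicted = pred, truth = y,
    sensitivity = if (length(lev) == 2L) unname(recall[lev[2]]) else NA_real_,
    specificity = if (length(lev) == 2L) unname(recall[lev[1]]) else NA_real_,
    k = k, seed = seed, features = features, fold_features = fold_features,
    select = select, cost = cost,
    gamma = gamma %||% (1 / length(features))
  )
  structure(report, class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> task %s, %d-fold CV (seed %d, %s features)\n",
              x$task, x$k, x$seed, x$select))
  print(x$confusion)
  cat(sprintf("balanced accuracy %.3f", x$balanced_accuracy))
  if (!is.na(x$mean_auc)) cat(sprintf(", mean fold AUC %.3f", x$mean_auc))
  cat("\n")
  invisible(x)
}

#' @describeIn evaluate_cv one-row performance summary.
#' @param x a `classifier_report`.
#' @param ... unused.
#' @method glance classifier_report
#' @export
glance.classifier_report <- function(x, ...) {
  tibble(task = x$task, balanced_accuracy = x$balanced_accuracy,
         mean_auc = x$mean_auc, pooled_auc = x$pooled_auc,
         sensitivity = x$sensitivity, specificity = x$specificity,
         k = x$k, seed = x$seed, select = x$select)
}

#' @describeIn evaluate_cv confusion matrix in long form (`truth`,
#'   `predicted`, `count`, `pct` of the truth row).
#' @method tidy classifier_report
#' @export
tidy.classifier_report <- function(x, ...) {
  counts <- as.data.frame(x$confusion, responseName = "count")
  pcts <- as.data.frame(x$confusion_pct, responseName = "pct")
  as_tibble(dplyr::left_join(counts, pcts, by = c("truth", "predicted")))
}

#' Training-set (optimistic) bootstrap ROC of a fitted binary SVM
#'
#' Scores the training data with the fitted model's positive-class
#' probability and runs [bootstrap_roc()] on it. In-sample ROC estimates are
#' optimistic; the result is flagged accordingly.
#'
#' @param model a binary `vf_svm`.
#' @param data the (standardized) training data with a label column.
#' @param label label column name.
#' @param b,seed see [bootstrap_roc()].
#' @return An `roc_boot` with attribute `"optimistic" = TRUE`.
#' @export
roc_training_set <- function(model, data, label = "label", b = 1000,
                             seed = 1L) {
  stopifnot(inherits(model, "vf_svm"))
  if (length(model$levels) != 2L) abort("training-set ROC needs a binary task.")
  pr <- predict(model, data)
  pos_lev <- model$levels[2]
  roc <- bootstrap_roc(as.matrix(pr)[, pos_lev], data[[label]],
                       positive = pos_lev, b = b, seed = seed)
  attr(roc, "optimistic") <- TRUE
  roc
}
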