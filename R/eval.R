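#' Cost-sensitive RBF-SVM specification
#'
#' The soft-margin objective carries separate misclassification costs for
#' the two classes: `cost_pos` (C+) for the positive class (the `start` /
#' `stop` intention windows) and `cost_neg` (C-) for the negative class
#' (`rest` / `walk`). Setting C+ above C- penalizes missed intentions more
#' than false alarms during training. With `cost_pos == cost_neg` the
#' machine is the standard unweighted SVM at that cost.
#'
#' @param gamma RBF kernel width; `NULL` means `1 / (n_features * mean
#'   feature variance)`, which is `1 / n_features` for standardized
#'   features.
#' @param cost_pos,cost_neg positive / negative class costs (> 0).
#' @export
svm_spec <- function(gamma = NULL, cost_pos = 2, cost_neg = 1) {
  assert_that(cost_pos > 0 && cost_neg > 0, "costs must be positive")
  assert_that(is.null(gamma) || gamma > 0, "gamma must be positive")
  structure(list(gamma = gamma, cost_pos = cost_pos, cost_neg = cost_neg),
            class = "gi_svm_spec")
}

#' Train a cost-sensitive RBF-kernel SVM
#'
#' @param features numeric samples x features matrix.
#' @param labels class labels (two levels).
#' @param positive label of the positive (intention) class.
#' @param spec an [svm_spec()].
#' @return Fitted model (class `gi_svm`).
#' @export
train_cost_svm <- function(features, labels, positive, spec = svm_spec()) {
  X <- as.matrix(features)
  y <- factor(as.character(labels))
  assert_that(nlevels(y) == 2, "need exactly two classes")
  assert_that(positive %in% levels(y), "positive class not present")
  gamma <- spec$gamma %||% (1 / (ncol(X) * mean(apply(X, 2, stats::var))))
  wts <- stats::setNames(
    ifelse(levels(y) == positive, spec$cost_pos, spec$cost_neg), levels(y))
  fit <- e1071::svm(x = X, y = y, type = "C-classification",
                    kernel = "radial", gamma = gamma, cost = 1,
                    class.weights = wts, scale = FALSE)
  structure(list(fit = fit, positive = positive, gamma = gamma, spec = spec),
            class = "gi_svm")
}

#' @export
predict.gi_svm <- function(object, newdata, ...) {
  stats::predict(object$fit, as.matrix(newdata))
}

confusion_counts <- function(truth, pred, positive) {
  truth_pos <- truth == positive
  pred_pos <- pred == positive
  list(TP = sum(truth_pos & pred_pos), TN = sum(!truth_pos & !pred_pos),
       FP = sum(!truth_pos & pred_pos), FN = sum(truth_pos & !pred_pos))
}

# stratified fold assignment: within each class, shuffle then deal
# round-robin, so fold class counts are balanced within one
stratified_folds <- function(labels, folds, seed) {
  with_rng(seed, {
    assign <- integer(length(labels))
    for (lv in levels(factor(labels))) {
      idx <- sample(which(labels == lv))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
    assign
  })
}

#' Stratified k-fold cross-validation of the full decoding chain
#'
#' Splits samples into stratified folds; in each round the held-out fold is
#' scored by a model fitted on the remaining folds. Feature
#' standardization (z-scoring) and, when `selection_scope = "per_fold"`,
#' redundancy-penalized feature selection are refit on the training folds
#' only, so no test-fold information leaks into the model. With
#' `selection_scope = "global"` selection is done once on all data before
#' splitting (provided for comparison; it leaks).
#'
#' @param features samples x features matrix.
#' @param labels two-level labels, one per row.
#' @param positive positive-class label.
#' @param folds fold count (>= 2); every class needs at least `folds`
#'   members.
#' @param seed integer seed for the fold shuffle.
#' @param spec an [svm_spec()].
#' @param k,beta feature-selection size and redundancy exponent.
#' @param selection_scope `"per_fold"` or `"global"`.
#' @param standardize z-score features with training-fold statistics.
#' @return List of per-fold confusion-count lists (TP, TN, FP, FN).
#' @export
crossval <- function(features, labels, positive, folds = 10, seed = 1,
                     spec = svm_spec(), k = 20, beta = 1,
                     selection_scope = c("per_fold", "global"),
                     standardize = TRUE) {
  selection_scope <- match.arg(selection_scope)
  X <- as.matrix(features)
  y <- factor(as.character(labels))
  assert_that(all(table(y) >= folds),
              "every class needs at least as many samples as folds")
  if (selection_scope == "global") {
    sel <- select_features(X, y, k = k, beta = beta)
    X <- X[, sel$selected, drop = FALSE]
  }
  assign <- stratified_folds(y, folds, seed)
  lapply(seq_len(folds), function(f) {
    tr <- assign != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xte <- X[!tr, , drop = FALSE]; yte <- y[!tr]
    if (standardize) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2, stats::sd)
      sdv[!is.finite(sdv) | sdv == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, `/`)
      Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, `/`)
    }
    if (selection_scope == "per_fold") {
      sel <- select_features(Xtr, ytr, k = k, beta = beta)
      Xtr <- Xtr[, sel$selected, drop = FALSE]
      Xte <- Xte[, sel$selected, drop = FALSE]
    }
    model <- train_cost_svm(Xtr, ytr, positive, spec)
    confusion_counts(yte, predict(model, Xte), positive)
  })
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)` and specificity
#' `TN/(TN+FP)`, in percent. A metric whose denominator is empty is
#' reported as `NA`.
#' @param confusion list with TP, TN, FP, FN (a single fold or summed
#'   counts).
#' @return Named numeric vector (percent).
#' @export
classification_metrics <- function(confusion) {
  with(confusion, {
    total <- TP + TN + FP + FN
    assert_that(total > 0, "empty confusion table")
    c(accuracy = 100 * (TP + TN) / total,
      sensitivity = if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_,
      specificity = if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_)
  })
}

sum_confusions <- function(confusions) {
  Reduce(function(a, b) Map(`+`, a, b), confusions)
}

#' Trial rate
#'
#' Number of negative-class (rest or walk) trials per minute of recording,
#' reported to two decimals.
#' @param n_trials trial count.
#' @param minutes total recording time (min).
#' @export
trials_per_minute <- function(n_trials, minutes) {
  assert_that(minutes > 0, "duration must be positive")
  round(n_trials / minutes, 2)
}

#' False positives per minute
#'
#' The false-positive rate `FP / (TN + FP)` scaled by the frequency of
#' negative trials: false intention detections per minute.
#' @param confusions a single confusion list or a list of per-fold lists.
#' @param trials_per_min negative-trial rate (per minute).
#' @export
fp_per_min <- function(confusions, trials_per_min) {
  if (!is.null(confusions$TP)) confusions <- list(confusions)
  cc <- sum_confusions(confusions)
  assert_that(cc$TN + cc$FP > 0, "no negative trials")
  cc$FP / (cc$TN + cc$FP) * trials_per_min
}

#' Cross-subject aggregation
#'
#' Arithmetic mean and sample standard deviation (n - 1) of per-subject
#' metric values.
#' @param per_subject numeric vector of per-subject values (>= 2 unless
#'   `allow_single`).
#' @return Named vector `c(mean, sd)`.
#' @export
aggregate_metrics <- function(per_subject) {
  per_subject <- per_subject[!is.na(per_subject)]
  assert_that(length(per_subject) >= 2, "need at least two subjects")
  c(mean = mean(per_subject), sd = stats::sd(per_subject))
}

#' Compare trans-event and pre-event windows
#'
#' For every (trans, pre) window pair within a classification problem, a
#' one-tailed two-sample t-test of per-subject accuracies (H1: trans-event
#' mean exceeds pre-event mean), with Holm step-down correction over the
#' pair family. Both the raw and the Holm-adjusted decisions at `alpha`
#' are returned.
#'
#' @param accuracies_by_window named list of per-subject accuracy vectors,
#'   one per window name; vectors must have equal length.
#' @param trans_specs,pre_specs window names treated as trans-event and
#'   pre-event.
#' @param alpha significance level.
#' @param var_equal pooled-variance (Student) test when `TRUE` (default);
#'   Welch otherwise.
#' @return data.frame with one row per pair: `trans`, `pre`, `t`, `p_raw`,
#'   `p_holm`, `reject_raw`, `reject_holm`.
#' @export
compare_windows <- function(accuracies_by_window, trans_specs, pre_specs,
                            alpha = 0.05, var_equal = TRUE) {
  assert_that(all(c(trans_specs, pre_specs) %in% names(accuracies_by_window)),
              "window names missing from the accuracy list")
  lens <- lengths(accuracies_by_window[c(trans_specs, pre_specs)])
  assert_that(length(unique(lens)) == 1, "unequal subject counts")
  assert_that(lens[1] >= 2, "need at least two subjects")
  grid <- expand.grid(pre = pre_specs, trans = trans_specs,
                      stringsAsFactors = FALSE)[, c("trans", "pre")]
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    tt <- stats::t.test(accuracies_by_window[[grid$trans[i]]],
                        accuracies_by_window[[grid$pre[i]]],
                        alternative = "greater", var.equal = var_equal)
    data.frame(trans = grid$trans[i], pre = grid$pre[i],
               t = unname(tt$statistic), p_raw = tt$p.value)
  }))
  res$p_holm <- stats::p.adjust(res$p_raw, method = "holm")
  res$reject_raw <- res$p_raw < alpha
  res$reject_holm <- res$p_holm < alpha
  res
}
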