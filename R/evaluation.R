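# Confusion-matrix metrics and stratified k-fold cross-validation.
# Class 1 (disease present) is the positive class throughout.

#' Confusion counts for binary predictions
#' @param y_true,y_pred Equal-length 0/1 label vectors.
#' @return List of counts `tp`, `fp`, `tn`, `fn` (summing to n).
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  if (!all(y_true %in% 0:1) || !all(y_pred %in% 0:1)) {
    stop("labels must be 0/1", call. = FALSE)
  }
  list(tp = sum(y_true == 1 & y_pred == 1),
       fp = sum(y_true == 0 & y_pred == 1),
       tn = sum(y_true == 0 & y_pred == 0),
       fn = sum(y_true == 1 & y_pred == 0))
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Standard metrics from confusion counts
#'
#' Accuracy, precision, sensitivity (TPR), false-positive rate,
#' specificity and F-score. Any 0/0 ratio is reported as 0 and the
#' affected metric names are listed in the `undefined` attribute.
#'
#' @param counts A list with `tp`, `fp`, `tn`, `fn` (see [confusion()]).
#' @return Named numeric vector of the six metrics.
#' @export
compute_metrics <- function(counts) {
  with(counts, {
    n <- tp + fp + tn + fn
    if (n == 0) stop("no evaluated samples", call. = FALSE)
    undefined <- character(0)
    if (tp + fp == 0) undefined <- c(undefined, "precision")
    if (tp + fn == 0) undefined <- c(undefined, "tpr")
    if (fp + tn == 0) undefined <- c(undefined, "fpr", "specificity")
    precision <- safe_ratio(tp, tp + fp)
    tpr <- safe_ratio(tp, tp + fn)
    f <- safe_ratio(2 * precision * tpr, precision + tpr)
    if (precision + tpr == 0) undefined <- c(undefined, "f_score")
    out <- c(accuracy = (tp + tn) / n,
             precision = precision,
             tpr = tpr,
             fpr = safe_ratio(fp, fp + tn),
             specificity = safe_ratio(tn, tn + fp),
             f_score = f)
    structure(out, undefined = unique(undefined))
  })
}

#' Metrics of a prediction vector
#' @inheritParams confusion
#' @return As [compute_metrics()].
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  compute_metrics(confusion(y_true, y_pred))
}

#' Stratified k-fold cross-validation of a pipeline
#'
#' Partitions the samples into k class-stratified folds (seeded); each
#' fold serves once as the test set while the pipeline is fit on the
#' remainder. The pipeline is a function
#' `function(X_train, y_train, X_test, fold_seed)` returning 0/1
#' predictions for `X_test`; any resampling it performs therefore stays
#' inside the training fold. Reported metrics are the per-fold means.
#'
#' @param pipeline Fitting/predicting function as described above.
#' @param X Numeric design matrix.
#' @param y 0/1 labels.
#' @param k Number of folds (2 <= k <= n).
#' @param seed Integer seed for the fold assignment.
#' @return List with `mean` (named metric vector) and `folds` (per-fold
#'   metric rows), plus the fold assignment.
#' @export
kfold_evaluate <- function(pipeline, X, y, k = 10L, seed = 1L) {
  n <- nrow(X)
  if (k < 2 || k > n) stop("k must lie in 2..n", call. = FALSE)
  folds <- with_seed(seed,
    caret::createFolds(factor(y), k = k, list = TRUE, returnTrain = FALSE))
  per_fold <- matrix(NA_real_, nrow = k, ncol = 6,
                     dimnames = list(NULL, c("accuracy", "precision", "tpr",
                                             "fpr", "specificity",
                                             "f_score")))
  for (f in seq_len(k)) {
    test <- folds[[f]]
    pred <- pipeline(X[-test, , drop = FALSE], y[-test],
                     X[test, , drop = FALSE], derive_seed(seed, f))
    per_fold[f, ] <- evaluate_predictions(y[test], pred)
  }
  list(mean = colMeans(per_fold), folds = per_fold,
       assignment = folds)
}

#' Format a train/test metric table
#' @param train,test Metric vectors from [compute_metrics()].
#' @return A character vector of table lines.
#' @export
format_metric_table <- function(train, test) {
  rows <- names(train)
  c(sprintf("%-12s %8s %8s", "metric", "train", "test"),
    vapply(rows, function(m) sprintf("%-12s %8.4f %8.4f", m,
                                     train[[m]], test[[m]]),
           character(1)))
}
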