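# Instance-level baseline classifiers: stratified k-fold cross-validation of
# standard learners on individual 100 ms MAV instances, with per-fold
# train-only z-normalization.

#' Stratified cross-validation folds
#'
#' Assigns instances to `folds` groups so that each class's instances are
#' spread as evenly as possible (each fold's class count is within one of any
#' other fold's).
#'
#' @param labels Character vector of class labels.
#' @param folds Number of folds.
#' @return Integer fold assignment, same length as `labels`.
#' @export
stratified_folds <- function(labels, folds = 10) {
  labels <- as.character(labels)
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Run one baseline classifier under stratified cross-validation
#'
#' The comparative harness for instance-level recognition: each 100 ms MAV
#' 8-tuple is classified in isolation. Channels are z-normalized per fold
#' with training-fold statistics only. Methods: `"tree"` (CART decision
#' tree), `"knn"` (1-NN, normalized Euclidean), `"rf"` (random forest, 25
#' trees), `"svm"` (RBF-kernel SVM, cost 5).
#'
#' @param x Instances x 8 MAV matrix (unnormalized).
#' @param labels Character class labels.
#' @param method One of `"rf"`, `"tree"`, `"knn"`, `"svm"`.
#' @param folds Number of stratified folds (default 10).
#' @param seed Optional seed for fold assignment and stochastic learners.
#' @param ntree Forest size for `"rf"`.
#' @param cost SVM regularization for `"svm"`.
#' @param k Neighbor count for `"knn"`.
#' @return List with `accuracy` (percent), `tpr` (per-class percent),
#'   `confusion` (rows = truth) and `method`.
#' @export
run_baseline <- function(x, labels, method = c("rf", "tree", "knn", "svm"),
                         folds = 10, seed = NULL, ntree = 25, cost = 5,
                         k = 1) {
  method <- match.arg(method)
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  counts <- table(labels)
  if (any(counts < folds))
    stop("class(es) with fewer than ", folds, " instances: ",
         paste(names(counts)[counts < folds], collapse = ", "),
         call. = FALSE)
  classes <- intersect(activity_codes(), unique(labels))
  run_cv <- function() {
    fold_id <- stratified_folds(labels, folds)
    pred <- character(length(labels))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      st <- fit_channel_stats(x[tr, , drop = FALSE])
      xtr <- apply_zscore(x[tr, , drop = FALSE], st)
      xte <- apply_zscore(x[!tr, , drop = FALSE], st)
      ytr <- factor(labels[tr], levels = classes)
      p <- switch(method,
        rf = {
          fit <- randomForest::randomForest(xtr, ytr, ntree = ntree)
          as.character(predict(fit, xte))
        },
        tree = {
          df_tr <- data.frame(y = ytr, xtr)
          df_te <- data.frame(xte)
          names(df_te) <- names(df_tr)[-1L]
          fit <- rpart::rpart(y ~ ., data = df_tr, method = "class")
          as.character(predict(fit, df_te, type = "class"))
        },
        knn = as.character(class::knn(xtr, xte, ytr, k = k)),
        svm = {
          fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = cost)
          as.character(predict(fit, xte))
        })
      pred[!tr] <- p
    }
    pred
  }
  pred <- if (is.null(seed)) run_cv() else with_seed(seed, run_cv())
  rep_eval <- eval_report(pred, labels, classes)
  c(rep_eval, list(method = method))
}
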