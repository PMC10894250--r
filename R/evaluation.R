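#' Confusion counts
#'
#' Standard 2x2 table with label 1 as the positive class.
#'
#' @param y_true,y_pred equal-length 0/1 label vectors.
#' @return object of class `confusion_counts`: `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) stop("labels must be 0/1")
  structure(list(TP = sum(y_true == 1L & y_pred == 1L),
                 TN = sum(y_true == 0L & y_pred == 0L),
                 FP = sum(y_true == 0L & y_pred == 1L),
                 FN = sum(y_true == 1L & y_pred == 0L)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes the five headline metrics: accuracy `(TP+TN)/total`, precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, `F1 = 2 P R/(P+R)`, and the
#' single-threshold AUC `(1 + TPR - FPR)/2` — algebraically identical to
#' balanced accuracy, computed from predicted labels at one threshold
#' rather than from ranked scores. Zero denominators map to 0 by
#' convention.
#'
#' @param cc a [confusion_counts()].
#' @return object of class `metric_set`: `accuracy`, `precision`, `recall`,
#'   `f1`, `auc_single_threshold`, `tpr`, `fpr`.
#' @export
compute_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  total <- cc$TP + cc$TN + cc$FP + cc$FN
  if (total == 0) stop("empty confusion counts")
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(cc$TP, cc$TP + cc$FP)
  recall <- safe_div(cc$TP, cc$TP + cc$FN)
  fpr <- safe_div(cc$FP, cc$FP + cc$TN)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  structure(list(accuracy = (cc$TP + cc$TN) / total, precision = precision,
                 recall = recall, f1 = f1,
                 auc_single_threshold = (1 + recall - fpr) / 2,
                 tpr = recall, fpr = fpr),
            class = "metric_set")
}

#' Rank-based ROC AUC (diagnostic, non-headline)
#'
#' Conventional Mann-Whitney AUC from continuous scores, offered as a
#' diagnostic alongside the single-threshold formula; the two are not the
#' same quantity.
#'
#' @param y_true 0/1 labels.
#' @param scores continuous scores, higher = more positive.
#' @return AUC in `[0,1]`.
#' @export
roc_auc_scores <- function(y_true, scores) {
  pos <- scores[y_true == 1]; neg <- scores[y_true == 0]
  if (length(pos) == 0 || length(neg) == 0) stop("need both classes")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Classifier registry
#'
#' The ten-model benchmark harness. Eight models are implemented in-package
#' with the study's default hyperparameters: AdaBoost (50 depth-1 stumps,
#' learning rate 1), decision tree (depth 3), k-NN (k = 3, Euclidean),
#' MLP (one hidden layer of 100 relu units, Adam), Gaussian naive Bayes
#' (var_smoothing 1e-9), random forest (100 trees, depth 5), gradient
#' boosted trees (100 rounds, depth 6, learning rate 0.3), and a linear SVM
#' with balanced class weights; an L1-logistic reference model (glmnet)
#' is included as well. The recurrent and LSTM networks require a
#' deep-learning backend and are registered as disabled plugins.
#'
#' @param enabled_only drop disabled entries. Default FALSE.
#' @return named list of classifier specs (`name`, `hyper`, `enabled`,
#'   `note`, `fit`, `predict`).
#' @export
classifier_registry <- function(enabled_only = FALSE) {
  reg <- list(
    adaboost = list(
      hyper = list(n_estimators = 50L, max_depth = 1L, learning_rate = 1),
      fit = fit_adaboost, predict = predict_adaboost, enabled = TRUE,
      note = "SAMME with depth-1 stumps"),
    decision_tree = list(
      hyper = list(max_depth = 3L),
      fit = fit_decision_tree, predict = predict_decision_tree,
      enabled = TRUE, note = "CART, Gini"),
    knn = list(
      hyper = list(n_neighbors = 3L),
      fit = fit_knn, predict = predict_knn, enabled = TRUE,
      note = "Euclidean, uniform weights"),
    mlp = list(
      hyper = list(hidden_layer_sizes = 100L, learning_rate_init = 1e-3,
                   max_iter = 30L),
      fit = fit_mlp, predict = predict_mlp, enabled = TRUE,
      note = "1 hidden layer, relu, Adam"),
    naive_bayes = list(
      hyper = list(var_smoothing = 1e-9),
      fit = fit_naive_bayes, predict = predict_naive_bayes, enabled = TRUE,
      note = "Gaussian"),
    random_forest = list(
      hyper = list(n_estimators = 100L, max_depth = 5L),
      fit = fit_random_forest, predict = predict_random_forest,
      enabled = TRUE, note = "bagged CART, mtry = floor(sqrt(d))"),
    gradient_boosting = list(
      hyper = list(n_estimators = 100L, learning_rate = 0.3, max_depth = 6L),
      fit = fit_gradient_boosting, predict = predict_gradient_boosting,
      enabled = TRUE, note = "logistic loss"),
    svm_linear = list(
      hyper = list(C = 1),
      fit = fit_svm_linear, predict = predict_svm_linear, enabled = TRUE,
      note = "squared hinge, balanced class weights"),
    l1_logistic = list(
      hyper = list(C = 1),
      fit = fit_l1_logistic_clf, predict = predict_l1_logistic_clf,
      enabled = TRUE, note = "glmnet, lasso penalty"),
    rnn = list(
      hyper = list(units = 32L, epochs = 20L, batch_size = 32L),
      fit = NULL, predict = NULL, enabled = FALSE,
      note = "requires a deep-learning backend; disabled plugin"),
    lstm = list(
      hyper = list(units = 50L, layers = 7L, epochs = 75L, batch_size = 32L),
      fit = NULL, predict = NULL, enabled = FALSE,
      note = "requires a deep-learning backend; disabled plugin (7 stacked layers as published; unusually deep for n of a few hundred)")
  )
  for (nm in names(reg)) reg[[nm]]$name <- nm
  if (enabled_only) reg <- Filter(function(e) e$enabled, reg)
  reg
}

#' Fit the registry classifiers on masked features and score the test set
#'
#' Each enabled classifier is fitted on the mask-restricted training
#' columns and its predicted labels on the mask-restricted test columns are
#' reduced to a [metric_set()]. A classifier that errors is recorded with
#' `status = "error"`; disabled plugins are recorded as `"skipped"`; the
#' rest proceed.
#'
#' @param train,test [tabular_dataset()]s with identical columns.
#' @param mask 0/1 feature mask (nonempty).
#' @param specs registry subset from [classifier_registry()].
#' @param seed integer seed fanned out per classifier.
#' @return data.frame with columns classifier, status, accuracy, precision,
#'   recall, f1, auc.
#' @export
evaluate_models <- function(train, test, mask,
                            specs = classifier_registry(), seed = 0L) {
  stopifnot(inherits(train, "tabular_dataset"), inherits(test, "tabular_dataset"))
  mask <- as.integer(mask)
  if (sum(mask) == 0L) stop("validation error: mask must be nonempty")
  if (length(specs) == 0L) stop("validation error: no classifier specs")
  Xtr <- train$features[, mask == 1L, drop = FALSE]
  Xte <- test$features[, mask == 1L, drop = FALSE]
  rows <- lapply(specs, function(sp) {
    base <- data.frame(classifier = sp$name, status = "ok",
                       accuracy = NA_real_, precision = NA_real_,
                       recall = NA_real_, f1 = NA_real_, auc = NA_real_,
                       stringsAsFactors = FALSE)
    if (!sp$enabled) { base$status <- "skipped"; return(base) }
    res <- tryCatch({
      model <- sp$fit(Xtr, train$target, sp$hyper,
                      derive_seed(seed, match(sp$name, names(specs))))
      pred <- sp$predict(model, Xte)
      ms <- compute_metrics(confusion_counts(test$target, pred))
      base$accuracy <- ms$accuracy; base$precision <- ms$precision
      base$recall <- ms$recall; base$f1 <- ms$f1
      base$auc <- ms$auc_single_threshold
      base
    }, error = function(e) { base$status <- conditionMessage(e); base })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average metric tables over repeated runs
#'
#' Arithmetic mean per (classifier, metric) across tables from repeated
#' evaluations, the multi-run averaging used for reporting.
#'
#' @param tables list of data.frames from [evaluate_models()] with
#'   identical classifier sets.
#' @return one data.frame of the same shape with averaged metrics.
#' @export
average_over_runs <- function(tables) {
  stopifnot(length(tables) >= 1)
  ref <- tables[[1]]$classifier
  for (tb in tables) {
    if (!identical(tb$classifier, ref)) stop("mismatched classifier sets")
  }
  out <- tables[[1]]
  for (col in c("accuracy", "precision", "recall", "f1", "auc")) {
    out[[col]] <- rowMeans(do.call(cbind, lapply(tables, `[[`, col)))
  }
  out$status <- apply(do.call(cbind, lapply(tables, `[[`, "status")), 1,
                      function(s) if (all(s == "ok")) "ok" else s[s != "ok"][1])
  out
}
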