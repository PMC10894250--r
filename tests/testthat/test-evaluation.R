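test_that("confusion counts match the 2x2 table", {
  cc <- confusion_counts(c(1, 0), c(1, 0))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  cc <- confusion_counts(c(1, 0), c(0, 1))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 0L, TN = 0L, FP = 1L, FN = 1L))
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(unlist(cc[c("TP", "FP", "TN", "FN")]),
               c(TP = 2L, FP = 2L, TN = 0L, FN = 0L))
  expect_error(confusion_counts(c(1, 0), c(1)), "length mismatch")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "0/1")
})

test_that("metric formulas on hand-built tables", {
  perfect <- compute_metrics(confusion_counts(c(1, 0), c(1, 0)))
  for (m in c("accuracy", "precision", "recall", "f1", "auc_single_threshold")) {
    expect_equal(perfect[[m]], 1.0)
  }
  cc <- structure(list(TP = 2L, TN = 6L, FP = 1L, FN = 1L),
                  class = "confusion_counts")
  ms <- compute_metrics(cc)
  expect_equal(ms$accuracy, 0.8)
  expect_equal(ms$precision, 2 / 3)
  expect_equal(ms$recall, 2 / 3)
  expect_equal(ms$f1, 2 / 3)
  expect_equal(ms$fpr, 1 / 7)
  expect_equal(ms$auc_single_threshold, (1 + 2 / 3 - 1 / 7) / 2)  # ~0.7619
  # degenerate: no positive predictions
  ms0 <- compute_metrics(structure(list(TP = 0L, TN = 3L, FP = 0L, FN = 2L),
                                   class = "confusion_counts"))
  expect_equal(ms0$precision, 0)
  expect_equal(ms0$f1, 0)
})

test_that("single-threshold AUC is balanced accuracy; F1 bounded by mean(P,R)", {
  rng <- local_rng(19)
  for (i in 1:200) {
    counts <- rng$sample(0:30, 4, replace = TRUE)
    if (sum(counts) == 0) next
    cc <- structure(list(TP = counts[1], TN = counts[2], FP = counts[3],
                         FN = counts[4]), class = "confusion_counts")
    ms <- compute_metrics(cc)
    tnr <- if (cc$FP + cc$TN == 0) 1 else cc$TN / (cc$FP + cc$TN)
    tpr_def <- if (cc$TP + cc$FN == 0) 0 else cc$TP / (cc$TP + cc$FN)
    expect_equal(ms$auc_single_threshold, (1 + tpr_def - ms$fpr) / 2)
    expect_lte(ms$f1, (ms$precision + ms$recall) / 2 + 1e-12)
    if (ms$precision == ms$recall && ms$precision > 0) {
      expect_equal(ms$f1, ms$precision)
    }
  }
})

test_that("rank AUC differs from the single-threshold formula in general", {
  y <- c(0, 0, 1, 1)
  s <- c(0.1, 0.6, 0.4, 0.9)
  expect_equal(roc_auc_scores(y, s), 0.75)
})

test_that("evaluate_models wires masks, stubs and skips correctly", {
  ds <- separable_dataset(n = 60, noise_cols = 2)
  sp <- stratified_split(ds, 0.25, seed = 1)
  seen_cols <- NULL
  stub <- list(stub = list(
    name = "stub", hyper = list(), enabled = TRUE, note = "",
    fit = function(X, y, hyper, seed) { seen_cols <<- ncol(X); list() },
    predict = function(model, X) rep(1L, nrow(X))))
  tab <- evaluate_models(sp$train, sp$test, c(1, 0, 0), stub, seed = 1)
  expect_equal(seen_cols, 1)  # mask restricted to one column
  # constant all-1 predictions on a balanced test set
  expect_equal(tab$accuracy, 0.5)
  expect_equal(tab$recall, 1.0)
  expect_equal(tab$auc, 0.5)
  # disabled plugins are skipped rows, not errors
  reg <- classifier_registry()
  tab2 <- evaluate_models(sp$train, sp$test, c(1, 1, 0),
                          reg[c("naive_bayes", "rnn", "lstm")], seed = 1)
  expect_equal(tab2$status, c("ok", "skipped", "skipped"))
  expect_true(is.na(tab2$accuracy[2]))
  # classifier errors are recorded, others proceed
  bad <- list(bad = list(name = "bad", hyper = list(), enabled = TRUE,
                         note = "",
                         fit = function(X, y, hyper, seed) stop("nope"),
                         predict = function(m, X) 0L),
              ok = reg$decision_tree)
  tab3 <- evaluate_models(sp$train, sp$test, c(1, 0, 0), bad, seed = 1)
  expect_match(tab3$status[1], "nope")
  expect_equal(tab3$status[2], "ok")
})

test_that("every enabled classifier learns an easy separable problem", {
  ds <- separable_dataset(n = 120, noise_cols = 1, seed = 7)
  sp <- stratified_split(ds, 0.25, seed = 2)
  tab <- evaluate_models(sp$train, sp$test, c(1, 1),
                         classifier_registry(enabled_only = TRUE), seed = 3)
  expect_true(all(tab$status == "ok"))
  expect_true(all(tab$accuracy > 0.8),
              info = paste(tab$classifier, round(tab$accuracy, 2),
                           collapse = "; "))
})

test_that("average_over_runs means metrics per classifier", {
  t1 <- data.frame(classifier = c("a", "b"), status = "ok", accuracy = c(0.8, 0.6),
                   precision = 0.5, recall = 0.5, f1 = 0.5, auc = 0.5)
  t2 <- t1; t2$accuracy <- c(1.0, 0.8)
  avg <- average_over_runs(list(t1, t2))
  expect_equal(avg$accuracy, c(0.9, 0.7))
  expect_identical(average_over_runs(list(t1))$accuracy, t1$accuracy)
  t3 <- t1; t3$classifier <- c("a", "c")
  expect_error(average_over_runs(list(t1, t3)), "mismatched")
})
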