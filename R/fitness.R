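#' Fitness parameters
#'
#' Controls the wrapper fitness: stratified k-fold cross-validated accuracy
#' of an L1-penalized logistic regression fitted on the masked features,
#' minus a feature-count penalty `alpha * k/d`.
#'
#' @param folds number of CV folds, default 5.
#' @param C inverse L1 penalty strength (sklearn-style), default 1.
#' @param alpha feature-count penalty weight, default 0.01: breaks accuracy
#'   ties toward sparser masks without overturning genuine accuracy
#'   differences.
#' @param fold_seed integer seed fixing the fold assignment for a whole run,
#'   so every mask is scored against identical folds.
#' @return object of class `fitness_params`.
#' @export
fitness_params <- function(folds = 5L, C = 1.0, alpha = 0.01, fold_seed = 0L) {
  stopifnot(folds >= 2, C > 0, alpha >= 0)
  structure(list(folds = as.integer(folds), C = C, alpha = alpha,
                 fold_seed = as.integer(fold_seed)),
            class = "fitness_params")
}

#' Stratified cross-validation folds
#'
#' Assigns every row to exactly one held-out fold, keeping per-fold class
#' proportions within one row of the global proportion.
#'
#' @param y 0/1 label vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..k, one per row.
#' @export
make_folds <- function(y, k, seed) {
  if (min(table(y)) < k) {
    stop("validation error: need at least ", k, " rows of each class for ",
         k, "-fold stratified CV")
  }
  rng <- local_rng(seed)
  fold <- integer(length(y))
  for (cls in c(0L, 1L)) {
    rows <- which(y == cls)
    rows <- rng$sample(rows)
    fold[rows] <- rep_len(seq_len(k), length(rows))
  }
  fold
}

sentinel_fitness <- function(d, score = -1) {
  structure(list(score = score, mean_cv_accuracy = NA_real_,
                 fold_accuracies = numeric(0), k = 0L,
                 penalty = 0, d = as.integer(d)),
            class = "fitness_value")
}

#' @export
print.fitness_value <- function(x, ...) {
  cat(sprintf("fitness_value: score %.4f (CV acc %.4f, k = %d/%d, penalty %.4f)\n",
              x$score, x$mean_cv_accuracy, x$k, x$d, x$penalty))
  invisible(x)
}

# glmnet requires >= 2 columns; pad single-feature designs with an all-zero
# column whose coefficient stays 0 and leaves the L1 objective unchanged.
pad1 <- function(X) if (ncol(X) == 1L) cbind(X, 0) else X

fit_l1_logistic <- function(X, y, C, thresh = 1e-6, maxit = 5000) {
  lambda <- 1 / (nrow(X) * C)
  fit <- glmnet::glmnet(pad1(X), y, family = "binomial", alpha = 1,
                        lambda = lambda, standardize = FALSE,
                        intercept = TRUE, thresh = thresh, maxit = maxit)
  if (fit$jerr != 0) {
    stop("fit error: L1 logistic solver returned code ", fit$jerr)
  }
  fit
}

predict_l1_logistic <- function(fit, X) {
  pr <- stats::predict(fit, newx = pad1(X), type = "response")[, 1]
  as.integer(pr > 0.5)
}

#' Evaluate the wrapper fitness of a feature mask
#'
#' Restricts the training data to the masked columns, fits the L1-penalized
#' logistic model on each CV training fold (intercept included, tolerance
#' 1e-6), scores label accuracy on the held-out fold, averages across folds
#' and subtracts the feature-count penalty `alpha * k/d`. The all-zero mask
#' gets the sentinel score -1 and is never fitted, so it can never beat a
#' nonempty mask whose score exceeds the sentinel.
#'
#' @param mask 0/1 vector over the d features.
#' @param train a [tabular_dataset()].
#' @param params a [fitness_params()].
#' @param folds optional precomputed fold vector from [make_folds()]; by
#'   default built from `params$fold_seed` (fixed folds make fitness a
#'   deterministic function of the mask).
#' @return object of class `fitness_value`: `score`, `mean_cv_accuracy`,
#'   `fold_accuracies`, `k`, `penalty`, `d`.
#' @export
evaluate_fitness <- function(mask, train, params = fitness_params(),
                             folds = NULL) {
  stopifnot(inherits(train, "tabular_dataset"))
  d <- ncol(train$features)
  mask <- as.integer(mask)
  if (length(mask) != d || !all(mask %in% c(0L, 1L))) {
    stop("validation error: mask must be a 0/1 vector of length ", d)
  }
  k <- sum(mask)
  if (k == 0L) return(sentinel_fitness(d))
  if (is.null(folds)) folds <- make_folds(train$target, params$folds, params$fold_seed)
  X <- train$features[, mask == 1L, drop = FALSE]
  y <- train$target
  acc <- vapply(seq_len(params$folds), function(f) {
    tr <- folds != f
    fit <- fit_l1_logistic(X[tr, , drop = FALSE], y[tr], params$C)
    pred <- predict_l1_logistic(fit, X[!tr, , drop = FALSE])
    mean(pred == y[!tr])
  }, numeric(1))
  penalty <- params$alpha * k / d
  structure(list(score = mean(acc) - penalty, mean_cv_accuracy = mean(acc),
                 fold_accuracies = acc, k = k, penalty = penalty,
                 d = as.integer(d)),
            class = "fitness_value")
}

#' Build a memoizing fitness function for a search run
#'
#' Returns `function(mask) -> fitness_value` with folds fixed once (from
#' `params$fold_seed`) and results cached by mask. Because the folds are
#' fixed, fitness is a deterministic function of the mask and the cache is
#' exact, not approximate. Passing a shared `cache` environment lets
#' repeated runs against identical folds reuse evaluations.
#'
#' @param train a [tabular_dataset()].
#' @param params a [fitness_params()].
#' @param cache environment used as mask -> fitness_value memo table.
#' @return a function of one argument (the 0/1 mask).
#' @export
make_fitness_fn <- function(train, params = fitness_params(),
                            cache = new.env(parent = emptyenv())) {
  folds <- make_folds(train$target, params$folds, params$fold_seed)
  force(train); force(params)
  function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    fv <- evaluate_fitness(mask, train, params, folds = folds)
    assign(key, fv, envir = cache)
    fv
  }
}
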