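#' Fit a standardizer on training data
#'
#' Per-column means and population standard deviations (divide by n).
#' Zero-variance columns are recorded so [apply_standardizer()] can map
#' them to exact zeros rather than dividing by zero.
#'
#' @param train a [tabular_dataset()].
#' @return object of class `standardizer_params`: `mean`, `sd`,
#'   `zero_variance` (logical per column).
#' @export
fit_standardizer <- function(train) {
  stopifnot(inherits(train, "tabular_dataset"))
  X <- train$features
  if (nrow(X) < 2L) stop("validation error: need at least 2 rows to standardize")
  mu <- colMeans(X)
  n <- nrow(X)
  sdev <- sqrt(colMeans(sweep(X, 2, mu)^2))  # population sd
  structure(
    list(mean = mu, sd = sdev, zero_variance = sdev == 0),
    class = "standardizer_params"
  )
}

#' Apply a fitted standardizer
#'
#' `x' = (x - mean)/sd` with the training-set parameters; zero-variance
#' columns become all zeros. Applying train parameters to test data is the
#' intended use: the test set never influences the scaling.
#'
#' @param ds a [tabular_dataset()].
#' @param p a `standardizer_params` from [fit_standardizer()].
#' @return a standardized [tabular_dataset()].
#' @export
apply_standardizer <- function(ds, p) {
  stopifnot(inherits(ds, "tabular_dataset"), inherits(p, "standardizer_params"))
  if (ncol(ds$features) != length(p$mean)) {
    stop("dimension mismatch: dataset has ", ncol(ds$features),
         " columns, params have ", length(p$mean))
  }
  denom <- ifelse(p$zero_variance, 1, p$sd)
  X <- sweep(sweep(ds$features, 2, p$mean), 2, denom, "/")
  X[, p$zero_variance] <- 0
  tabular_dataset(X, ds$target, ds$feature_names)
}

#' Fit the coefficient-weighting transform
#'
#' Fits an intercept-including logistic regression with an L2
#' (ridge) penalty at inverse strength `C` on standardized training data and
#' stores the per-feature coefficient vector. The coefficients indicate each
#' feature's contribution to the linear predictor and can afterwards be
#' applied as a column weighting to both partitions via
#' [apply_coef_weighting()].
#'
#' The objective matches the common machine-learning parameterization:
#' sum of log-losses plus \eqn{\|w\|_2^2 / (2C)}, solved to tolerance 1e-6.
#'
#' @param train a standardized [tabular_dataset()].
#' @param C inverse penalty strength, positive. Default 1.
#' @return object of class `coef_weighting`: `w` (named coefficients,
#'   no intercept), `intercept`, `C`.
#' @export
fit_coef_weighting <- function(train, C = 1.0) {
  stopifnot(inherits(train, "tabular_dataset"), C > 0)
  X <- train$features
  n <- nrow(X)
  # glmnet minimizes (1/n) sum loss + lambda/2 ||w||^2 for alpha=0
  lambda <- 1 / (n * C)
  fit <- glmnet::glmnet(X, train$target, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-6, maxit = 100000)
  if (fit$jerr != 0) {
    stop("fit error: ridge logistic solver returned code ", fit$jerr)
  }
  beta <- as.numeric(fit$beta[, 1])
  if (any(!is.finite(beta))) stop("fit error: non-finite coefficients")
  names(beta) <- train$feature_names
  structure(list(w = beta, intercept = as.numeric(fit$a0), C = C),
            class = "coef_weighting")
}

#' Apply coefficient weighting
#'
#' Multiplies column j elementwise by `w_j` (or `|w_j|` when `mode =
#' "abs"`). With no zero entries the transform is invertible. This is the
#' "regularized dataset" transform; it is off by default in the pipeline
#' because its exact intended semantics are ambiguous (see the methods
#' vignette).
#'
#' @param ds a [tabular_dataset()].
#' @param cw a `coef_weighting` from [fit_coef_weighting()].
#' @param mode `"signed"` (default, multiply by w_j) or `"abs"`.
#' @return a weighted [tabular_dataset()].
#' @export
apply_coef_weighting <- function(ds, cw, mode = c("signed", "abs")) {
  stopifnot(inherits(ds, "tabular_dataset"), inherits(cw, "coef_weighting"))
  mode <- match.arg(mode)
  if (ncol(ds$features) != length(cw$w)) {
    stop("dimension mismatch: dataset has ", ncol(ds$features),
         " columns, weighting has ", length(cw$w))
  }
  w <- if (mode == "abs") abs(cw$w) else cw$w
  tabular_dataset(sweep(ds$features, 2, w, "*"), ds$target, ds$feature_names)
}

#' Serialize preprocessing parameters to JSON
#'
#' @param x a `standardizer_params` or `coef_weighting`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
preprocessing_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "standardizer_params") || inherits(x, "coef_weighting"))
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
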