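#' Synthetic dataset configuration
#'
#' Describes a generated binary-outcome dataset with planted structure:
#' `k_informative` standard-normal features that drive the label through a
#' zero-intercept logistic model, `k_redundant` noisy copies of randomly
#' chosen informative features, and `k_noise` features independent of the
#' label. The defaults emulate the shape of desk-scale clinical risk
#' tables: a few hundred rows, roughly balanced outcome, a handful of true
#' risk factors among correlated and irrelevant ones.
#'
#' @param n number of rows, default 500.
#' @param k_informative informative features, default 3.
#' @param k_redundant redundant (noisy-copy) features, default 2.
#' @param k_noise pure-noise features, default 5.
#' @param beta effect size(s) on the logit for the informative features,
#'   recycled to `k_informative`. Default 2.
#' @param redundancy_sd sd of the noise added to copied columns, default 0.1.
#' @param label_noise rate of random label flips in `[0, 0.5)`, default 0.
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 500L, k_informative = 3L, k_redundant = 2L,
                             k_noise = 5L, beta = 2.0, redundancy_sd = 0.1,
                             label_noise = 0, seed = 0L) {
  d <- k_informative + k_redundant + k_noise
  stopifnot(d >= 1, n >= 2, label_noise >= 0, label_noise < 0.5,
            all(beta > 0), redundancy_sd >= 0)
  if (k_redundant > 0 && k_informative == 0) {
    stop("invalid config: redundant features require informative features")
  }
  if (n < 10 * d) {
    warning("synthetic_config: n < 10 * d; recovery properties may be weak")
  }
  structure(list(n = as.integer(n), k_informative = as.integer(k_informative),
                 k_redundant = as.integer(k_redundant),
                 k_noise = as.integer(k_noise),
                 beta = rep_len(beta, k_informative),
                 redundancy_sd = redundancy_sd, label_noise = label_noise,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Informative columns are iid standard normal; the label is Bernoulli with
#' `P(y=1) = logistic(sum_i beta_i x_i)` (no intercept, so classes are
#' balanced in expectation); each redundant column is a randomly chosen
#' informative column plus `N(0, redundancy_sd^2)` noise; noise columns are
#' standard normal and independent of the label. Optional label flips at
#' rate `label_noise`. Column order is informative, redundant, noise, with
#' names `inf1..`, `red1..`, `noi1..`.
#'
#' @param cfg a [synthetic_config()].
#' @return list `dataset` (a [tabular_dataset()]) and `truth` (class
#'   `ground_truth`: index vectors `informative`, `redundant`, `noise`,
#'   coefficient vector `beta`, `redundant_source`).
#' @export
generate_synthetic <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  rng <- local_rng(cfg$seed)
  n <- cfg$n
  Xi <- matrix(rng$rnorm(n * cfg$k_informative), n, cfg$k_informative)
  logit <- as.numeric(Xi %*% cfg$beta)
  y <- rng$rbinom(n, 1, 1 / (1 + exp(-logit)))
  src <- integer(0)
  Xr <- matrix(numeric(0), n, 0)
  if (cfg$k_redundant > 0) {
    src <- rng$sample(seq_len(cfg$k_informative), cfg$k_redundant,
                      replace = TRUE)
    Xr <- Xi[, src, drop = FALSE] +
      matrix(rng$rnorm(n * cfg$k_redundant, sd = cfg$redundancy_sd),
             n, cfg$k_redundant)
  }
  Xn <- matrix(rng$rnorm(n * cfg$k_noise), n, cfg$k_noise)
  if (cfg$label_noise > 0) {
    flip <- rng$rbinom(n, 1, cfg$label_noise) == 1
    y[flip] <- 1L - y[flip]
  }
  # degenerate single-class draws are a config problem, not a generator bug:
  # resample the seed space rarely enough that callers see an error instead
  if (length(unique(y)) < 2L) {
    stop("generated a single-class target; increase n or decrease |beta|")
  }
  X <- cbind(Xi, Xr, Xn)
  nm <- c(sprintf("inf%d", seq_len(cfg$k_informative)),
          sprintf("red%d", seq_len(cfg$k_redundant)),
          sprintf("noi%d", seq_len(cfg$k_noise)))
  d <- ncol(X)
  truth <- structure(
    list(informative = seq_len(cfg$k_informative),
         redundant = seq_len(cfg$k_redundant) + cfg$k_informative,
         noise = seq_len(cfg$k_noise) + cfg$k_informative + cfg$k_redundant,
         beta = cfg$beta, redundant_source = src),
    class = "ground_truth")
  list(dataset = tabular_dataset(X, y, nm), truth = truth)
}

#' Exhaustive subset-enumeration oracle
#'
#' Evaluates [evaluate_fitness()] on every nonempty mask (2^d - 1 of them,
#' refused above d = 16) with one fixed fold assignment and returns the
#' maximum — the ground-truth optimum any heuristic search is measured
#' against. Ties are broken toward fewer features, then the
#' lexicographically smallest mask.
#'
#' @param train a [tabular_dataset()] with d <= 16 features.
#' @param params a [fitness_params()].
#' @param fitness_fn optional memoized fitness function (shared with a
#'   search run to guarantee identical folds); defaults to
#'   [make_fitness_fn()] on `train`/`params`.
#' @return list `mask` (0/1 vector), `fitness` (`fitness_value`).
#' @export
exhaustive_best <- function(train, params = fitness_params(),
                            fitness_fn = NULL) {
  d <- ncol(train$features)
  if (d > 16) {
    stop("exhaustive_best: refusing d = ", d,
         " (> 16; 2^d - 1 evaluations is not desk-scale)")
  }
  if (is.null(fitness_fn)) fitness_fn <- make_fitness_fn(train, params)
  best <- NULL; best_mask <- NULL
  for (code in seq_len(2^d - 1)) {
    mask <- as.integer(bitwAnd(bitwShiftR(code, seq_len(d) - 1L), 1L))
    fv <- fitness_fn(mask)
    better <- is.null(best) ||
      fv$score > best$score + 1e-12 ||
      (abs(fv$score - best$score) <= 1e-12 &&
         (fv$k < best$k ||
            (fv$k == best$k &&
               paste(mask, collapse = "") < paste(best_mask, collapse = ""))))
    if (better) { best <- fv; best_mask <- mask }
  }
  list(mask = best_mask, fitness = best)
}

#' Recovery score of a selected set against planted truth
#'
#' @param selected integer indices of selected features.
#' @param truth a `ground_truth` from [generate_synthetic()].
#' @return list `recall` (fraction of informative features recovered) and
#'   `false_inclusions` (number of pure-noise features selected).
#' @export
recovery_score <- function(selected, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  list(recall = length(intersect(selected, truth$informative)) /
         max(length(truth$informative), 1L),
       false_inclusions = length(intersect(selected, truth$noise)))
}
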