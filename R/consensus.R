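#' Consensus (stability) selection parameters
#'
#' The search is stochastic, so it is repeated `runs` times with derived
#' seeds (`base_seed + 0 .. runs-1`) and a feature is retained when it
#' appears in at least `threshold` of the run masks — the canonical rule
#' is 10 runs with an 80% threshold, i.e. a feature must be selected in at
#' least 8 of 10 runs.
#'
#' @param runs number of repeated runs R, default 10.
#' @param threshold frequency threshold in (0,1], inclusive, default 0.8.
#' @param base_seed integer; run r uses seed `base_seed + r - 1`.
#' @return object of class `consensus_params`.
#' @export
consensus_params <- function(runs = 10L, threshold = 0.8, base_seed = 0L) {
  stopifnot(runs >= 1, threshold > 0, threshold <= 1)
  structure(list(runs = as.integer(runs), threshold = threshold,
                 base_seed = as.integer(base_seed)),
            class = "consensus_params")
}

#' Tally per-feature selection frequencies
#'
#' @param masks R x d matrix of 0/1 run masks (or a list of equal-length
#'   mask vectors).
#' @return numeric vector of length d: fraction of runs selecting each
#'   feature.
#' @export
tally_frequencies <- function(masks) {
  if (is.list(masks)) {
    lens <- lengths(masks)
    if (length(unique(lens)) != 1L) stop("validation error: ragged masks")
    masks <- do.call(rbind, masks)
  }
  if (nrow(masks) < 1L) stop("validation error: need at least one mask")
  colMeans(masks)
}

#' Apply the frequency threshold
#'
#' Inclusive rule ("at least"): feature j is retained iff
#' `frequency_j >= threshold`. A small numeric guard absorbs floating-point
#' representation of ratios like 8/10.
#'
#' @param freq frequency vector from [tally_frequencies()].
#' @param threshold value in (0,1].
#' @return ascending integer indices of retained features.
#' @export
select_consensus <- function(freq, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  unname(which(freq >= threshold - 1e-9))
}

#' Repeated WOA selection with consensus
#'
#' Executes [run_selection()] R times with seeds `base_seed + 0..R-1`.
#' Folds are fixed within each run but re-seeded per run (fold seed =
#' run seed): within a run every mask is compared against identical folds,
#' while across runs the fold noise varies, which is what lets the
#' frequency threshold wash out features that only look useful on one fold
#' assignment. Per-feature frequencies are tallied and features meeting
#' the threshold retained. If no feature qualifies, the result falls back
#' to the single best-fitness run's mask and is flagged.
#'
#' @param train a [tabular_dataset()].
#' @param sel_params a [selector_params()]; its seed is overridden per run.
#' @param fit_params a [fitness_params()]; its fold seed is overridden
#'   with each run's seed.
#' @param con_params a [consensus_params()].
#' @return object of class `consensus_result`: `frequencies` (named),
#'   `selected` (indices), `selected_names`, `masks` (R x d), `run_scores`,
#'   `run_seeds`, `runs` (list of `run_result`), `threshold`, `fallback`.
#' @export
run_repeated <- function(train, sel_params = selector_params(),
                         fit_params = fitness_params(),
                         con_params = consensus_params()) {
  stopifnot(inherits(train, "tabular_dataset"))
  d <- ncol(train$features)
  run_seeds <- con_params$base_seed + seq_len(con_params$runs) - 1L
  runs <- vector("list", con_params$runs)
  for (r in seq_len(con_params$runs)) {
    sp <- sel_params
    sp$woa$seed <- run_seeds[r]
    fp <- fit_params
    fp$fold_seed <- run_seeds[r]
    runs[[r]] <- tryCatch(
      run_selection(train, sp, make_fitness_fn(train, fp)),
      error = function(e) stop("run ", r, " (seed ", run_seeds[r],
                               ") failed: ", conditionMessage(e))
    )
  }
  masks <- do.call(rbind, lapply(runs, `[[`, "best_mask"))
  colnames(masks) <- train$feature_names
  freq <- tally_frequencies(masks)
  selected <- select_consensus(freq, con_params$threshold)
  fallback <- FALSE
  if (length(selected) == 0L) {
    best_run <- which.max(vapply(runs, function(r) r$best_fitness$score,
                                 numeric(1)))
    selected <- unname(which(masks[best_run, ] == 1L))
    fallback <- TRUE
    warning("run_repeated: empty consensus set; falling back to best run's mask")
  }
  structure(
    list(frequencies = freq, selected = selected,
         selected_names = train$feature_names[selected], masks = masks,
         run_scores = vapply(runs, function(r) r$best_fitness$score, numeric(1)),
         run_seeds = run_seeds, runs = runs,
         threshold = con_params$threshold, fallback = fallback),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result:", nrow(x$masks), "runs, threshold", x$threshold,
      if (x$fallback) "(fallback to best run)" else "", "\n")
  cat("selected:", paste(x$selected_names, collapse = ", "), "\n")
  invisible(x)
}

#' Write consensus artifacts
#'
#' Writes `masks.csv` (R x d of 0/1), `frequencies.csv` and
#' `selected_features.json` into `dir`.
#'
#' @param x a `consensus_result`.
#' @param dir output directory (created if needed).
#' @return invisible character vector of paths written.
#' @export
write_consensus <- function(x, dir) {
  stopifnot(inherits(x, "consensus_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("masks.csv", "frequencies.csv",
                            "selected_features.json"))
  utils::write.csv(as.data.frame(x$masks), paths[1], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(feature = names(x$frequencies),
                              frequency = as.numeric(x$frequencies)),
                   paths[2], row.names = FALSE, quote = FALSE)
  writeLines(jsonlite::toJSON(
    list(selected = x$selected, selected_names = x$selected_names,
         threshold = x$threshold, fallback = x$fallback,
         run_seeds = x$run_seeds),
    auto_unbox = TRUE, digits = NA), paths[3])
  invisible(paths)
}
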