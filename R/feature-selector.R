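#' Logistic sigmoid transfer function
#'
#' Maps a continuous whale position component to a selection probability in
#' (0,1): `1/(1 + exp(-x))`.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Binarize a continuous position
#'
#' `mask_j = 1` iff `sigmoid(position_j) > tau`, with a strict inequality:
#' the tie at `sigmoid = tau` maps to 0, so a zero position component is
#' unambiguously "feature off" and binary initial positions binarize to
#' themselves.
#'
#' @param position numeric position vector.
#' @param tau threshold in (0,1), default 0.5.
#' @return integer 0/1 mask of the same length.
#' @export
binarize <- function(position, tau = 0.5) {
  stopifnot(tau > 0, tau < 1)
  as.integer(sigmoid(position) > tau)
}

#' Selector parameters
#'
#' @param woa a [woa_params()].
#' @param tau sigmoid threshold in (0,1), default 0.5.
#' @param sentinel score assigned to the empty mask, default -1.
#' @return object of class `selector_params`.
#' @export
selector_params <- function(woa = woa_params(), tau = 0.5, sentinel = -1) {
  stopifnot(inherits(woa, "woa_params"), tau > 0, tau < 1)
  structure(list(woa = woa, tau = tau, sentinel = sentinel),
            class = "selector_params")
}

#' Initialize the whale population
#'
#' Initial positions are binary: each component is drawn iid from {0,1}
#' with probability 0.5, encoding an initial random feature subset per
#' agent.
#'
#' @param n_agents number of agents (>= 2).
#' @param d number of features (>= 1).
#' @param rng a [local_rng()] stream.
#' @return numeric matrix n_agents x d of 0/1 positions.
#' @export
initialize_population <- function(n_agents, d, rng) {
  stopifnot(n_agents >= 2, d >= 1)
  matrix(as.numeric(rng$rbinom(n_agents * d, 1, 0.5)), n_agents, d)
}

#' Run one binary-WOA feature-selection search
#'
#' Implements the binary adaptation of WOA: binary initialization,
#' continuous position evolution via [whale_step()], sigmoid transfer +
#' threshold binarization for fitness evaluation, and strict-improvement
#' tracking of the global best. Agents are re-evaluated only when their
#' mask changes (fitness is deterministic given the mask because folds are
#' fixed per run).
#'
#' @param train a [tabular_dataset()]; used only when `fitness_fn` is NULL.
#' @param params a [selector_params()].
#' @param fitness_fn function(mask) -> `fitness_value`; defaults to
#'   [make_fitness_fn()] on `train` with default [fitness_params()].
#' @return object of class `run_result`: `best_mask` (0/1 vector),
#'   `best_fitness` (`fitness_value`), `trace` (best score at t = 0..T,
#'   nondecreasing), `seed`, `n_agents`, `n_iterations`, `n_evaluations`
#'   (distinct fitness evaluations performed).
#' @export
run_selection <- function(train, params = selector_params(), fitness_fn = NULL) {
  stopifnot(inherits(params, "selector_params"))
  if (is.null(fitness_fn)) fitness_fn <- make_fitness_fn(train)
  wp <- params$woa
  d <- ncol(train$features)
  rng <- local_rng(wp$seed)
  pop <- initialize_population(wp$n_agents, d, rng)

  agent_mask <- vector("list", wp$n_agents)
  agent_fit <- vector("list", wp$n_agents)
  best_fit <- NULL
  best_mask <- NULL
  best_pos <- NULL
  n_eval <- 0L

  eval_mask <- function(mask) {
    if (sum(mask) == 0L) return(sentinel_fitness(d, params$sentinel))
    n_eval <<- n_eval + 1L
    fv <- fitness_fn(mask)
    if (!is.finite(fv$score)) {
      stop("fitness error: non-finite score for mask ",
           paste(mask, collapse = ""))
    }
    fv
  }

  for (i in seq_len(wp$n_agents)) {
    m <- binarize(pop[i, ], params$tau)
    fv <- tryCatch(eval_mask(m), error = function(e) {
      stop("fitness failed at initialization, agent ", i, ": ",
           conditionMessage(e))
    })
    agent_mask[[i]] <- m
    agent_fit[[i]] <- fv
    if (is.null(best_fit) || fv$score > best_fit$score) {
      best_fit <- fv; best_mask <- m; best_pos <- pop[i, ]
    }
  }
  trace <- numeric(wp$n_iterations + 1L)
  trace[1] <- best_fit$score

  for (t in seq_len(wp$n_iterations)) {
    a <- control_scalar(t, wp$n_iterations)
    for (i in seq_len(wp$n_agents)) {
      st <- whale_step(pop[i, ], best_pos, pop, a, wp, rng)
      pop[i, ] <- st$position
      m <- binarize(st$position, params$tau)
      if (identical(m, agent_mask[[i]])) {
        fv <- agent_fit[[i]]
      } else {
        fv <- tryCatch(eval_mask(m), error = function(e) {
          stop("fitness failed at iteration ", t, ", agent ", i, ": ",
               conditionMessage(e))
        })
        agent_mask[[i]] <- m
        agent_fit[[i]] <- fv
      }
      if (fv$score > best_fit$score) {
        best_fit <- fv; best_mask <- m; best_pos <- pop[i, ]
      }
    }
    trace[t + 1L] <- best_fit$score
  }
  if (sum(best_mask) == 0L) {
    warning("run_selection: best mask is empty (all agents empty throughout)")
  }
  structure(
    list(best_mask = best_mask, best_fitness = best_fit, trace = trace,
         seed = wp$seed, n_agents = wp$n_agents,
         n_iterations = wp$n_iterations, n_evaluations = n_eval),
    class = "run_result"
  )
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf(
    "run_result: seed %d, %d agents x %d iterations, best score %.4f, k = %d\n",
    x$seed, x$n_agents, x$n_iterations, x$best_fitness$score, sum(x$best_mask)))
  invisible(x)
}

#' Serialize a run result to JSON
#'
#' @param x a `run_result`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
run_result_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "run_result"))
  obj <- list(best_mask = paste(x$best_mask, collapse = ""),
              best_score = x$best_fitness$score,
              mean_cv_accuracy = x$best_fitness$mean_cv_accuracy,
              k = x$best_fitness$k, trace = x$trace, seed = x$seed,
              n_agents = x$n_agents, n_iterations = x$n_iterations,
              n_evaluations = x$n_evaluations)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
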