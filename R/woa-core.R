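#' WOA search parameters
#'
#' @param n_agents population size (>= 2).
#' @param n_iterations number of iterations T (>= 1).
#' @param b logarithmic-spiral constant, default 1.
#' @param clip positive bound; positions are clipped to `[-clip, clip]`
#'   after every move so the sigmoid transfer never saturates completely
#'   (sigmoid(6) ~ 0.9975). Default 6.
#' @param seed integer seed for the search stream.
#' @return object of class `woa_params`.
#' @export
woa_params <- function(n_agents = 30L, n_iterations = 50L, b = 1.0,
                       clip = 6.0, seed = 0L) {
  stopifnot(n_agents >= 2, n_iterations >= 1, clip > 0)
  structure(list(n_agents = as.integer(n_agents),
                 n_iterations = as.integer(n_iterations),
                 b = b, clip = clip, seed = as.integer(seed)),
            class = "woa_params")
}

#' Control scalar a(t)
#'
#' Linearly decreases from 2 at t = 0 to 0 at t = T, governing the
#' exploration/exploitation balance: the coefficient A is drawn from
#' `[-a, a]`, and |A| >= 1 triggers random search instead of encircling.
#'
#' @param t current iteration, 0..T.
#' @param T total iterations.
#' @return a = 2 (1 - t/T).
#' @export
control_scalar <- function(t, T) {
  if (t < 0 || t > T) stop("t must be in [0, T]")
  2 * (1 - t / T)
}

#' Draw the coefficient vectors A and C
#'
#' Componentwise A_j = 2 a r1_j - a and C_j = 2 r2_j with r1, r2 iid
#' Uniform(0,1), so A_j falls in `[-a, a]` and C_j in `[0, 2]`.
#'
#' @param a control scalar in `[0, 2]`.
#' @param d dimension count.
#' @param rng a [local_rng()] stream.
#' @return list with vectors `A` and `C`.
#' @export
draw_coefficients <- function(a, d, rng) {
  r1 <- rng$runif(d)
  r2 <- rng$runif(d)
  list(A = 2 * a * r1 - a, C = 2 * r2)
}

clip_position <- function(x, clip) pmin(pmax(x, -clip), clip)

#' Encircling (shrinking) move
#'
#' D = |C * Xbest - X|, new position = Xbest - A * D, per dimension,
#' clipped to the search bound. With A = 0 the agent lands exactly on the
#' incumbent best.
#'
#' @param X agent position.
#' @param Xbest incumbent best position.
#' @param A,C coefficient vectors from [draw_coefficients()].
#' @param clip position bound.
#' @return updated position vector.
#' @export
encircling_update <- function(X, Xbest, A, C, clip = 6.0) {
  if (length(X) != length(Xbest)) stop("dimension mismatch")
  D <- abs(C * Xbest - X)
  clip_position(Xbest - A * D, clip)
}

#' Logarithmic-spiral (bubble-net) move
#'
#' D' = |Xbest - X|, new position = D' e^{b l} cos(2 pi l) + Xbest, the
#' humpback spiral toward the best solution. `l` is drawn uniformly from
#' `[-1, 1]` by the caller.
#'
#' @param X agent position.
#' @param Xbest incumbent best position.
#' @param b spiral constant.
#' @param l spiral parameter in `[-1, 1]`.
#' @param clip position bound.
#' @return updated position vector.
#' @export
spiral_update <- function(X, Xbest, b, l, clip = 6.0) {
  if (length(X) != length(Xbest)) stop("dimension mismatch")
  Dp <- abs(Xbest - X)
  clip_position(Dp * exp(b * l) * cos(2 * pi * l) + Xbest, clip)
}

#' Random-search (exploration) move
#'
#' Same form as encircling but toward a randomly chosen member of the
#' population instead of the best: D = |C * Xr - X|, result = Xr - A * D.
#'
#' @param X agent position.
#' @param Xrand position of a uniformly drawn agent.
#' @param A,C coefficient vectors.
#' @param clip position bound.
#' @return updated position vector.
#' @export
random_search_update <- function(X, Xrand, A, C, clip = 6.0) {
  if (length(X) != length(Xrand)) stop("dimension mismatch")
  D <- abs(C * Xrand - X)
  clip_position(Xrand - A * D, clip)
}

#' One whale position update with trace
#'
#' The stochastic dispatch of the three moves for one agent at one
#' iteration: `p` is drawn once per agent-step; `p >= 0.5` takes the spiral
#' move with a fresh `l ~ U(-1, 1)`; `p < 0.5` draws A and C componentwise
#' and, per dimension, applies encircling when `|A_j| < 1` and random
#' search toward a single `Xrand` (drawn once for the step) when
#' `|A_j| >= 1`. All draws and per-dimension branches are recorded in the
#' returned trace.
#'
#' @param X agent position.
#' @param Xbest incumbent best position.
#' @param population matrix of all agent positions (agents x dims),
#'   source of the random agent.
#' @param a control scalar for this iteration.
#' @param params a [woa_params()].
#' @param rng a [local_rng()] stream.
#' @return list `position` (new vector) and `trace` (list with `p`, `l`,
#'   `A`, `C`, `rand_agent`, `branch` per dimension:
#'   "spiral"/"encircle"/"search").
#' @export
whale_step <- function(X, Xbest, population, a, params, rng) {
  d <- length(X)
  p <- rng$runif(1)
  if (p >= 0.5) {
    l <- rng$runif(1, -1, 1)
    pos <- spiral_update(X, Xbest, params$b, l, params$clip)
    trace <- list(p = p, l = l, A = NULL, C = NULL, rand_agent = NA_integer_,
                  branch = rep("spiral", d))
  } else {
    co <- draw_coefficients(a, d, rng)
    rand_agent <- rng$sample(seq_len(nrow(population)), 1)
    Xrand <- population[rand_agent, ]
    explore <- abs(co$A) >= 1
    enc <- encircling_update(X, Xbest, co$A, co$C, params$clip)
    sea <- random_search_update(X, Xrand, co$A, co$C, params$clip)
    pos <- ifelse(explore, sea, enc)
    trace <- list(p = p, l = NA_real_, A = co$A, C = co$C,
                  rand_agent = rand_agent,
                  branch = ifelse(explore, "search", "encircle"))
  }
  list(position = pos, trace = trace)
}
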