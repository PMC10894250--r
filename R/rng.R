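#' Isolated random number stream
#'
#' Creates a self-contained RNG stream seeded with `seed`. Draws from the
#' stream never touch (and are never perturbed by) the global
#' `.Random.seed`, which makes every seeded component of the pipeline —
#' split, population initialization, whale steps, fold assignment —
#' reproducible independently of anything else the session does.
#'
#' The returned object exposes `$runif(n, min, max)`, `$sample(x, size,
#' replace)`, `$rbinom(n, size, prob)` and `$rnorm(n, mean, sd)`, each
#' advancing the stream deterministically.
#'
#' @param seed integer seed.
#' @return an environment of class `woafs_rng`.
#' @export
local_rng <- function(seed) {
  self <- new.env(parent = emptyenv())
  g <- globalenv()
  swap_in <- function() {
    self$saved <- get0(".Random.seed", envir = g, inherits = FALSE)
    assign(".Random.seed", self$state, envir = g)
  }
  swap_out <- function() {
    self$state <- get(".Random.seed", envir = g)
    if (is.null(self$saved)) {
      rm(".Random.seed", envir = g)
    } else {
      assign(".Random.seed", self$saved, envir = g)
    }
  }
  draw <- function(f) {
    swap_in()
    on.exit(swap_out())
    f()
  }
  # initialize state without disturbing the global stream
  self$saved <- get0(".Random.seed", envir = g, inherits = FALSE)
  set.seed(seed)
  swap_out()

  self$runif <- function(n, min = 0, max = 1) draw(function() stats::runif(n, min, max))
  self$rnorm <- function(n, mean = 0, sd = 1) draw(function() stats::rnorm(n, mean, sd))
  self$rbinom <- function(n, size, prob) draw(function() stats::rbinom(n, size, prob))
  self$sample <- function(x, size = length(x), replace = FALSE) {
    draw(function() sample(x, size, replace))
  }
  class(self) <- "woafs_rng"
  self
}

#' Derive a child seed from a base seed
#'
#' Deterministic fan-out of one global seed into per-component seeds,
#' kept inside 32-bit integer range.
#'
#' @param base integer base seed.
#' @param offset nonnegative integer offset.
#' @return integer seed.
#' @export
derive_seed <- function(base, offset) {
  as.integer((as.numeric(base) * 1000003 + as.numeric(offset)) %% 2147483647)
}
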