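# Fixtures are built in code; nothing on disk.

# Tiny fully numeric CSV on disk (for load/round-trip tests).
write_tiny_csv <- function(path, n = 10) {
  df <- data.frame(a = seq_len(n), b = rev(seq_len(n)) / 2,
                   target = rep(c(0, 1), length.out = n))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Balanced dataset with one perfectly separating feature (wide margin:
# class 0 has x1 in [-2,-1], class 1 in [1,2]) plus pure-noise columns.
separable_dataset <- function(n = 200, noise_cols = 2, seed = 42) {
  rng <- local_rng(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x1 <- ifelse(y == 1, rng$runif(n, 1, 2), rng$runif(n, -2, -1))
  X <- cbind(x1, matrix(rng$rnorm(n * noise_cols), n, noise_cols))
  tabular_dataset(X, y, c("sep", paste0("noise", seq_len(noise_cols))))
}

# Scripted RNG stub with the local_rng() interface: pops values from fixed
# queues so whale_step branches can be forced exactly.
stub_rng <- function(runif_vals = numeric(), sample_vals = integer()) {
  self <- new.env(parent = emptyenv())
  self$ru <- as.numeric(runif_vals)
  self$sa <- sample_vals
  self$runif <- function(n, min = 0, max = 1) {
    stopifnot(length(self$ru) >= n)
    out <- self$ru[seq_len(n)]
    self$ru <- self$ru[-seq_len(n)]
    min + out * (max - min)  # queued values are in [0,1]
  }
  self$sample <- function(x, size = length(x), replace = FALSE) {
    stopifnot(length(self$sa) >= 1)
    out <- self$sa[1]
    self$sa <- self$sa[-1]
    x[out]
  }
  self$rnorm <- function(n, mean = 0, sd = 1) stop("rnorm not stubbed")
  self$rbinom <- function(n, size, prob) stop("rbinom not stubbed")
  class(self) <- "woafs_rng"
  self
}

# RNG stub returning fixed Bernoulli draws (for population initialization).
stub_rng_binom <- function(vals) {
  self <- new.env(parent = emptyenv())
  self$vals <- vals
  self$rbinom <- function(n, size, prob) {
    out <- self$vals[seq_len(n)]
    self$vals <- self$vals[-seq_len(n)]
    out
  }
  class(self) <- "woafs_rng"
  self
}

# A constant-fitness function and a popcount fitness for search tests.
const_fitness <- function(value = 0.5) {
  function(mask) structure(
    list(score = value, mean_cv_accuracy = value,
         fold_accuracies = rep(value, 5), k = sum(mask), penalty = 0,
         d = length(mask)),
    class = "fitness_value")
}

popcount_fitness <- function() {
  function(mask) structure(
    list(score = sum(mask) / length(mask),
         mean_cv_accuracy = sum(mask) / length(mask),
         fold_accuracies = numeric(0), k = sum(mask), penalty = 0,
         d = length(mask)),
    class = "fitness_value")
}
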