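test_that("control scalar is linear with endpoints 2 and 0", {
  expect_equal(control_scalar(0, 100), 2)
  expect_equal(control_scalar(100, 100), 0)
  expect_equal(control_scalar(50, 100), 1)
  T <- 17
  a <- vapply(0:T, control_scalar, numeric(1), T = T)
  expect_equal(a, 2 * (1 - (0:T) / T))
  expect_true(all(diff(a) < 0))
  expect_error(control_scalar(-1, 10), "must be in")
  expect_error(control_scalar(11, 10), "must be in")
})

test_that("coefficient draws obey A in [-a,a], C in [0,2] and substitution identities", {
  # forced draws: r1 = 0 -> A = -a; r2 = 0 -> C = 0, etc.
  co <- draw_coefficients(1.5, 3, stub_rng(c(0, 1, 0.5, 0, 1, 0.5)))
  expect_equal(co$A, c(-1.5, 1.5, 0))
  expect_equal(co$C, c(0, 2, 1))
  rng <- local_rng(8)
  for (a in c(0, 0.7, 2)) {
    co <- draw_coefficients(a, 50, rng)
    expect_true(all(co$A >= -a - 1e-12 & co$A <= a + 1e-12))
    expect_true(all(co$C >= 0 & co$C <= 2))
  }
})

test_that("encircling update matches its closed form and fixed points", {
  Xb <- c(2, -1, 0.5)
  # A = 0 -> lands exactly on the best
  expect_equal(encircling_update(c(1, 1, 1), Xb, rep(0, 3), rep(1.3, 3)), Xb)
  # C = 1, X = Xbest -> D = 0 -> stays at best
  expect_equal(encircling_update(Xb, Xb, rep(0.4, 3), rep(1, 3)), Xb)
  # scalar substitution: Xbest=2, X=1, C=1, A=1 -> D=1, result=1
  expect_equal(encircling_update(1, 2, 1, 1), 1)
  expect_error(encircling_update(1:2, 1:3, 0, 1), "dimension mismatch")
})

test_that("spiral update matches its closed form and fixed points", {
  Xb <- c(0.3, -2)
  expect_equal(spiral_update(Xb, Xb, b = 1, l = 0.6), Xb)       # D' = 0
  expect_equal(spiral_update(c(1, 1), Xb, b = 1, l = 0),        # e^0 cos0 = 1
               abs(Xb - c(1, 1)) + Xb)
  expect_equal(spiral_update(c(1, 1), Xb, b = 1, l = 0.25), Xb,  # cos(pi/2)=0
               tolerance = 1e-12)
})

test_that("random search update matches its closed form and clips", {
  Xr <- c(3, -3)
  expect_equal(random_search_update(c(1, 1), Xr, rep(0, 2), rep(1, 2)), Xr)
  expect_equal(random_search_update(Xr, Xr, rep(0.9, 2), rep(1, 2)), Xr)
  # Xrand=3, X=1, C=1, A=-1 -> D=2, result=5, clipped to bound 4
  expect_equal(random_search_update(1, 3, -1, 1, clip = 4), 4)
  expect_equal(random_search_update(1, 3, -1, 1, clip = 6), 5)
})

test_that("whale_step dispatches on p and |A| as specified", {
  params <- woa_params(n_agents = 3, n_iterations = 10)
  pop <- rbind(c(0, 0), c(1, 1), c(2, 2))
  Xb <- c(1, -1)
  # p = 0.9 -> spiral for every dimension (queued l draw follows p)
  st <- whale_step(c(0, 0), Xb, pop, a = 1, params, stub_rng(c(0.9, 0.5)))
  expect_true(all(st$trace$branch == "spiral"))
  expect_equal(st$position, spiral_update(c(0, 0), Xb, params$b, 0, params$clip))
  # p = 0.1 with r1 = 0.5 -> A = 0 (<1): pure encircling
  st <- whale_step(c(0, 0), Xb, pop, a = 1,
                   params, stub_rng(c(0.1, 0.5, 0.5, 0.3, 0.3), sample_vals = 2))
  expect_true(all(st$trace$branch == "encircle"))
  expect_equal(st$position, Xb)  # A = 0 contracts onto the best
  # p = 0.1 with r1 = 1 at a = 2 -> A = 2 (>=1): pure random search
  st <- whale_step(c(0, 0), Xb, pop, a = 2,
                   params, stub_rng(c(0.1, 1, 1, 0.5, 0.5), sample_vals = 3))
  expect_true(all(st$trace$branch == "search"))
  expect_equal(st$trace$rand_agent, 3)
  expect_equal(st$position,
               random_search_update(c(0, 0), c(2, 2), c(2, 2), c(1, 1),
                                    params$clip))
})

test_that("positions stay within the clip bound through many steps", {
  params <- woa_params(n_agents = 4, n_iterations = 20, clip = 6)
  rng <- local_rng(21)
  pop <- matrix(rng$runif(4 * 3, -6, 6), 4, 3)
  Xb <- pop[1, ]
  for (t in 1:20) {
    a <- control_scalar(t, 20)
    for (i in 1:4) {
      st <- whale_step(pop[i, ], Xb, pop, a, params, rng)
      pop[i, ] <- st$position
      expect_true(all(abs(st$position) <= params$clip + 1e-12))
    }
  }
})

test_that("coefficient draw distribution is centred as specified", {
  rng <- local_rng(33)
  co <- draw_coefficients(1, 1e5, rng)
  expect_lt(abs(mean(co$C) - 1), 0.02)
  expect_lt(abs(mean(co$A)), 0.02)
})

test_that("identical seed gives identical step sequences", {
  params <- woa_params(n_agents = 3, n_iterations = 5)
  run_steps <- function(seed) {
    rng <- local_rng(seed)
    pop <- matrix(rng$runif(6, -2, 2), 3, 2)
    out <- list()
    for (i in 1:3) {
      st <- whale_step(pop[i, ], pop[1, ], pop, 1.2, params, rng)
      out[[i]] <- st
    }
    out
  }
  expect_identical(run_steps(77), run_steps(77))
})
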