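test_that("firing rate has the right limit, tails and monotonicity", {
  p <- mfm_params()
  # removable singularity at a x = b: limit 1/d
  expect_lt(abs(mfm_firing_rate(p$b / p$a, p) - 1 / p$d), 1e-12)
  expect_lt(abs(mfm_firing_rate(p$b / p$a + 1e-9, p) - 1 / p$d), 1e-6)
  expect_lt(abs(mfm_firing_rate(p$b / p$a - 1e-9, p) - 1 / p$d), 1e-6)
  # x = 1: exp(-d(a-b)) is negligible, H ~ a - b = 162 Hz
  expect_equal(mfm_firing_rate(1, p), p$a - p$b, tolerance = 1e-8)
  # x = 0: tiny but positive
  h0 <- mfm_firing_rate(0, p)
  expect_gt(h0, 0)
  expect_lt(h0, 1e-5)
  # nondecreasing over a wide input grid
  grid <- seq(-1, 2, by = 1e-3)
  expect_true(all(diff(mfm_firing_rate(grid, p)) >= 0))
})

test_that("linear firing-rate variant is the chord of H over the S-bounds", {
  p <- mfm_params(firing_rate = "linear")
  pn <- mfm_params()
  x_lo <- p$I0
  x_hi <- p$w * p$J + p$I0
  expect_equal(mfm_firing_rate(x_lo, p), mfm_firing_rate(x_lo, pn))
  expect_equal(mfm_firing_rate(x_hi, p), mfm_firing_rate(x_hi, pn))
  # affine in between
  xm <- (x_lo + x_hi) / 2
  expect_equal(mfm_firing_rate(xm, p),
               (mfm_firing_rate(x_lo, p) + mfm_firing_rate(x_hi, p)) / 2)
  # explicit override wins
  po <- mfm_params(firing_rate = "linear", lin_slope = 2, lin_icpt = 1)
  expect_equal(mfm_firing_rate(3, po), 7)
})

test_that("drift functions match the model equations", {
  two <- as_connectome(matrix(c(0, 1, 1, 0), 2, 2))
  # LSM arithmetic: x = (1,1), G = 0.5 -> drift (-0.5, -0.5)
  expect_equal(unname(lsm_drift(c(1, 1), two, lsm_params(G = 0.5))),
               c(-0.5, -0.5))
  expect_equal(unname(lsm_drift(c(0, 0), two, lsm_params(G = 0.5))), c(0, 0))
  # linearity
  sc <- synthetic_connectome(6, "dense-random", 0.3, seed = 2)
  p <- lsm_params(G = 0.01)
  x <- runif(6); y <- runif(6)
  expect_equal(lsm_drift(x + y, sc, p),
               lsm_drift(x, sc, p) + lsm_drift(y, sc, p))

  # MFM: G = 0 decouples nodes
  pm <- mfm_params(G = 0)
  s1 <- runif(6, 0, 1)
  s2 <- s1; s2[-3] <- runif(5)
  expect_equal(mfm_drift(s1, sc, pm)[3], mfm_drift(s2, sc, pm)[3])
  # S = 1: gating saturated, drift strictly negative
  expect_true(all(mfm_drift(rep(1, 6), sc, mfm_params(G = 0.01)) < 0))
  # agreement with an independent transcription of the equations
  expect_equal(unname(mfm_drift(s1, sc, mfm_params(G = 0.02))),
               mfm_drift_oracle(s1, sc$weights, G = 0.02), tolerance = 1e-12)
  expect_error(mfm_drift(c(0.1, 0.2), sc, pm), "match")
  expect_error(lsm_drift(c(0.1, 0.2), sc, p), "match")
})

test_that("Euler integration matches the matrix-exponential solution at O(dt)", {
  skip_if_not_installed("Matrix")
  sc <- synthetic_connectome(5, "dense-random", 0.4, seed = 8)
  G <- 0.5 / max(eigen(sc$weights, symmetric = TRUE, only.values = TRUE)$values)
  A <- -diag(5) + G * sc$weights
  x0 <- runif(5)
  closed <- function(t) as.numeric(Matrix::expm(t * A) %*% x0)

  # the LSM decay rate is O(1) per ms, so the comparison horizon must keep
  # the state representable: 5 ms spans ~2.5-10 relaxation times here
  t_cmp <- 5
  ref <- closed(t_cmp)
  xT <- simulate_dynamics("lsm", sc, lsm_params(G = G), x0,
                          duration = t_cmp, dt = 0.001)$state
  expect_lt(max(abs(xT - ref)) / max(abs(ref)), 1e-3)

  # halving dt halves the global error (first-order convergence)
  err <- vapply(c(0.2, 0.1, 0.05), function(dt) {
    max(abs(simulate_dynamics("lsm", sc, lsm_params(G = G), x0,
                              duration = t_cmp, dt = dt)$state - ref))
  }, numeric(1))
  expect_lt(err[2] / err[1], 0.7)
  expect_lt(err[3] / err[2], 0.7)
})

test_that("clamped and frozen nodes never leave their held values", {
  sc <- synthetic_connectome(8, "dense-random", 0.3, seed = 4)
  init <- runif(8)
  out <- simulate_dynamics("lsm", sc, lsm_params(G = 0.01), init,
                           duration = 2000, record_every = 50,
                           clamp = list(idx = 2, value = 0.77), frozen = 5)
  expect_true(all(out$trajectory[, 2] == 0.77))
  expect_true(all(out$trajectory[, 5] == init[5]))
  expect_equal(unname(out$state[2]), 0.77)
  expect_error(simulate_dynamics("lsm", sc, lsm_params(), init, 100,
                                 clamp = list(idx = 3, value = 1), frozen = 3),
               "disjoint")
})

test_that("noisy integration is seed-reproducible", {
  sc <- synthetic_connectome(6, "dense-random", 0.3, seed = 9)
  p <- lsm_params(G = 0.005, sigma = 0.05)
  a <- simulate_dynamics("lsm", sc, p, rep(0, 6), 1000, noise = TRUE, seed = 5)
  b <- simulate_dynamics("lsm", sc, p, rep(0, 6), 1000, noise = TRUE, seed = 5)
  d <- simulate_dynamics("lsm", sc, p, rep(0, 6), 1000, noise = TRUE, seed = 6)
  expect_identical(a$state, b$state)
  expect_false(identical(a$state, d$state))
})

test_that("divergence is reported with step and node", {
  two <- as_connectome(matrix(c(0, 1, 1, 0), 2, 2))
  expect_error(
    simulate_dynamics("lsm", two, lsm_params(G = 5), c(1, 1), 5000),
    "diverged at step [0-9]+ .* node [0-9]+")
  out <- simulate_dynamics("lsm", two, lsm_params(G = 5), c(1, 1), 5000,
                           on_divergence = "flag")
  expect_true(out$diverged)
  expect_true(out$step > 0)
})

test_that("settling contracts the LSM to zero and is idempotent", {
  sc <- synthetic_connectome(10, "dense-random", 0.3, seed = 6)
  G <- 0.5 / max(eigen(sc$weights, symmetric = TRUE, only.values = TRUE)$values)
  st <- settle_steady_state("lsm", sc, lsm_params(G = G), seed = 3)
  expect_lt(max(abs(st)), 1e-8)
  st2 <- settle_steady_state("lsm", sc, lsm_params(G = G),
                             init = as.numeric(st), t_settle = 1000)
  expect_lt(max(abs(st2 - st)), 1e-10)
  # norm shrinks under contraction within 5 s from any [0,1] start
  x0 <- runif(10)
  xT <- simulate_dynamics("lsm", sc, lsm_params(G = G), x0, 5000)$state
  expect_lt(sqrt(sum(xT^2)), sqrt(sum(x0^2)))
})

test_that("a too-short settle raises a not-settled error", {
  ring <- ring_sc(10)
  expect_error(
    settle_steady_state("lsm", ring, lsm_params(G = 0.499), seed = 1,
                        t_settle = 20),
    "not settled")
})

test_that("MFM settling stays in [0, 1+eps] and matches a root-solve oracle", {
  skip_if_not_installed("pracma")
  sc <- synthetic_connectome(10, "dense-random", 0.3, seed = 3)
  G <- 0.05 / (0.2609 * mean(node_strength(sc)))
  p <- mfm_params(G = G)
  out <- simulate_dynamics("mfm", sc, p, runif(10), 60000, record_every = 100)
  expect_true(all(out$trajectory >= 0 & out$trajectory <= 1 + 1e-3))
  st <- settle_steady_state("mfm", sc, p, seed = 2)
  expect_lt(attr(st, "max_drift"), 1e-8)
  root <- pracma::fsolve(function(S) mfm_drift_oracle(S, sc$weights, G = G),
                         as.numeric(st), tol = 1e-12)$x
  expect_lt(max(abs(st - root)), 1e-6)
})

test_that("bistability scan: decoupled MFM settles low; labels reproducible", {
  sc <- synthetic_connectome(8, "dense-random", 0.3, seed = 12)
  bs <- mfm_bistability_scan(sc, mfm_params(), G_grid = 0, trials = 3,
                             t_evolve = 20000, seed = 4)
  expect_equal(bs$regime, "low-only")
  bs2 <- mfm_bistability_scan(sc, mfm_params(), G_grid = 0, trials = 3,
                              t_evolve = 20000, seed = 4)
  expect_identical(bs, bs2)
})

test_that("LSM stability threshold matches the spectral radius", {
  # analytic 2-node case: lambda_max = 1
  two <- as_connectome(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(lsm_stability_threshold(two, seed = 1), 1, tolerance = 0.011)
  # ring of 20: lambda_max = 2
  expect_equal(lsm_stability_threshold(ring_sc(20), seed = 1), 0.5,
               tolerance = 0.011)
  # scaling the weights by k divides the threshold by k
  k <- 2
  scaled <- as_connectome(k * ring_sc(20)$weights)
  expect_equal(lsm_stability_threshold(scaled, G_step = 0.005, seed = 1),
               0.25, tolerance = 0.0051)
})
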