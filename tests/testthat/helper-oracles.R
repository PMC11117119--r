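# Shared fixtures and independent oracles. Everything here is algebraic or
# closed-form, independent of the package's Euler integrator.

ring_sc <- function(n, weight = 1) {
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    w[i, j] <- w[j, i] <- weight
  }
  as_connectome(w)
}

chain_sc <- function(n = 3) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) w[i, i + 1] <- w[i + 1, i] <- 1
  as_connectome(w)
}

# clamped-linear-system transfer: column n = steady state of the free nodes
# when node n is held at 1 (nodes in `excl` removed from the network)
lin_transfer <- function(C, G, excl = integer(0)) {
  n <- nrow(C)
  g <- matrix(0, n, n)
  for (src in setdiff(seq_len(n), excl)) {
    free <- setdiff(seq_len(n), c(src, excl))
    g[free, src] <- solve(diag(length(free)) - G * C[free, free],
                          G * C[free, src])
  }
  g
}

# analytic response matrix for the LSM with trivial (floored) steady state:
# R_mn = (1 + alpha) g_mn / alpha, zero diagonal
lin_response_oracle <- function(C, G, alpha, excl = integer(0)) {
  R <- (1 + alpha) / alpha * lin_transfer(C, G, excl)
  diag(R) <- 0
  R
}

# mean-field drift transcribed directly from the model equations (kept
# separate from the package implementation on purpose)
mfm_drift_oracle <- function(S, C, G, w = 0.9, J = 0.2609, I0 = 0.3,
                             gamma = 0.641 / 1000, tauS = 100,
                             a = 270, b = 108, d = 0.154) {
  x <- w * J * S + G * J * as.numeric(C %*% S) + I0
  u <- a * x - b
  H <- ifelse(abs(u) < 1e-8, 1 / d, u / (1 - exp(-d * u)))
  -S / tauS + (1 - S) * gamma * H
}

expect_valid_connectome <- function(sc) {
  expect_s3_class(sc, "connectome")
  w <- sc$weights
  expect_true(all(is.finite(w)))
  expect_identical(w, t(w))
  expect_true(all(diag(w) == 0))
  expect_true(all(w >= 0))
  expect_gte(sc$n_nodes, 2)
}
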