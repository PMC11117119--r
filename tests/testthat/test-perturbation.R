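test_that("perturbation config validates its invariants", {
  expect_error(perturbation_config(alpha = 0), "alpha")
  expect_error(perturbation_config(alpha = -1.5), "alpha")
  expect_error(perturbation_config(t_perturb = -5), "t_perturb")
  expect_equal(perturbation_config()$alpha, -0.1)
})

test_that("decoupled nodes elicit no response", {
  sc <- synthetic_connectome(6, "dense-random", 0.3, seed = 2)
  R <- response_matrix("lsm", sc, lsm_params(G = 0), seed = 1)
  expect_true(all(R == 0))
})

test_that("simulated LSM responses match the clamped-linear-system oracle", {
  for (seed in c(3, 4)) {
    sc <- synthetic_connectome(if (seed == 3) 5 else 10, "dense-random",
                               0.3, seed = seed)
    lam <- max(eigen(sc$weights, symmetric = TRUE, only.values = TRUE)$values)
    G <- 0.5 / lam
    R <- response_matrix("lsm", sc, lsm_params(G = G), seed = 1)
    Rex <- lin_response_oracle(sc$weights, G, alpha = -0.1)
    expect_lt(max(abs(unclass(R) - Rex)), 1e-4)
  }
  # the 2-node worked case: R_21 = (1 + alpha) G / alpha = -4.5
  two <- as_connectome(matrix(c(0, 1, 1, 0), 2, 2))
  R2 <- response_matrix("lsm", two, lsm_params(G = 0.5), seed = 1)
  expect_equal(R2[2, 1], 0.9 * 0.5 / -0.1, tolerance = 1e-3)
})

test_that("doubling the perturbed relaxation time changes nothing (settled)", {
  sc <- synthetic_connectome(6, "dense-random", 0.3, seed = 5)
  G <- 0.5 / max(eigen(sc$weights, symmetric = TRUE, only.values = TRUE)$values)
  steady <- settle_steady_state("lsm", sc, lsm_params(G = G), seed = 1)
  r1 <- response_column("lsm", sc, lsm_params(G = G), steady, 2,
                        perturbation_config())
  r2 <- response_column("lsm", sc, lsm_params(G = G), steady, 2,
                        perturbation_config(t_perturb = 10000))
  expect_lt(max(abs(r1 - r2)), 1e-6)
})

test_that("node relabeling conjugates the response matrix", {
  sc <- synthetic_connectome(7, "dense-random", 0.3, seed = 6)
  G <- 0.5 / max(eigen(sc$weights, symmetric = TRUE, only.values = TRUE)$values)
  R <- response_matrix("lsm", sc, lsm_params(G = G), seed = 1)
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  sp <- as_connectome(sc$weights[perm, perm], sc$node_ids[perm])
  Rp <- response_matrix("lsm", sp, lsm_params(G = G), seed = 1)
  expect_equal(unclass(Rp), unclass(R)[perm, perm], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("an isolated node has zero response row and column", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1  # node 4 isolated
  sc <- as_connectome(w)
  R <- response_matrix("lsm", sc, lsm_params(G = 0.4), seed = 1)
  expect_true(all(R[4, ] == 0))
  expect_true(all(R[, 4] == 0))
  # and lesioning it leaves the rest of R untouched
  steady <- settle_steady_state("lsm", sc, lsm_params(G = 0.4), seed = 1)
  R4 <- lesioned_response("lsm", sc, lsm_params(G = 0.4), steady, 4,
                          perturbation_config())
  expect_lt(max(abs(unclass(R4)[-4, -4] - unclass(R)[-4, -4])), 1e-8)
  # flow through the isolated node is exactly zero; it is also excluded
  # as a source (Z_4 = 0)
  lesions <- lapply(1:4, function(i)
    lesioned_response("lsm", sc, lsm_params(G = 0.4), steady, i,
                      perturbation_config()))
  fl <- flow_centrality(R, lesions)
  expect_equal(unname(fl$F[4]), 0)
  expect_true(4 %in% fl$excluded_sources)
})

test_that("net influence is the column-row asymmetry and is conserved", {
  R <- matrix(c(0, 1, 0, 2, 0, 0, 0, 0, 0), 3, 3)  # R[1,2] = 2, R[2,1] = 1
  expect_equal(net_influence(R), c(-1, 1, 0))
  expect_equal(net_influence(t(R)), -net_influence(R))
  sym <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(net_influence(sym), c(0, 0))
  for (seed in 1:20) {
    sc <- synthetic_connectome(8, "dense-random", 0.5, seed = seed)
    gs <- 0.6 / max(eigen(sc$weights, symmetric = TRUE,
                          only.values = TRUE)$values)
    R <- response_matrix("lsm", sc, lsm_params(G = gs), seed = seed)
    I <- net_influence(R)
    expect_lt(abs(sum(I)), 1e-10 * sum(abs(I)))
  }
})

test_that("total response sums each column without the diagonal", {
  R <- matrix(0, 3, 3)
  R[, 1] <- c(0, 1, 2)
  expect_equal(unname(total_response(R)), c(3, 0, 0))
  expect_equal(total_response(R, 1), 3)
  expect_equal(total_response(2 * R, 1), 6)  # linear in R
  expect_equal(unname(total_response(matrix(0, 4, 4))), rep(0, 4))
})

test_that("exact lesioning severs all paths through the frozen node", {
  chain <- chain_sc(3)
  p <- lsm_params(G = 0.4)
  steady <- settle_steady_state("lsm", chain, p, seed = 1)
  R2 <- lesioned_response("lsm", chain, p, steady, 2, perturbation_config())
  expect_equal(R2[3, 1], 0)
  expect_equal(R2[1, 3], 0)
  expect_true(all(R2[2, ] == 0))
  expect_true(all(R2[, 2] == 0))  # frozen node is skipped as a source
  # oracle: clamped + frozen linear solve
  Rex <- lin_response_oracle(chain$weights, 0.4, -0.1, excl = 2)
  Rex[2, ] <- Rex[, 2] <- 0
  expect_lt(max(abs(unclass(R2) - Rex)), 1e-8)
})

test_that("approximate lesioning follows the composition formula", {
  R <- matrix(0.05, 4, 4)
  diag(R) <- 0
  R[2, 3] <- 0.5; R[2, 1] <- 0.2; R[1, 3] <- 0.3
  Ra <- lesion_approx(R, 1)
  expect_equal(Ra[2, 3], 0.5 - 0.2 * 0.3)  # 0.44
  expect_true(all(Ra[1, ] == 0) && all(Ra[, 1] == 0))
  # zero middle factor: lesioned responses equal the originals
  R0 <- R
  R0[, 1] <- 0
  Ra0 <- lesion_approx(R0, 1)
  expect_equal(unclass(Ra0)[-1, -1], R0[-1, -1], ignore_attr = TRUE)
})

test_that("exact and approximate lesions agree near a nondegenerate steady state", {
  # MFM with weak coupling: steady states are finite and nonzero, the regime
  # in which the composition approximation is valid
  sc <- synthetic_connectome(10, "dense-random", 0.3, seed = 3)
  G <- 0.1 / (0.2609 * mean(node_strength(sc)))
  p <- mfm_params(G = G)
  cfg <- perturbation_config(alpha = -0.01)
  steady <- settle_steady_state("mfm", sc, p, seed = 1)
  R <- response_matrix("mfm", sc, p, cfg, steady = steady)
  lex <- lapply(1:10, function(i) lesioned_response("mfm", sc, p, steady, i, cfg))
  lap <- lapply(1:10, function(i) lesion_approx(R, i))
  err <- max(vapply(1:10, function(i)
    max(abs(unclass(lap[[i]]) - unclass(lex[[i]]))), numeric(1)))
  expect_lt(err, 1e-3)
  # and the two flow routes rank nodes identically
  Fex <- flow_centrality(R, lex)$F
  Fap <- flow_centrality(R, lap)$F
  expect_gt(cor(Fex, Fap, method = "spearman"), 0.95)
})

test_that("flow captures total lesion impact: middle of a chain carries all", {
  chain <- chain_sc(3)
  pa <- perturb_analysis(chain, "lsm", lsm_params(G = 0.4), lesion = "exact",
                         seed = 1)
  f <- unname(pa$flow$F)
  # lesioning the middle kills every response: flow exactly 1
  expect_equal(f[2], 1)
  expect_gt(f[2], f[1])
  expect_gt(f[2], f[3])
  expect_equal(f[1], f[3], tolerance = 1e-10)
})

test_that("flow errors when no admissible source remains", {
  R <- matrix(0, 3, 3)  # all Z_n = 0
  lesions <- lapply(1:3, function(i) lesion_approx(R, i))
  expect_error(flow_centrality(R, lesions), "no admissible source")
})

test_that("the pipeline produces consistent, reproducible artifacts", {
  sc <- synthetic_connectome(20, "dense-random", 0.3, seed = 10)
  gs <- lsm_stability_threshold(sc, seed = 1)
  pa <- perturb_analysis(sc, "lsm", lsm_params(G = 0.8 * gs), seed = 2)
  expect_true(all(is.finite(pa$R)))
  expect_true(all(diag(pa$R) == 0))
  expect_lt(abs(sum(pa$influence)), 1e-10 * sum(abs(pa$influence)))
  expect_true(all(is.finite(pa$flow$F)))
  pa2 <- perturb_analysis(sc, "lsm", lsm_params(G = 0.8 * gs), seed = 2)
  expect_identical(pa$R, pa2$R)
  expect_identical(pa$flow$F, pa2$flow$F)
  df <- as.data.frame(pa)
  expect_named(df, c("node_id", "strength", "net_influence", "flow"))
  expect_equal(nrow(df), 20)
  expect_output(print(pa), "Perturbation analysis")
})

test_that("strength-regular networks show no influence asymmetry (null)", {
  ring <- ring_sc(12)
  pa <- perturb_analysis(ring, "lsm", lsm_params(G = 0.3), lesion = "exact",
                         seed = 2)
  expect_lt(max(abs(pa$influence)), 1e-6)
  expect_lt(diff(range(pa$flow$F)), 1e-6)
})
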