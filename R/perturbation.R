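#' Perturbation protocol configuration
#'
#' Settings of the clamped-perturbation protocol: the system is first
#' settled noiselessly for `t_settle` ms; each node `n` in turn is clamped
#' at `(1 + alpha) x_n` while the rest relax for `t_perturb` ms to the
#' perturbed steady state. The default `alpha = -0.1` perturbs downward,
#' which avoids kicking the dynamics into an unstable regime.
#'
#' When a node's unperturbed steady state is trivial (smaller in magnitude
#' than `trivial_floor`), the floor value `1e-60` is substituted wherever the
#' steady state is divided by — in the response denominator and as the seed
#' of the source clamp `(1 + alpha) * floor` — so the relative response
#' remains defined. Everywhere else (initialization, frozen lesion values,
#' the numerator difference) the true steady state is used; see the package
#' vignette for why this reading is the consistent one.
#'
#' @param alpha Relative perturbation strength (nonzero, `|alpha| < 1`).
#' @param t_settle Unperturbed settling time (ms, default 60 s).
#' @param t_perturb Clamped relaxation time (ms, default 5 s).
#' @param trivial_floor Magnitude below which a steady state is treated as
#'   trivial (default 1e-60).
#' @param settle_tol Residual drift tolerance (1/ms).
#' @param z_floor Sources whose total response is below this magnitude are
#'   excluded from flow averages (avoids 0/0).
#' @param dt Euler step (ms).
#' @return A classed list (`perturbation_config`).
#' @export
perturbation_config <- function(alpha = -0.1, t_settle = 60000,
                                t_perturb = 5000, trivial_floor = 1e-60,
                                settle_tol = 1e-8, z_floor = 1e-12, dt = 1) {
  stopifnot(alpha != 0, abs(alpha) < 1, t_settle > 0, t_perturb > 0,
            trivial_floor > 0, settle_tol > 0, dt > 0)
  structure(list(alpha = alpha, t_settle = t_settle, t_perturb = t_perturb,
                 trivial_floor = trivial_floor, settle_tol = settle_tol,
                 z_floor = z_floor, dt = dt),
            class = "perturbation_config")
}

# steady-state values with trivial entries replaced by the floor, for use in
# divisions and as the source-clamp seed
floor_steady <- function(steady, floor) {
  ifelse(abs(steady) < floor, floor, steady)
}

#' Response of the network to clamping one node
#'
#' Clamps node `source` at `(1 + alpha) x_n`, initializes all other nodes at
#' the unperturbed steady state, relaxes noiselessly for `t_perturb` ms,
#' verifies settling, and returns the column of relative responses
#' \deqn{R_{mn} = \frac{\tilde x_m - x_m}{\alpha\, x_m}, \qquad m \ne n,}
#' with `0` at the source position (diagonal convention).
#'
#' @inheritParams simulate_dynamics
#' @param steady Unperturbed steady state (from [settle_steady_state()]).
#' @param source Node index to perturb.
#' @param cfg A [perturbation_config()].
#' @param frozen Optional node indices held at their unperturbed steady
#'   values (functional lesion); responses at frozen nodes are zero.
#' @return Numeric response vector of length `N`.
#' @export
response_column <- function(model, sc, params, steady, source,
                            cfg = perturbation_config(),
                            frozen = integer(0)) {
  sc <- as_sc(sc)
  n <- sc$n_nodes
  stopifnot(length(steady) == n, source >= 1, source <= n,
            !(source %in% frozen))
  sdiv <- floor_steady(steady, cfg$trivial_floor)
  clamp_value <- (1 + cfg$alpha) * sdiv[source]
  perturbed <- tryCatch(
    settle_steady_state(model, sc, params, init = as.numeric(steady),
                        t_settle = cfg$t_perturb, dt = cfg$dt,
                        tol = cfg$settle_tol,
                        clamp = list(idx = source, value = clamp_value),
                        frozen = frozen),
    error = function(e) {
      if (grepl("diverged", conditionMessage(e)))
        stop("perturbed run diverged (source ", source,
             "); try a smaller |alpha|. ", conditionMessage(e), call. = FALSE)
      stop(conditionMessage(e), call. = FALSE)
    })
  r <- (as.numeric(perturbed) - as.numeric(steady)) / (cfg$alpha * sdiv)
  r[source] <- 0
  if (length(frozen)) r[frozen] <- 0
  r
}

#' Linear response matrix of a network dynamical system
#'
#' Runs the full perturbation protocol: one noiseless settle to the
#' unperturbed steady state, then one clamped relaxation per source node.
#' Column `n` holds the relative steady-state responses of all nodes to
#' clamping node `n` at `(1 + alpha) x_n`; the diagonal is fixed at 0.
#' The protocol is noiseless, hence deterministic given the initial state.
#'
#' @inheritParams response_column
#' @param steady Optional precomputed steady state; settled from a seeded
#'   uniform `[0, 1]` initial condition when omitted.
#' @param seed Seed for the settling initial condition.
#' @return An `N x N` matrix of class `response_matrix` with attributes
#'   `alpha`, `model` and `steady`.
#' @examples
#' sc <- synthetic_connectome(10, "dense-random", 0.5, seed = 1)
#' gs <- lsm_stability_threshold(sc)
#' R <- response_matrix("lsm", sc, lsm_params(G = 0.5 * gs), seed = 1)
#' net_influence(R)
#' @export
response_matrix <- function(model = c("lsm", "mfm"), sc, params,
                            cfg = perturbation_config(), steady = NULL,
                            seed = 1L) {
  model <- match.arg(model)
  sc <- as_sc(sc)
  if (is.null(steady))
    steady <- settle_steady_state(model, sc, params, t_settle = cfg$t_settle,
                                  dt = cfg$dt, tol = cfg$settle_tol,
                                  seed = seed)
  n <- sc$n_nodes
  R <- matrix(0, n, n, dimnames = list(sc$node_ids, sc$node_ids))
  for (src in seq_len(n))
    R[, src] <- response_column(model, sc, params, steady, src, cfg)
  structure(R, class = c("response_matrix", "matrix", "array"),
            alpha = cfg$alpha, model = model, steady = as.numeric(steady))
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Linear response matrix: %d nodes (alpha = %g, %s model)\n",
              nrow(x), attr(x, "alpha"), toupper(attr(x, "model"))))
  m <- unclass(x)
  attr(m, "alpha") <- attr(m, "model") <- attr(m, "steady") <- NULL
  print(head(m[, seq_len(min(6, ncol(m))), drop = FALSE], 6), digits = 4)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Total response elicited by perturbing each node
#'
#' `Z_n = sum_{m != n} R_mn`: the summed relative response of the whole
#' network to clamping source `n` (column sums of the response matrix under
#' the zero-diagonal convention).
#'
#' @param R A response matrix.
#' @param n Optional single source index; returns the full vector otherwise.
#' @return Numeric vector `Z` (or scalar `Z_n`).
#' @export
total_response <- function(R, n = NULL) {
  Z <- colSums(R)
  if (is.null(n)) Z else Z[[n]]
}

#' Net influence of every node
#'
#' The response asymmetry `I_i = sum_m R_mi - sum_m R_im` (responses the node
#' elicits in the network minus responses the network elicits in it).
#' Positive values mark influencers, negative values followers; the vector
#' sums to zero by construction.
#'
#' @param R A response matrix.
#' @return Named numeric vector of net influences.
#' @export
net_influence <- function(R) {
  colSums(R) - rowSums(R)
}

#' Response matrix under a functional lesion
#'
#' A functional lesion freezes node `i` at its unperturbed steady-state
#' value, so it neither responds to perturbations nor transmits them.
#' `method = "exact"` reruns the whole clamped-perturbation protocol with
#' node `i` frozen (skipping `i` as a source); `method = "approx"` uses the
#' small-perturbation composition approximation
#' `R^{i}_mn = R_mn - R_mi R_in`, which only needs the unlesioned matrix.
#' Row and column `i` are zero in either case.
#'
#' Note the approximation is only meaningful near a nondegenerate steady
#' state; with trivial (floored) steady states — the LSM below its stability
#' threshold — the unlesioned responses scale like `1/alpha` and the product
#' term overshoots, so `"exact"` is the reliable route there.
#'
#' @inheritParams response_column
#' @param lesioned Index of the frozen node.
#' @param R Precomputed [response_matrix()] (required for `"approx"`;
#'   optional for `"exact"`).
#' @param method `"exact"` or `"approx"`.
#' @return An `N x N` matrix of class `lesioned_response` with attributes
#'   `lesioned` and `method`.
#' @export
lesioned_response <- function(model, sc, params, steady = NULL, lesioned,
                              cfg = perturbation_config(),
                              method = c("exact", "approx"), R = NULL,
                              seed = 1L) {
  method <- match.arg(method)
  if (method == "approx") {
    if (is.null(R)) {
      R <- response_matrix(model, sc, params, cfg, steady = steady,
                           seed = seed)
    }
    return(lesion_approx(R, lesioned))
  }
  sc <- as_sc(sc)
  n <- sc$n_nodes
  stopifnot(lesioned >= 1, lesioned <= n)
  if (is.null(steady))
    steady <- settle_steady_state(model, sc, params, t_settle = cfg$t_settle,
                                  dt = cfg$dt, tol = cfg$settle_tol,
                                  seed = seed)
  Ri <- matrix(0, n, n, dimnames = list(sc$node_ids, sc$node_ids))
  for (src in setdiff(seq_len(n), lesioned)) {
    Ri[, src] <- response_column(model, sc, params, steady, src, cfg,
                                 frozen = lesioned)
  }
  structure(Ri, class = c("lesioned_response", "matrix", "array"),
            lesioned = lesioned, method = "exact")
}

#' @rdname lesioned_response
#' @export
lesion_approx <- function(R, lesioned) {
  n <- nrow(R)
  stopifnot(lesioned >= 1, lesioned <= n)
  Ri <- unclass(R) - outer(R[, lesioned], R[lesioned, ])
  Ri[lesioned, ] <- 0
  Ri[, lesioned] <- 0
  diag(Ri) <- 0
  attr(Ri, "alpha") <- attr(Ri, "model") <- attr(Ri, "steady") <- NULL
  structure(Ri, class = c("lesioned_response", "matrix", "array"),
            lesioned = lesioned, method = "approx")
}

#' Flow centrality from lesioned response matrices
#'
#' For each lesioned node `i` and admissible source `n != i`, the flow
#' \deqn{F^i_n = \frac{Z_n - Z^{i}_n}{Z_n}}
#' is the fractional reduction of the total response elicited by `n` when
#' `i` is frozen (`Z^{i}_n = sum_{m \notin \{n, i\}} R^{i}_{mn}`); the flow
#' through node `i` is the average of `F^i_n` over admissible sources.
#' Sources with `|Z_n|` below `z_floor` are excluded from the average (and
#' recorded), since their flow fraction is 0/0.
#'
#' @param R The unlesioned [response_matrix()].
#' @param lesioned_responses List of `N` lesioned matrices (entry `i` for
#'   lesioning node `i`), from [lesioned_response()] / [lesion_approx()].
#' @param z_floor Admissibility floor on `|Z_n|`.
#' @return An object of class `flow_result`: list with `F` (per-node flow),
#'   `F_per_source` (`N x N`, entry `[n, i]` = flow through `i` for source
#'   `n`), `Z`, `Z_lesioned` (`[n, i]`), and `excluded_sources`.
#' @export
flow_centrality <- function(R, lesioned_responses, z_floor = 1e-12) {
  n <- nrow(R)
  stopifnot(length(lesioned_responses) == n)
  Z <- total_response(R)
  admissible <- abs(Z) > z_floor
  Fmat <- matrix(NA_real_, n, n, dimnames = dimnames(R))
  Zles <- matrix(NA_real_, n, n, dimnames = dimnames(R))
  Fbar <- stats::setNames(numeric(n), rownames(R))
  for (i in seq_len(n)) {
    Zi <- total_response(lesioned_responses[[i]])
    sources <- setdiff(which(admissible), i)
    if (!length(sources))
      stop("flow undefined for node ", i,
           ": no admissible source (all |Z_n| <= z_floor)")
    Fmat[sources, i] <- (Z[sources] - Zi[sources]) / Z[sources]
    Zles[, i] <- Zi
    Zles[i, i] <- NA_real_
    Fbar[i] <- mean(Fmat[sources, i])
  }
  structure(list(F = Fbar, F_per_source = Fmat, Z = Z, Z_lesioned = Zles,
                 excluded_sources = which(!admissible)),
            class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("Flow centrality over %d nodes", length(x$F)))
  if (length(x$excluded_sources))
    cat(sprintf(" (%d source(s) excluded: |Z| below floor)",
                length(x$excluded_sources)))
  cat("\n")
  print(summary(unname(x$F)))
  invisible(x)
}

#' End-to-end perturbation analysis of a connectome
#'
#' Orchestrates the full protocol: settle to the unperturbed steady state,
#' assemble the response matrix, derive net influence, lesion every node
#' (exactly or via the composition approximation), and compute flow
#' centrality. Results are returned in a single classed object with
#' `print()`, `summary()`, `plot()` and `as.data.frame()` methods.
#'
#' @inheritParams response_matrix
#' @param lesion `"approx"` (default; one protocol run) or `"exact"`
#'   (`N + 1` protocol runs).
#' @return An object of class `perturbation_analysis`: list with `R`,
#'   `influence`, `flow` (a [flow_centrality()] result), `strength`,
#'   `steady`, `model`, `params`, `cfg`, `lesion`, `seed`.
#' @examples
#' sc <- synthetic_connectome(12, "dense-random", 0.5, seed = 2)
#' gs <- lsm_stability_threshold(sc)
#' pa <- perturb_analysis(sc, "lsm", lsm_params(G = 0.5 * gs),
#'                        lesion = "exact", seed = 1)
#' summary(pa)
#' @export
perturb_analysis <- function(sc, model = c("lsm", "mfm"), params,
                             cfg = perturbation_config(),
                             lesion = c("approx", "exact"), seed = 1L) {
  model <- match.arg(model)
  lesion <- match.arg(lesion)
  sc <- as_sc(sc)
  steady <- settle_steady_state(model, sc, params, t_settle = cfg$t_settle,
                                dt = cfg$dt, tol = cfg$settle_tol,
                                seed = seed)
  R <- response_matrix(model, sc, params, cfg, steady = steady)
  lesions <- lapply(seq_len(sc$n_nodes), function(i) {
    if (lesion == "approx") lesion_approx(R, i)
    else lesioned_response(model, sc, params, steady, i, cfg)
  })
  fl <- flow_centrality(R, lesions, z_floor = cfg$z_floor)
  structure(list(R = R, influence = net_influence(R), flow = fl,
                 strength = node_strength(sc),
                 steady = as.numeric(steady), model = model, params = params,
                 cfg = cfg, lesion = lesion, seed = seed,
                 node_ids = sc$node_ids),
            class = "perturbation_analysis")
}

#' @export
print.perturbation_analysis <- function(x, ...) {
  cat(sprintf("Perturbation analysis: %s model, %d nodes, alpha = %g, %s lesions\n",
              toupper(x$model), length(x$influence), x$cfg$alpha, x$lesion))
  cat(sprintf("  net influence: [%.3g, %.3g] (sum %.2g)\n",
              min(x$influence), max(x$influence), sum(x$influence)))
  cat(sprintf("  flow:          [%.3g, %.3g]\n", min(x$flow$F), max(x$flow$F)))
  invisible(x)
}

#' @export
summary.perturbation_analysis <- function(object, n_top = 5, ...) {
  df <- as.data.frame(object)
  ord_i <- order(df$net_influence, decreasing = TRUE)
  cat("Top influencers (net influence):\n")
  print(df[utils::head(ord_i, n_top), ], row.names = FALSE, digits = 3)
  cat("Top followers:\n")
  print(df[utils::head(rev(ord_i), n_top), ], row.names = FALSE, digits = 3)
  cat("Highest flow:\n")
  print(df[utils::head(order(df$flow, decreasing = TRUE), n_top), ],
        row.names = FALSE, digits = 3)
  rho_i <- stats::cor(df$strength, df$net_influence, method = "spearman")
  cat(sprintf("Spearman(strength, net influence) = %.3f\n", rho_i))
  invisible(df)
}

#' @export
as.data.frame.perturbation_analysis <- function(x, ...) {
  data.frame(node_id = x$node_ids, strength = unname(x$strength),
             net_influence = unname(x$influence), flow = unname(x$flow$F),
             stringsAsFactors = FALSE)
}

#' @export
plot.perturbation_analysis <- function(x, ...) {
  old <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  s <- unname(x$strength)
  plot(s, unname(x$influence), pch = 16,
       col = adjustcolor("steelblue", 0.8),
       xlab = "node strength", ylab = "net influence",
       main = "Influencers vs followers")
  abline(h = 0, lty = 3)
  plot(s, unname(x$flow$F), pch = 16, col = adjustcolor("firebrick", 0.8),
       xlab = "node strength", ylab = "flow", main = "Flow centrality")
  invisible(x)
}
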