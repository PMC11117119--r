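#' Mean-field model parameters
#'
#' Parameters of the reduced Wong-Wang dynamic mean-field model (MFM). Each
#' node carries one NMDA synaptic gating variable `S_i` with
#' \deqn{\dot S_i = -S_i/\tau_S + (1 - S_i)\,\gamma\, H(x_i), \qquad
#'       x_i = w J S_i + G J \sum_j C_{ij} S_j + I_0,}
#' where `H` is the population firing-rate function (see
#' [mfm_firing_rate()]). Time is in milliseconds throughout.
#'
#' @param w Local excitatory recurrence (dimensionless).
#' @param J Synaptic coupling (nA).
#' @param I0 External input (nA).
#' @param gamma Kinetic rate (1/ms).
#' @param tauS Gating time constant (ms).
#' @param a Firing-rate gain (n/C).
#' @param b Firing-rate threshold (Hz).
#' @param d Firing-rate shape (s).
#' @param sigma Noise amplitude for stochastic runs.
#' @param G Global coupling scaling (dimensionless, >= 0).
#' @param firing_rate `"nonlinear"` (default) or `"linear"`. The linear
#'   variant is the affine chord of `H` between the inputs attained at the
#'   gating-variable bounds `S = 0` and `S = 1` under local drive
#'   (`x = I0` and `x = wJ + I0`); slope and intercept may be overridden.
#' @param lin_slope,lin_icpt Optional explicit affine coefficients for the
#'   linear variant.
#' @return A classed parameter list (`mfm_params`).
#' @export
mfm_params <- function(w = 0.9, J = 0.2609, I0 = 0.3, gamma = 0.641 / 1000,
                       tauS = 100, a = 270, b = 108, d = 0.154,
                       sigma = 0.001, G = 0,
                       firing_rate = c("nonlinear", "linear"),
                       lin_slope = NULL, lin_icpt = NULL) {
  firing_rate <- match.arg(firing_rate)
  stopifnot(tauS > 0, d > 0, a > 0, sigma >= 0, G >= 0)
  p <- list(w = w, J = J, I0 = I0, gamma = gamma, tauS = tauS,
            a = a, b = b, d = d, sigma = sigma, G = G,
            firing_rate = firing_rate)
  if (firing_rate == "linear") {
    if (is.null(lin_slope) || is.null(lin_icpt)) {
      x_lo <- I0
      x_hi <- w * J + I0
      h_lo <- firing_rate_scalar(x_lo, a, b, d)
      h_hi <- firing_rate_scalar(x_hi, a, b, d)
      slope <- (h_hi - h_lo) / (x_hi - x_lo)
      p$lin_slope <- if (is.null(lin_slope)) slope else lin_slope
      p$lin_icpt <- if (is.null(lin_icpt)) h_lo - slope * x_lo else lin_icpt
    } else {
      p$lin_slope <- lin_slope
      p$lin_icpt <- lin_icpt
    }
  }
  structure(p, class = c("mfm_params", "model_params"))
}

#' Linear stochastic model parameters
#'
#' Parameters of the linear stochastic model (LSM),
#' \deqn{\dot x_i = -x_i + G \sum_j C_{ij} x_j + \sigma \eta_i(t),}
#' an Ornstein-Uhlenbeck-like network process. Below the stability threshold
#' `G_stable = 1 / lambda_max(C)` the noiseless system contracts to the zero
#' steady state; above it, it diverges.
#'
#' @param G Global coupling scaling (>= 0).
#' @param sigma Noise amplitude (>= 0).
#' @return A classed parameter list (`lsm_params`).
#' @export
lsm_params <- function(G = 0, sigma = 0) {
  stopifnot(G >= 0, sigma >= 0)
  structure(list(G = G, sigma = sigma),
            class = c("lsm_params", "model_params"))
}

# scalar nonlinear firing rate with series evaluation near the removable
# singularity at a*x == b (limit value 1/d)
firing_rate_scalar <- function(x, a, b, d) {
  u <- a * x - b
  du <- d * u
  ifelse(abs(u) < 1e-6,
         (1 / d) * (1 + du / 2 + du^2 / 12),
         u / (1 - exp(-du)))
}

#' MFM population firing-rate function
#'
#' `H(x) = (a x - b) / (1 - exp(-d (a x - b)))`, the sigmoidal-linear
#' input-output curve of the mean-field reduction. The singularity at
#' `a x = b` is removable with limit `1/d`; it is evaluated by series
#' expansion within `|a x - b| < 1e-6` so `H` is continuous, positive and
#' nondecreasing everywhere. With `firing_rate = "linear"` parameters, the
#' calibrated affine map is returned instead.
#'
#' @param x Input current(s), vectorized.
#' @param params An [mfm_params()] object.
#' @return Firing rate(s) in Hz.
#' @examples
#' p <- mfm_params()
#' mfm_firing_rate(p$b / p$a, p)  # removable singularity: 1/d ~ 6.4935
#' @export
mfm_firing_rate <- function(x, params = mfm_params()) {
  stopifnot(inherits(params, "mfm_params"), all(is.finite(x)))
  if (params$firing_rate == "linear")
    params$lin_slope * x + params$lin_icpt
  else
    firing_rate_scalar(x, params$a, params$b, params$d)
}

#' Drift (deterministic derivative) of the node dynamics
#'
#' The noiseless right-hand side of the model equations, used by the
#' integrator, by the steady-state residual check, and directly in tests.
#'
#' @param state Numeric vector of node activities (`S` for the MFM, `x` for
#'   the LSM), one per connectome node.
#' @param sc A `connectome` (or weight matrix).
#' @param params [mfm_params()] / [lsm_params()].
#' @return Derivative vector (1/ms).
#' @export
mfm_drift <- function(state, sc, params = mfm_params()) {
  sc <- as_sc(sc)
  if (length(state) != sc$n_nodes)
    stop("state length ", length(state), " does not match connectome size ",
         sc$n_nodes)
  x_in <- params$w * params$J * state +
    params$G * params$J * drop(sc$weights %*% state) + params$I0
  -state / params$tauS +
    (1 - state) * params$gamma * mfm_firing_rate(x_in, params)
}

#' @rdname mfm_drift
#' @export
lsm_drift <- function(state, sc, params = lsm_params()) {
  sc <- as_sc(sc)
  if (length(state) != sc$n_nodes)
    stop("state length ", length(state), " does not match connectome size ",
         sc$n_nodes)
  -state + params$G * drop(sc$weights %*% state)
}

model_code <- function(model, params) {
  switch(model,
         lsm = 0L,
         mfm = if (identical(params$firing_rate, "linear")) 2L else 1L,
         stop("unknown model: ", model))
}

drift_fun <- function(model) if (model == "lsm") lsm_drift else mfm_drift

par_vector <- function(model, params) {
  if (model == "lsm") {
    c(G = params$G)
  } else {
    c(G = params$G, w = params$w, J = params$J, I0 = params$I0,
      gamma = params$gamma, tauS = params$tauS, a = params$a, b = params$b,
      d = params$d,
      lin_slope = if (is.null(params$lin_slope)) 0 else params$lin_slope,
      lin_icpt = if (is.null(params$lin_icpt)) 0 else params$lin_icpt)
  }
}

#' Integrate node dynamics with the fixed-step Euler scheme
#'
#' Forward-Euler integration `x <- x + dt * drift(x)` with optional
#' Euler-Maruyama noise increments `sigma * sqrt(dt) * eta` per node and
#' step. After every step, clamped nodes are reset to their held values and
#' frozen nodes to their initial values — this is how perturbation sources
#' ("maintain activity at `(1+alpha) x_n`") and functional lesions ("freeze
#' at the unperturbed steady state") are realized. Identical seeds give
#' identical trajectories.
#'
#' @param model `"lsm"` or `"mfm"`.
#' @param sc A `connectome`.
#' @param params Model parameters ([mfm_params()] / [lsm_params()]).
#' @param init Initial state vector.
#' @param duration Integration time (ms); must be a positive multiple of `dt`.
#' @param dt Time step (ms, default 1).
#' @param noise If `TRUE`, add Euler-Maruyama increments with the parameter
#'   `sigma`; noiseless otherwise.
#' @param seed Optional seed for the noise stream (caller RNG restored).
#' @param clamp Named numeric vector: held values indexed by node (integer
#'   index as name or position via `names = node index`). May also be a list
#'   with elements `idx` and `value`.
#' @param frozen Integer vector of node indices held at their initial values.
#' @param record_every Record the state every this many steps (0 = none).
#' @param on_divergence `"error"` (default) or `"flag"`: what to do when the
#'   state leaves `[-div_limit, div_limit]` or becomes non-finite.
#' @param div_limit Divergence guard (default `1e6`).
#' @return List with `state` (final vector), `trajectory` (matrix,
#'   `record_every > 0`), `times` (ms, recorded rows), `diverged`, and —
#'   if divergence was flagged — `step` and `node`.
#' @export
simulate_dynamics <- function(model = c("lsm", "mfm"), sc, params, init,
                              duration, dt = 1, noise = FALSE, seed = NULL,
                              clamp = NULL, frozen = integer(0),
                              record_every = 0L,
                              on_divergence = c("error", "flag"),
                              div_limit = 1e6) {
  model <- match.arg(model)
  on_divergence <- match.arg(on_divergence)
  sc <- as_sc(sc)
  if (dt <= 0) stop("`dt` must be positive")
  n_steps <- duration / dt
  if (duration <= 0 || abs(n_steps - round(n_steps)) > 1e-8)
    stop("`duration` must be a positive multiple of `dt`")
  n_steps <- as.integer(round(n_steps))
  if (length(init) != sc$n_nodes)
    stop("`init` length does not match connectome size")
  if (any(!is.finite(init))) stop("`init` contains non-finite values")

  if (is.list(clamp)) {
    clamp_idx <- as.integer(clamp$idx)
    clamp_val <- as.numeric(clamp$value)
  } else if (!is.null(clamp)) {
    clamp_idx <- as.integer(names(clamp))
    clamp_val <- as.numeric(clamp)
  } else {
    clamp_idx <- integer(0)
    clamp_val <- numeric(0)
  }
  if (length(clamp_idx) != length(clamp_val))
    stop("clamp indices and values differ in length")
  frozen <- as.integer(frozen)
  if (length(intersect(clamp_idx, frozen)))
    stop("clamped and frozen node sets must be disjoint")
  if (any(c(clamp_idx, frozen) < 1) || any(c(clamp_idx, frozen) > sc$n_nodes))
    stop("clamp/frozen node index out of range")

  sigma <- if (noise) params$sigma else 0
  res <- with_seed(seed,
    cpp_integrate(model_code(model, params), sc$weights,
                  par_vector(model, params), as.numeric(init), dt, n_steps,
                  sigma, clamp_idx - 1L, clamp_val, frozen - 1L,
                  as.integer(record_every), div_limit))

  if (isTRUE(res$diverged) && on_divergence == "error")
    stop(sprintf("dynamics diverged at step %d (t = %g ms), node %d",
                 res$step, res$step * dt, res$node))
  out <- list(state = stats::setNames(as.numeric(res$state), sc$node_ids),
              diverged = isTRUE(res$diverged))
  if (record_every > 0) {
    out$trajectory <- res$trajectory
    colnames(out$trajectory) <- sc$node_ids
    out$times <- dt * record_every * seq_len(nrow(res$trajectory))
  }
  if (out$diverged) {
    out$step <- res$step
    out$node <- res$node
  }
  out
}

#' Relax the dynamics to a steady state
#'
#' Noiseless Euler evolution for `t_settle` ms (default 60 s) from `init`
#' (default: uniform draws in `[0, 1]`), followed by a residual check: the
#' maximum absolute drift at the final state must fall below `tol`
#' (default 1e-8/ms), otherwise a "not settled" error is raised. Settling a
#' state that is already a fixed point returns it unchanged.
#'
#' @inheritParams simulate_dynamics
#' @param t_settle Settling time (ms).
#' @param tol Residual drift tolerance (1/ms).
#' @param frozen Optional node indices held at their initial values (used by
#'   the functional-lesion protocol).
#' @param clamp Optional clamp specification, as in [simulate_dynamics()].
#' @return Named numeric steady-state vector with attribute `max_drift`
#'   (residual over non-held nodes).
#' @export
settle_steady_state <- function(model = c("lsm", "mfm"), sc, params,
                                init = NULL, t_settle = 60000, dt = 1,
                                tol = 1e-8, seed = NULL,
                                clamp = NULL, frozen = integer(0)) {
  model <- match.arg(model)
  sc <- as_sc(sc)
  if (is.null(init))
    init <- with_seed(seed, runif(sc$n_nodes))
  res <- simulate_dynamics(model, sc, params, init, duration = t_settle,
                           dt = dt, noise = FALSE, clamp = clamp,
                           frozen = frozen)
  state <- res$state
  held <- c(if (is.list(clamp)) as.integer(clamp$idx)
            else if (!is.null(clamp)) as.integer(names(clamp)),
            as.integer(frozen))
  resid <- abs(drift_fun(model)(state, sc, params))
  if (length(held)) resid[held] <- 0
  max_drift <- max(resid)
  if (max_drift >= tol)
    stop(sprintf(paste0("system not settled after %g ms: max |drift| = %.3g",
                        " (tolerance %.3g)"), t_settle, max_drift, tol))
  attr(state, "max_drift") <- max_drift
  state
}

#' Map the bistability structure of the MFM across coupling values
#'
#' The mean-field model supports a stable low-activity ("spontaneous") state
#' at weak coupling; increasing `G` first adds a coexisting high-activity
#' state (bistable regime) and eventually destabilizes the spontaneous state
#' (high-only regime). For each `G` in `G_grid`, this runs `trials` noiseless
#' evolutions of `t_evolve` ms from low initial conditions (`S(0)` uniform in
#' `[0, 0.1]`) and `trials` from high ones (uniform in `[0.3, 1]`), classifies
#' every final state as "high" when `mean(S) > state_threshold`, and labels
#' the regime by which basins were reached.
#'
#' @inheritParams simulate_dynamics
#' @param G_grid Increasing vector of coupling values.
#' @param trials Noiseless evolutions per initial-condition range.
#' @param t_evolve Evolution time per trial (ms, default 40 s).
#' @param state_threshold Mean-activity boundary separating the low and high
#'   basins (default 0.2, between the two initialization ranges).
#' @return A data frame (class `bistability_scan`) with columns `G`,
#'   `regime` (`low-only`, `bistable`, `high-only`), `p_high_from_low`,
#'   `p_high_from_high`.
#' @export
mfm_bistability_scan <- function(sc, params = mfm_params(), G_grid,
                                 trials = 10, t_evolve = 40000, dt = 1,
                                 seed = 1L, state_threshold = 0.2) {
  sc <- as_sc(sc)
  stopifnot(trials >= 1, !is.unsorted(G_grid))
  n <- sc$n_nodes
  res <- with_seed(seed, {
    lapply(G_grid, function(G) {
      p <- params
      p$G <- G
      ends_high <- function(init) {
        out <- simulate_dynamics("mfm", sc, p, init, duration = t_evolve,
                                 dt = dt, noise = FALSE)
        mean(out$state) > state_threshold
      }
      low <- vapply(seq_len(trials),
                    function(k) ends_high(runif(n, 0, 0.1)), logical(1))
      high <- vapply(seq_len(trials),
                     function(k) ends_high(runif(n, 0.3, 1)), logical(1))
      c(p_low = mean(low), p_high = mean(high))
    })
  })
  p_low <- vapply(res, `[[`, numeric(1), "p_low")
  p_high <- vapply(res, `[[`, numeric(1), "p_high")
  reached_high <- p_low > 0 | p_high > 0
  reached_low <- p_low < 1 | p_high < 1
  regime <- ifelse(reached_high & reached_low, "bistable",
                   ifelse(reached_high, "high-only", "low-only"))
  structure(data.frame(G = G_grid, regime = regime,
                       p_high_from_low = p_low, p_high_from_high = p_high),
            class = c("bistability_scan", "data.frame"))
}

#' Find the LSM stability threshold by simulation
#'
#' Scans the coupling upward in steps of `G_step`; at each grid value it runs
#' `trials` noiseless evolutions from uniform `[0, 1]` initial conditions and
#' records whether any trajectory diverges. The threshold is the smallest
#' diverging grid value minus one step. Analytically this equals
#' `1 / lambda_max(C)` (to within the grid step), which tests use as an
#' independent oracle; the scan itself never touches the spectrum.
#'
#' @inheritParams simulate_dynamics
#' @param G_step Grid resolution of the scan.
#' @param trials Trials per grid value.
#' @param t_test Evolution time used to detect divergence (ms). Divergence
#'   just above threshold grows like `exp(lambda_max * G_step * t)`, so the
#'   default 5 s resolves thresholds for `lambda_max * G_step >= ~3e-3`.
#' @param G_max Scan ceiling (error if no divergence below it).
#' @return The threshold estimate `G_stable` (>= 0).
#' @export
lsm_stability_threshold <- function(sc, G_step = 0.01, trials = 20,
                                    t_test = 5000, dt = 1, seed = 1L,
                                    G_max = 100) {
  sc <- as_sc(sc)
  stopifnot(G_step > 0, trials >= 1)
  n <- sc$n_nodes
  found <- with_seed(seed, {
    G <- G_step
    res <- NA_real_
    while (G <= G_max) {
      diverged <- FALSE
      for (k in seq_len(trials)) {
        out <- simulate_dynamics("lsm", sc, lsm_params(G = G),
                                 runif(n), duration = t_test, dt = dt,
                                 noise = FALSE, on_divergence = "flag")
        if (out$diverged) {
          diverged <- TRUE
          break
        }
      }
      if (diverged) {
        res <- G - G_step
        break
      }
      G <- G + G_step
    }
    res
  })
  if (is.na(found))
    stop("no divergence found up to G_max = ", G_max,
         "; increase `G_max` or `G_step`")
  found
}
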