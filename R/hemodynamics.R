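#' Balloon-Windkessel hemodynamic parameters
#'
#' Canonical constants of the hemodynamic forward model that converts neural
#' activity into a BOLD signal: vasodilatory signal decay `kappa` (1/s),
#' flow-dependent elimination `gamma_f` (1/s), venous transit time `tau` (s),
#' Grubb vessel-stiffness exponent `alpha_bw`, resting oxygen extraction
#' fraction `rho`, resting venous volume fraction `V0`, and the BOLD
#' coefficients `k1 = 7 rho`, `k2 = 2`, `k3 = 2 rho - 0.2`.
#'
#' @param kappa,gamma_f,tau,alpha_bw,rho,V0,k1,k2,k3 See description.
#' @return A classed parameter list (`bw_params`).
#' @export
bw_params <- function(kappa = 0.65, gamma_f = 0.41, tau = 0.98,
                      alpha_bw = 0.32, rho = 0.34, V0 = 0.02,
                      k1 = 7 * rho, k2 = 2, k3 = 2 * rho - 0.2) {
  stopifnot(kappa > 0, gamma_f > 0, tau > 0, alpha_bw > 0, rho > 0, rho < 1,
            V0 > 0)
  structure(list(kappa = kappa, gamma_f = gamma_f, tau = tau,
                 alpha_bw = alpha_bw, rho = rho, V0 = V0,
                 k1 = k1, k2 = k2, k3 = k3),
            class = "bw_params")
}

#' Balloon-Windkessel BOLD forward model
#'
#' Integrates, per node, the four-state hemodynamic system (vasodilatory
#' signal `s`, inflow `f`, venous volume `v`, deoxyhemoglobin content `q`)
#' driven by the neural series `z`:
#' \deqn{\dot s = z - \kappa s - \gamma_f (f - 1),\quad \dot f = s,\quad
#'       \tau \dot v = f - v^{1/\alpha},\quad
#'       \tau \dot q = \frac{f}{\rho}\left(1 - (1-\rho)^{1/f}\right)
#'                     - v^{1/\alpha} q / v,}
#' and returns the BOLD signal
#' `V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))`. Integration shares the
#' neural time step; rest (`z = 0`) is a fixed point with zero BOLD output.
#'
#' @param neural `T x N` matrix of neural activity sampled at `dt`.
#' @param dt Neural sampling step in milliseconds (default 1).
#' @param params A [bw_params()] object.
#' @return `T x N` matrix of BOLD samples (pre-downsampling).
#' @export
balloon_windkessel <- function(neural, dt = 1, params = bw_params()) {
  neural <- as.matrix(neural)
  if (any(!is.finite(neural))) stop("`neural` contains non-finite values")
  stopifnot(inherits(params, "bw_params"), dt > 0)
  cpp_balloon_windkessel(neural, dt / 1000, params$kappa, params$gamma_f,
                         params$tau, params$alpha_bw, params$rho, params$V0,
                         params$k1, params$k2, params$k3)
}

#' Simulate a resting-state functional connectivity matrix
#'
#' Full forward pipeline at one coupling value: stochastic Euler-Maruyama
#' simulation of the node dynamics, Balloon-Windkessel BOLD generation at the
#' neural resolution, removal of the initial transient, downsampling to the
#' repetition time `TR` (every `TR/dt`-th sample, no anti-alias filter),
#' per-node z-scoring, and pairwise Pearson correlation.
#'
#' @inheritParams simulate_dynamics
#' @param duration_s Total simulated time (s, default 96).
#' @param transient_s Initial BOLD span discarded as transient (s, default 12).
#' @param tr_s Repetition time of the downsampled BOLD (s, default 0.6);
#'   must be a multiple of `dt`.
#' @param hemo A [bw_params()] object.
#' @param init Optional initial state (default: uniform `[0, 1]` draws).
#' @return `N x N` Pearson correlation matrix (unit diagonal, symmetric).
#' @export
simulate_bold_fc <- function(model = c("lsm", "mfm"), sc, params,
                             duration_s = 96, transient_s = 12, tr_s = 0.6,
                             dt = 1, seed = NULL, hemo = bw_params(),
                             init = NULL) {
  model <- match.arg(model)
  sc <- as_sc(sc)
  if (duration_s <= transient_s)
    stop("`duration_s` must exceed `transient_s`")
  tr_steps <- tr_s * 1000 / dt
  if (abs(tr_steps - round(tr_steps)) > 1e-8)
    stop("`tr_s` must be a multiple of `dt`")
  tr_steps <- as.integer(round(tr_steps))
  n_keep <- floor((duration_s - transient_s) / tr_s)
  if (n_keep < 2)
    stop("fewer than 2 BOLD samples would remain; increase `duration_s`")

  with_seed(seed, {
    if (is.null(init)) init <- runif(sc$n_nodes)
    run <- simulate_dynamics(model, sc, params, init,
                             duration = duration_s * 1000, dt = dt,
                             noise = TRUE, record_every = 1L)
    bold <- balloon_windkessel(run$trajectory, dt = dt, params = hemo)
    drop_rows <- as.integer(round(transient_s * 1000 / dt))
    bold <- bold[-seq_len(drop_rows), , drop = FALSE]
    bold <- bold[seq_len(nrow(bold)) %% tr_steps == 0, , drop = FALSE]
    sds <- apply(bold, 2, stats::sd)
    if (any(sds == 0))
      stop("constant BOLD series for node(s) ",
           paste(which(sds == 0), collapse = ", "),
           "; correlation undefined")
    z <- scale(bold)
    fc <- stats::cor(z)
    dimnames(fc) <- list(sc$node_ids, sc$node_ids)
    fc
  })
}

#' Fisher-z average of functional connectivity matrices
#'
#' Averages subject-level FC matrices on the Fisher z scale: `atanh` each
#' off-diagonal entry (after clipping `|r|` to `1 - 1e-15`), take the
#' elementwise mean, transform back with `tanh`, set negative averaged
#' correlations to zero, and restore the unit diagonal.
#'
#' @param fc_list Non-empty list of same-sized square correlation matrices.
#' @return The averaged, positively-thresholded FC matrix.
#' @export
fisher_z_average_fc <- function(fc_list) {
  if (!is.list(fc_list) || length(fc_list) == 0)
    stop("`fc_list` must be a non-empty list")
  fc_list <- lapply(fc_list, as.matrix)
  n <- nrow(fc_list[[1]])
  for (k in seq_along(fc_list)) {
    m <- fc_list[[k]]
    if (nrow(m) != n || ncol(m) != n)
      stop("matrix ", k, " has different dimensions")
  }
  zs <- lapply(fc_list, function(m) {
    m <- pmin(pmax(m, -1 + 1e-15), 1 - 1e-15)
    atanh(m)
  })
  avg <- tanh(Reduce(`+`, zs) / length(zs))
  avg[avg < 0] <- 0
  diag(avg) <- 1
  dimnames(avg) <- dimnames(fc_list[[1]])
  avg
}

#' Functional connectivity distance
#'
#' Squared-deviation objective between an empirical and a simulated FC
#' matrix,
#' \deqn{FCD = \frac{1}{N} \sum_{i=1}^N \sum_{j=1}^N
#'       (FC^{emp}_{ij} - FC^{sim}_{ij})^2,}
#' summed over the full matrix (the diagonal contributes zero for proper
#' correlation matrices). Nonnegative, zero iff the matrices are equal, and
#' symmetric in its arguments.
#'
#' @param fc_emp,fc_sim Same-sized square FC matrices.
#' @return A single nonnegative number.
#' @export
fc_distance <- function(fc_emp, fc_sim) {
  fc_emp <- as.matrix(fc_emp)
  fc_sim <- as.matrix(fc_sim)
  if (!all(dim(fc_emp) == dim(fc_sim)))
    stop("FC matrices differ in size: ", nrow(fc_emp), " vs ", nrow(fc_sim))
  sum((fc_emp - fc_sim)^2) / nrow(fc_emp)
}

#' Sweep the global coupling against an empirical FC
#'
#' For every coupling value in `G_grid` and every trial, simulates a
#' resting-state FC ([simulate_bold_fc()]) and scores it against `fc_emp`
#' with [fc_distance()]. The operating point `G_star` is the grid value
#' minimizing the trial-mean distance (ties broken toward smaller `G`).
#'
#' For the LSM the noise amplitude follows the rule
#' `sigma = G_stable - G`, so the stability threshold is computed first
#' (or supplied via `G_stable`); grid points at which all trials diverge are
#' recorded as missing, excluded from the argmin, and reported with a
#' warning. For the MFM the `sigma` of `params` is used unchanged.
#'
#' @inheritParams simulate_bold_fc
#' @param fc_emp Reference (empirical) FC matrix.
#' @param G_grid Coupling values to scan.
#' @param trials Simulated FCs per grid value (default 30).
#' @param seed Integer seed; trials draw from a deterministic per-call
#'   stream, so the same call reproduces the same distance table.
#' @param params Base model parameters; `G` (and for the LSM `sigma`) are
#'   overridden per grid point.
#' @param G_stable Precomputed LSM stability threshold (computed via
#'   [lsm_stability_threshold()] when omitted).
#' @return An object of class `g_sweep`: list with `G_grid`, `fcd`
#'   (`length(G_grid) x trials` matrix, `NA` for diverged runs), `mean_fcd`,
#'   `G_star`, `model`, `G_stable`.
#' @export
sweep_coupling <- function(model = c("lsm", "mfm"), sc, fc_emp, G_grid,
                           trials = 30, seed = 1L, params = NULL,
                           duration_s = 96, transient_s = 12, tr_s = 0.6,
                           dt = 1, hemo = bw_params(), G_stable = NULL) {
  model <- match.arg(model)
  sc <- as_sc(sc)
  if (length(G_grid) == 0) stop("`G_grid` is empty")
  ord <- order(G_grid)
  G_grid <- G_grid[ord]
  if (is.null(params))
    params <- if (model == "lsm") lsm_params() else mfm_params()
  if (model == "lsm" && is.null(G_stable))
    G_stable <- lsm_stability_threshold(sc, seed = seed)

  fcd <- matrix(NA_real_, length(G_grid), trials,
                dimnames = list(sprintf("G=%g", G_grid), NULL))
  with_seed(seed, {
    for (gi in seq_along(G_grid)) {
      p <- params
      p$G <- G_grid[gi]
      if (model == "lsm") p$sigma <- G_stable - G_grid[gi]
      for (tr in seq_len(trials)) {
        fc_sim <- tryCatch(
          simulate_bold_fc(model, sc, p, duration_s = duration_s,
                           transient_s = transient_s, tr_s = tr_s, dt = dt,
                           hemo = hemo),
          error = function(e) NULL)
        if (!is.null(fc_sim)) fcd[gi, tr] <- fc_distance(fc_emp, fc_sim)
      }
    }
  })
  all_missing <- rowSums(!is.na(fcd)) == 0
  if (any(all_missing))
    warning("all trials diverged at G = ",
            paste(G_grid[all_missing], collapse = ", "),
            "; excluded from the argmin")
  mean_fcd <- rowMeans(fcd, na.rm = TRUE)
  mean_fcd[all_missing] <- NA_real_
  G_star <- G_grid[which.min(mean_fcd)]  # grid sorted: ties -> smallest G
  structure(list(G_grid = G_grid, fcd = fcd, mean_fcd = unname(mean_fcd),
                 G_star = G_star, model = model, G_stable = G_stable,
                 trials = trials),
            class = "g_sweep")
}

#' @export
print.g_sweep <- function(x, ...) {
  cat(sprintf("Coupling sweep (%s model): %d grid points x %d trials\n",
              toupper(x$model), length(x$G_grid), x$trials))
  if (!is.null(x$G_stable))
    cat(sprintf("  G_stable = %g (noise rule sigma = G_stable - G)\n",
                x$G_stable))
  cat(sprintf("  best fit G* = %g (mean FCD = %.4g)\n", x$G_star,
              min(x$mean_fcd, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.g_sweep <- function(x, ...) {
  plot(x$G_grid, x$mean_fcd, type = "b", pch = 16,
       xlab = "global coupling G", ylab = "mean FC distance",
       main = "Coupling sweep", ...)
  abline(v = x$G_star, lty = 2)
  mtext(sprintf("G* = %g", x$G_star), side = 3, line = 0, adj = 1, cex = 0.8)
  invisible(x)
}
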