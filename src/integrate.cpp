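// Fixed-step Euler / Euler-Maruyama integrator for network node dynamics
// with per-step clamp and freeze resets, plus the Balloon-Windkessel
// hemodynamic filter. The fixed-step scheme with post-step state resets is
// part of the simulation protocol itself (dt = 1 ms by default), which is
// why a generic adaptive ODE solver is not used here.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Wong-Wang population firing rate H(x) = (a x - b) / (1 - exp(-d (a x - b))).
// The singularity at a x = b is removable; near it we use the series
// 1/d * (1 + d u / 2 + (d u)^2 / 12), u = a x - b, which is accurate to
// ~1e-19 inside |u| < 1e-6 and keeps H continuous and monotone.
static inline double firing_rate_nl(double x, double a, double b, double d) {
  const double u = a * x - b;
  const double du = d * u;
  if (std::fabs(u) < 1e-6) {
    return (1.0 / d) * (1.0 + 0.5 * du + du * du / 12.0);
  }
  return u / (1.0 - std::exp(-du));
}

// model codes: 0 = linear stochastic model, 1 = mean-field model
// (nonlinear rate), 2 = mean-field model with affine firing rate.
// [[Rcpp::export]]
List cpp_integrate(const int model,
                   const arma::mat& C,
                   const NumericVector par,
                   const arma::vec& x0,
                   const double dt,
                   const int n_steps,
                   const double sigma,
                   const IntegerVector clamp_idx,   // 0-based
                   const NumericVector clamp_val,
                   const IntegerVector frozen_idx,  // 0-based
                   const int record_every,
                   const double div_limit) {
  const arma::uword N = C.n_rows;
  arma::vec x = x0;

  // parameters (unused slots are ignored per model)
  const double G = par["G"];
  double w = 0, J = 0, I0 = 0, gamma = 0, tauS = 0, a = 0, b = 0, d = 0;
  double lin_slope = 0, lin_icpt = 0;
  if (model >= 1) {
    w = par["w"]; J = par["J"]; I0 = par["I0"];
    gamma = par["gamma"]; tauS = par["tauS"];
    a = par["a"]; b = par["b"]; d = par["d"];
  }
  if (model == 2) {
    lin_slope = par["lin_slope"];
    lin_icpt = par["lin_icpt"];
  }

  // coupling matrix folded with model-specific prefactor
  arma::mat K;
  if (model == 0) K = G * C;        // LSM: x' = -x + G C x
  else            K = G * J * C;    // MFM input: w J S + G J C S + I0

  arma::vec frozen_val(frozen_idx.size());
  for (int k = 0; k < frozen_idx.size(); ++k)
    frozen_val[k] = x0[frozen_idx[k]];

  auto apply_holds = [&](arma::vec& v) {
    for (int k = 0; k < clamp_idx.size(); ++k) v[clamp_idx[k]] = clamp_val[k];
    for (int k = 0; k < frozen_idx.size(); ++k) v[frozen_idx[k]] = frozen_val[k];
  };
  apply_holds(x);

  const int n_rec = (record_every > 0) ? n_steps / record_every : 0;
  arma::mat traj(n_rec, N);
  int rec = 0;

  const double noise_scale = sigma * std::sqrt(dt);
  arma::vec drift(N);

  for (int step = 1; step <= n_steps; ++step) {
    const arma::vec coup = K * x;
    if (model == 0) {
      drift = -x + coup;
    } else {
      for (arma::uword i = 0; i < N; ++i) {
        const double xin = w * J * x[i] + coup[i] + I0;
        const double H = (model == 1)
          ? firing_rate_nl(xin, a, b, d)
          : lin_slope * xin + lin_icpt;
        drift[i] = -x[i] / tauS + (1.0 - x[i]) * gamma * H;
      }
    }
    x += dt * drift;
    if (noise_scale > 0.0) {
      for (arma::uword i = 0; i < N; ++i) x[i] += noise_scale * norm_rand();
    }
    apply_holds(x);

    if (!x.is_finite() || arma::abs(x).max() > div_limit) {
      arma::uword bad = 0;
      for (arma::uword i = 0; i < N; ++i) {
        if (!std::isfinite(x[i]) || std::fabs(x[i]) > div_limit) { bad = i; break; }
      }
      arma::mat traj_part = (rec > 0) ? arma::mat(traj.rows(0, rec - 1))
                                      : arma::mat(0, N);
      return List::create(_["state"] = NumericVector(x.begin(), x.end()),
                          _["trajectory"] = traj_part,
                          _["diverged"] = true,
                          _["step"] = step,
                          _["node"] = (int)(bad + 1));
    }
    if (record_every > 0 && step % record_every == 0) {
      traj.row(rec++) = x.t();
    }
  }

  return List::create(_["state"] = NumericVector(x.begin(), x.end()),
                      _["trajectory"] = traj,
                      _["diverged"] = false,
                      _["step"] = n_steps,
                      _["node"] = NA_INTEGER);
}

// Balloon-Windkessel hemodynamic filter. Four states per node (vasodilatory
// signal s, inflow f, venous volume v, deoxyhemoglobin q) driven by the
// neural series z, integrated with the same fixed-step Euler scheme at the
// neural resolution. Rest is the fixed point (s, f, v, q) = (0, 1, 1, 1).
// [[Rcpp::export]]
NumericMatrix cpp_balloon_windkessel(const NumericMatrix z,
                                     const double dt_s,
                                     const double kappa,
                                     const double gamma_f,
                                     const double tau,
                                     const double alpha_bw,
                                     const double rho,
                                     const double V0,
                                     const double k1,
                                     const double k2,
                                     const double k3) {
  const int T = z.nrow(), N = z.ncol();
  NumericMatrix bold(T, N);
  const double ia = 1.0 / alpha_bw;
  const double floor_state = 1e-9;  // f, v, q must stay positive (pow/div)

  for (int j = 0; j < N; ++j) {
    double s = 0.0, f = 1.0, v = 1.0, q = 1.0;
    for (int t = 0; t < T; ++t) {
      const double ds = z(t, j) - kappa * s - gamma_f * (f - 1.0);
      const double df = s;
      const double fv = std::pow(v, ia);
      const double E = 1.0 - std::pow(1.0 - rho, 1.0 / f);  // O2 extraction
      const double dv = (f - fv) / tau;
      const double dq = ((f / rho) * E - fv * q / v) / tau;
      s += dt_s * ds;
      f += dt_s * df;
      v += dt_s * dv;
      q += dt_s * dq;
      if (f < floor_state) f = floor_state;
      if (v < floor_state) v = floor_state;
      if (q < floor_state) q = floor_state;
      bold(t, j) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
      if (!std::isfinite(bold(t, j)))
        stop("hemodynamic model diverged at sample %d, node %d", t + 1, j + 1);
    }
  }
  return bold;
}
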