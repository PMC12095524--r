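// Delay-ODE model of ERK-driven gene expression.
//
// State y = (TFP, M, P, PP):
//   dTFP/dt = k_ptf * E(t) * (TF_T - TFP) - k_dtf * TFP
//   dM/dt   = (k_b + k_m * TFP(t - tau_m)) /
//               (((P(t - tau_m) + PP(t - tau_m)) / K_D)^v + 1) - k_dm * M
//   dP/dt   = k_p * M(t - tau_p) + k_deph * PP - (k_dp + k_pp * E(t)) * P
//   dPP/dt  = k_pp * E(t) * P - (k_dpp + k_deph) * PP
//
// The phosphorylation flux k_pp * E * P leaves P and enters PP (mass
// conserving).  Integration is fixed-step RK4; delayed states are read from
// the stored solution grid with linear interpolation.  Pre-history equals
// the initial condition.  ERK input is supplied pre-interpolated on the
// half-step grid so stage evaluations are O(1) lookups.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Pars {
  double k_ptf, k_dtf, tf_total, k_b, k_m, tau_m, k_dm, K_D, v,
         k_p, tau_p, k_dp, k_pp, k_deph, k_dpp;
};

Pars unpack(const arma::rowvec& p) {
  Pars q;
  q.k_ptf = p(0);  q.k_dtf = p(1); q.tf_total = p(2);
  q.k_b = p(3);    q.k_m = p(4);   q.tau_m = p(5);
  q.k_dm = p(6);   q.K_D = p(7);   q.v = p(8);
  q.k_p = p(9);    q.tau_p = p(10); q.k_dp = p(11);
  q.k_pp = p(12);  q.k_deph = p(13); q.k_dpp = p(14);
  return q;
}

inline double feedback(double ptot, const Pars& q) {
  if (!std::isfinite(q.K_D)) return 1.0;
  return 1.0 / (std::pow(ptot / q.K_D, q.v) + 1.0);
}

// Linear interpolation into the filled solution grid (columns = states at
// t0 + i*dt, filled through index `filled`).  Times before t0 return y0.
inline void hist_at(const arma::mat& grid, int filled, double t0, double dt,
                    double tq, double* out) {
  double u = (tq - t0) / dt;
  if (u <= 0.0) {
    for (int s = 0; s < 4; ++s) out[s] = grid(s, 0);
    return;
  }
  if (u >= filled) {
    for (int s = 0; s < 4; ++s) out[s] = grid(s, filled);
    return;
  }
  int i = static_cast<int>(std::floor(u));
  double w = u - i;
  for (int s = 0; s < 4; ++s)
    out[s] = (1.0 - w) * grid(s, i) + w * grid(s, i + 1);
}

inline void deriv(const double* y, double erk, const double* lag_m,
                  const double* lag_p, const Pars& q, double* dy) {
  double fb = feedback(lag_m[2] + lag_m[3], q);
  double flux = q.k_pp * erk * y[2];
  dy[0] = q.k_ptf * erk * (q.tf_total - y[0]) - q.k_dtf * y[0];
  dy[1] = (q.k_b + q.k_m * lag_m[0]) * fb - q.k_dm * y[1];
  dy[2] = q.k_p * lag_p[1] + q.k_deph * y[3] - q.k_dp * y[2] - flux;
  dy[3] = flux - (q.k_dpp + q.k_deph) * y[3];
}

// One full trajectory; returns 4 x (n_steps + 1) grid.  erk_half holds the
// input on the half-step grid: erk_half[j] = E(t0 + j * dt / 2),
// j = 0..2*n_steps.
arma::mat integrate_one(const arma::rowvec& pvec, const arma::vec& erk_half,
                        const arma::vec& y0, double t0, double dt,
                        int n_steps) {
  Pars q = unpack(pvec);
  arma::mat grid(4, n_steps + 1);
  grid.col(0) = y0;

  double y[4], k1[4], k2[4], k3[4], k4[4], ytmp[4];
  double lag_m[4], lag_p[4];

  for (int i = 0; i < n_steps; ++i) {
    double t = t0 + i * dt;
    for (int s = 0; s < 4; ++s) y[s] = grid(s, i);

    // stage 1 (t)
    hist_at(grid, i, t0, dt, t - q.tau_m, lag_m);
    hist_at(grid, i, t0, dt, t - q.tau_p, lag_p);
    deriv(y, erk_half(2 * i), lag_m, lag_p, q, k1);

    // stage 2, 3 (t + dt/2)
    hist_at(grid, i, t0, dt, t + 0.5 * dt - q.tau_m, lag_m);
    hist_at(grid, i, t0, dt, t + 0.5 * dt - q.tau_p, lag_p);
    for (int s = 0; s < 4; ++s) ytmp[s] = y[s] + 0.5 * dt * k1[s];
    deriv(ytmp, erk_half(2 * i + 1), lag_m, lag_p, q, k2);
    for (int s = 0; s < 4; ++s) ytmp[s] = y[s] + 0.5 * dt * k2[s];
    deriv(ytmp, erk_half(2 * i + 1), lag_m, lag_p, q, k3);

    // stage 4 (t + dt)
    hist_at(grid, i, t0, dt, t + dt - q.tau_m, lag_m);
    hist_at(grid, i, t0, dt, t + dt - q.tau_p, lag_p);
    for (int s = 0; s < 4; ++s) ytmp[s] = y[s] + dt * k3[s];
    deriv(ytmp, erk_half(2 * i + 2), lag_m, lag_p, q, k4);

    for (int s = 0; s < 4; ++s) {
      double yn = y[s] + dt / 6.0 * (k1[s] + 2.0 * k2[s] + 2.0 * k3[s] + k4[s]);
      grid(s, i + 1) = (yn > 0.0) ? yn : 0.0;
    }
  }
  return grid;
}

// Steady state under constant ERK.  With feedback the fixed point in total
// protein is found by bisection (the implied total is decreasing in the
// assumed total, so the root is unique and bracketed by [0, implied(0)]).
// Returns NaN states if no finite steady state exists.
arma::vec steady_one(const arma::rowvec& pvec, double erk) {
  Pars q = unpack(pvec);
  arma::vec y(4, arma::fill::value(arma::datum::nan));

  double denom_tf = q.k_ptf * erk + q.k_dtf;
  double tfp = (denom_tf > 0.0) ? q.k_ptf * erk * q.tf_total / denom_tf : 0.0;

  if (q.k_dm <= 0.0) {
    if (q.k_b + q.k_m * tfp > 0.0) return y;  // unbounded mRNA
    y = {tfp, 0.0, 0.0, 0.0};
    return y;
  }

  double denom_pp = q.k_dpp + q.k_deph;
  double c_pp;  // PP = c_pp * P at equilibrium
  if (denom_pp > 0.0) {
    c_pp = q.k_pp * erk / denom_pp;
  } else if (q.k_pp * erk == 0.0) {
    c_pp = 0.0;
  } else {
    return y;  // phospho-protein accumulates without bound
  }
  double ceff = q.k_dp + q.k_pp * erk - q.k_deph * c_pp;

  auto implied_ptot = [&](double ptot) {
    double m = (q.k_b + q.k_m * tfp) * feedback(ptot, q) / q.k_dm;
    if (q.k_p * m == 0.0) return 0.0;
    if (ceff <= 0.0) return arma::datum::inf;
    return q.k_p * m / ceff * (1.0 + c_pp);
  };

  double hi = implied_ptot(0.0);
  if (!std::isfinite(hi)) return y;  // no clearance of protein

  double ptot;
  if (!std::isfinite(q.K_D)) {
    ptot = hi;  // no feedback: closed form
  } else {
    double lo = 0.0;
    for (int it = 0; it < 200; ++it) {
      double mid = 0.5 * (lo + hi);
      if (implied_ptot(mid) > mid) lo = mid; else hi = mid;
      if (hi - lo < 1e-14 * (1.0 + hi)) break;
    }
    ptot = 0.5 * (lo + hi);
  }

  double m = (q.k_b + q.k_m * tfp) * feedback(ptot, q) / q.k_dm;
  double p = ptot / (1.0 + c_pp);
  y = {tfp, m, p, c_pp * p};
  return y;
}

}  // namespace

// [[Rcpp::export]]
arma::vec simetg_steady_cpp(const arma::rowvec& params, double erk) {
  return steady_one(params, erk);
}

// [[Rcpp::export]]
arma::mat simetg_integrate_cpp(const arma::rowvec& params,
                               const arma::vec& erk_half, const arma::vec& y0,
                               double t0, double dt, int n_steps) {
  return integrate_one(params, erk_half, y0, t0, dt, n_steps).t();
}

// Endpoint survey: one row per gene, one column per cell.  erk_half_mat has
// one column per cell (half-step grid).  readout: 0 = P + PP, 1 = PP.
// init_erk gives the constant pre-stimulus ERK level per cell used for the
// steady-state initial condition.
// [[Rcpp::export]]
arma::mat simetg_survey_cpp(const arma::mat& params, const arma::mat& erk_half_mat,
                            const arma::vec& init_erk, double t0, double dt,
                            int n_steps, int readout) {
  int n_genes = params.n_rows, n_cells = erk_half_mat.n_cols;
  arma::mat out(n_genes, n_cells);
  for (int g = 0; g < n_genes; ++g) {
    for (int c = 0; c < n_cells; ++c) {
      arma::vec y0 = steady_one(params.row(g), init_erk(c));
      arma::mat grid = integrate_one(params.row(g), erk_half_mat.col(c), y0,
                                     t0, dt, n_steps);
      out(g, c) = (readout == 1) ? grid(3, n_steps)
                                 : grid(2, n_steps) + grid(3, n_steps);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
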