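#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Feed-forward part of the membrane potential on the simulation grid:
// P[k] = sum_j w[j] * eps(k*dt - arrival[j]) with the alpha-shaped PSP
// eps(s) = (s/tau) * exp(1 - s/tau) for s > 0.
//
// Each arrival contributes only on (arrival, arrival + cutoff]; within that
// window exp(1 - s/tau) is advanced recursively (one exp per event, one
// multiply per grid step), which keeps N_I = 500 simulations cheap.
// [[Rcpp::export]]
NumericVector psp_grid_cpp(NumericVector arrival, NumericVector w,
                           int n_grid, double dt, double tau_psp,
                           double cutoff) {
  NumericVector P(n_grid);
  const double m = std::exp(-dt / tau_psp);
  const int n = arrival.size();
  for (int j = 0; j < n; ++j) {
    const double a = arrival[j];
    const double wj = w[j];
    if (wj == 0.0) continue;
    // first grid index with k*dt strictly greater than the arrival time
    int k0 = (int)std::floor(a / dt) + 1;
    while (k0 > 0 && (k0 - 1) * dt > a) --k0;  // fp guard
    while (k0 * dt <= a) ++k0;
    int k1 = (int)std::ceil((a + cutoff) / dt);
    if (k1 > n_grid - 1) k1 = n_grid - 1;
    if (k0 < 0) k0 = 0;
    double s = k0 * dt - a;
    double e = std::exp(1.0 - s / tau_psp);
    for (int k = k0; k <= k1; ++k) {
      P[k] += wj * (s / tau_psp) * e;
      s += dt;
      e *= m;
    }
  }
  return P;
}

// Threshold walk over the grid. P holds the feed-forward potential; the
// refractoriness of the most recent output spike is added on the fly.
// A spike is registered when u >= theta (to within a small absolute
// tolerance, so exact-tie peaks are robust to round-off) and the hard
// absolute refractory window has elapsed.
// [[Rcpp::export]]
NumericVector srm_fire_cpp(NumericVector P, double dt, double theta,
                           double tau_ref, double t_abs) {
  const int n_grid = P.size();
  const double tol = 1e-9;
  std::vector<double> out;
  double last = R_NegInf;
  for (int k = 0; k < n_grid; ++k) {
    const double t = k * dt;
    double u = P[k];
    if (!std::isfinite(u))
      stop("non-finite membrane potential at t = %g ms (grid step %d)", t,
           k + 1);
    if (std::isfinite(last)) {
      const double s = t - last;
      if (s > 0) u -= theta * std::exp(-s / tau_ref);
    }
    if (u >= theta - tol && (t - last) > t_abs) {
      out.push_back(t);
      last = t;
    }
  }
  return wrap(out);
}

// Per-synapse double-sum brackets shared by the weight and delay rules:
//   B[i] = sum_g sum_f K(t_d^g - t_i^f - d_i) - sum_h sum_f K(t_o^h - t_i^f - d_i)
// where K depends on `mode`:
//   0: kernel itself, Laplacian exp(-|x|/tau)
//   1: kernel itself, Gaussian exp(-x^2 / (2 tau^2))
//   2: Laplacian delay derivative as printed in the rule, exp(-|x|/tau)/tau
//   3: signed Laplacian delay derivative, sign(x) * exp(-|x|/tau)/tau
//   4: Gaussian delay derivative, (x/tau^2) * exp(-x^2/(2 tau^2))
// Input spikes arrive concatenated with a 0-based synapse index so one call
// covers all synapses.
// [[Rcpp::export]]
NumericVector delta_brackets_cpp(NumericVector in_times, IntegerVector syn,
                                 int n_syn, NumericVector delays,
                                 NumericVector desired, NumericVector actual,
                                 double tau, int mode) {
  NumericVector B(n_syn);
  const int n_in = in_times.size();
  const int n_d = desired.size();
  const int n_a = actual.size();
  for (int j = 0; j < n_in; ++j) {
    const int i = syn[j];
    const double a = in_times[j] + delays[i];
    double acc = 0.0;
    for (int g = 0; g < n_d + n_a; ++g) {
      const double x = (g < n_d ? desired[g] : actual[g - n_d]) - a;
      double v;
      switch (mode) {
      case 0: v = std::exp(-std::fabs(x) / tau); break;
      case 1: v = std::exp(-x * x / (2.0 * tau * tau)); break;
      case 2: v = std::exp(-std::fabs(x) / tau) / tau; break;
      case 3:
        v = ((x > 0) - (x < 0)) * std::exp(-std::fabs(x) / tau) / tau;
        break;
      default: v = (x / (tau * tau)) * std::exp(-x * x / (2.0 * tau * tau));
      }
      acc += (g < n_d) ? v : -v;
    }
    B[i] += acc;
  }
  return B;
}

// Kernel-filtered signal of a spike train evaluated on the uniform grid
// {0, dt, ..., (n_grid-1)*dt}; no truncation, so it agrees with pointwise
// scalar evaluation to round-off. family: 0 Laplacian, 1 Gaussian.
// [[Rcpp::export]]
NumericVector kernel_signal_grid_cpp(NumericVector times, int n_grid,
                                     double dt, double scale, int family) {
  NumericVector f(n_grid);
  const int n = times.size();
  for (int j = 0; j < n; ++j) {
    const double tf = times[j];
    for (int k = 0; k < n_grid; ++k) {
      const double s = k * dt - tf;
      f[k] += (family == 1) ? std::exp(-s * s / (2.0 * scale * scale))
                            : std::exp(-std::fabs(s) / scale);
    }
  }
  return f;
}
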