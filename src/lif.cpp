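#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integration of the conductance-based LIF network.
//
// Per step: (1) exponential decay of the three conductance classes;
// (2) delivery of last step's internal spikes and freshly drawn external
// Poisson counts as conductance jumps ghat/tau per spike (the exact integral
// of the first-order synapse against a delta input, so total charge is
// independent of dt); (3) membrane update with additive noise of intensity Q
// for non-refractory units; (4) threshold/reset/refractory bookkeeping.
//
// Uses R's RNG (norm_rand / R::rpois): the caller brackets the call with
// set.seed() for determinism. Noiseless runs (Q == 0) draw no normals so the
// stream differs from a Q > 0 run by construction.
//
// adj_targets / adj_ptr: CSR by source, 1-based indices as produced in R.
// ext_rate_ms: per-unit aggregate external Poisson rate (events per ms).
// g_ext_clamp: if >= 0, the external conductance of every unit is held at
// this constant and no external events are drawn (used by analytic oracles).
// [[Rcpp::export]]
List lif_integrate_cpp(int n, IntegerVector is_exc,
                       IntegerVector adj_targets, IntegerVector adj_ptr,
                       NumericVector ext_rate_ms,
                       NumericVector v_init,
                       double dt, int n_steps,
                       double v_thres, double v_reset, double v_leak,
                       double v_rev_exc, double v_rev_inh, double v_rev_ext,
                       double tau_mem, double tau_e, double tau_i,
                       double tau_x, int n_ref_steps,
                       double g_leak, double ghat_e, double ghat_i,
                       double ghat_x, double q_noise,
                       double g_ext_clamp) {
  std::vector<double> v(v_init.begin(), v_init.end());
  std::vector<double> ge(n, 0.0), gi(n, 0.0), gx(n, 0.0);
  std::vector<int> ref(n, 0);
  const bool clamp_ext = g_ext_clamp >= 0.0;
  if (clamp_ext) std::fill(gx.begin(), gx.end(), g_ext_clamp);

  const double de = dt / tau_e, di = dt / tau_i, dx = dt / tau_x;
  const double je = ghat_e / tau_e, ji = ghat_i / tau_i, jx = ghat_x / tau_x;
  const double noise_sd = std::sqrt(q_noise * dt) / tau_mem;
  const double dtm = dt / tau_mem, ginv = 1.0 / g_leak;

  NumericVector phi_e(n_steps), phi_i(n_steps), phi_x(n_steps);
  NumericVector v_mean(n_steps), v_mean_exc(n_steps);
  std::vector<int> sp_unit;
  std::vector<double> sp_time;
  std::vector<int> pending;      // units that spiked in the previous step
  pending.reserve(256);

  int n_exc = 0;
  for (int i = 0; i < n; ++i) n_exc += is_exc[i];
  const double inv_n = 1.0 / n;
  const double inv_exc = n_exc > 0 ? 1.0 / n_exc : 0.0;

  for (int t = 0; t < n_steps; ++t) {
    // conductance decay
    for (int i = 0; i < n; ++i) {
      ge[i] -= ge[i] * de;
      gi[i] -= gi[i] * di;
    }
    if (!clamp_ext) for (int i = 0; i < n; ++i) gx[i] -= gx[i] * dx;

    // deliver internal spikes emitted in the previous step
    long ne_del = 0, ni_del = 0;
    for (size_t s = 0; s < pending.size(); ++s) {
      const int m = pending[s];
      const int lo = adj_ptr[m] - 1, hi = adj_ptr[m + 1] - 1;
      if (is_exc[m]) {
        for (int e = lo; e < hi; ++e) ge[adj_targets[e] - 1] += je;
        ne_del += hi - lo;
      } else {
        for (int e = lo; e < hi; ++e) gi[adj_targets[e] - 1] += ji;
        ni_del += hi - lo;
      }
    }
    pending.clear();
    phi_e[t] = ne_del * inv_n / dt;
    phi_i[t] = ni_del * inv_n / dt;

    // external Poisson counts (aggregate rate per unit)
    long nx = 0;
    if (!clamp_ext) {
      for (int i = 0; i < n; ++i) {
        const double lam = ext_rate_ms[i] * dt;
        if (lam > 0.0) {
          const int c = (int) R::rpois(lam);
          if (c > 0) { gx[i] += jx * c; nx += c; }
        }
      }
    }
    phi_x[t] = nx * inv_n / dt;

    // membrane update, threshold, reset
    double acc = 0.0, acc_exc = 0.0;
    for (int i = 0; i < n; ++i) {
      if (ref[i] > 0) {
        v[i] = v_reset;
        --ref[i];
      } else {
        double vi = v[i];
        double drift = -((vi - v_leak)
                         + ginv * (ge[i] * (vi - v_rev_exc)
                                   + gi[i] * (vi - v_rev_inh)
                                   + gx[i] * (vi - v_rev_ext)));
        vi += drift * dtm;
        if (noise_sd > 0.0) vi += noise_sd * norm_rand();
        if (!std::isfinite(vi))
          stop("non-finite membrane potential at step %d, unit %d", t + 1, i + 1);
        if (vi >= v_thres) {
          sp_unit.push_back(i + 1);
          sp_time.push_back((t + 1) * dt);
          pending.push_back(i);
          vi = v_reset;
          ref[i] = n_ref_steps;
        }
        v[i] = vi;
      }
      acc += v[i];
      if (is_exc[i]) acc_exc += v[i];
    }
    v_mean[t] = acc * inv_n;
    v_mean_exc[t] = acc_exc * inv_exc;
  }

  return List::create(
    _["spike_unit"] = wrap(sp_unit),
    _["spike_time"] = wrap(sp_time),
    _["phi_exc"] = phi_e, _["phi_inh"] = phi_i, _["phi_ext"] = phi_x,
    _["v_mean"] = v_mean, _["v_mean_exc"] = v_mean_exc,
    _["v_final"] = wrap(v));
}

// Forward-Euler integration of the factorised second-order mass dynamics
//   [tau_mem d/dt + 1][tau_syn d/dt + 1] V = J(t)
// in cascade form U := tau_syn dV/dt + V, so dU = (J - U) dt / tau_mem and
// dV = (U - V) dt / tau_syn. The forcing potential F in
//   J = v_leak - sum_sigma r_sigma (F - v_rev_sigma) Phi_sigma
// is the constant v_bar for the conventional model (mfm = false) and the
// instantaneous state V for the modified model (mfm = true); the drive is
// held piecewise constant per bin.
// method = 0: forward Euler (the stated reference scheme; conditionally
// stable for the MFM, whose parametric forcing makes the frozen system's
// effective restoring coefficient a(t) = sum_sigma r_sigma Phi_sigma spike
// during population bursts).
// method = 1: per-bin exact propagation. Within a bin the coefficients are
// constant, so the cascade is a 2x2 affine LTI system x' = M x + c with
//   x = (V, U),  M = [[-1/ts, 1/ts], [-a/tm, -1/tm]],
//   fixed point V* = U* = (v_leak + b) / (1 + a),
// advanced by x <- x* + exp(M dt)(x - x*) using Putzer's form of the 2x2
// matrix exponential (complex eigenvalues handled in complex arithmetic).
// Unconditionally stable for a >= 0 and identical to Euler up to O(dt)
// whenever Euler is stable.
// [[Rcpp::export]]
NumericVector mass_integrate_cpp(NumericVector phi_e, NumericVector phi_i,
                                 NumericVector phi_x,
                                 double dt, double tau_mem, double tau_syn,
                                 double v_leak, double v_rev_exc,
                                 double v_rev_inh, double v_rev_ext,
                                 double r_exc, double r_inh, double r_ext,
                                 double v_bar, bool mfm,
                                 double v0, double dv0, int method) {
  const int n = phi_e.size();
  if (phi_i.size() != n || phi_x.size() != n)
    stop("drive channels must share one length");
  NumericVector out(n);
  double V = v0;
  double U = tau_syn * dv0 + v0;
  const double dm = dt / tau_mem, ds = dt / tau_syn;
  const double am = 1.0 / tau_mem, as = 1.0 / tau_syn;

  if (method == 0) {
    for (int t = 0; t < n; ++t) {
      const double F = mfm ? V : v_bar;
      const double J = v_leak
        - r_exc * (F - v_rev_exc) * phi_e[t]
        - r_inh * (F - v_rev_inh) * phi_i[t]
        - r_ext * (F - v_rev_ext) * phi_x[t];
      const double Un = U + (J - U) * dm;
      V += (U - V) * ds;
      U = Un;
      if (!std::isfinite(V)) stop("non-finite mass potential at step %d", t + 1);
      out[t] = V;
    }
    return out;
  }

  for (int t = 0; t < n; ++t) {
    // J = v_leak - sum r (F - vrev) Phi = v_leak + b - a F; for the CFM the
    // forcing F = v_bar is constant, so fold a*v_bar into b and set a = 0.
    double a = r_exc * phi_e[t] + r_inh * phi_i[t] + r_ext * phi_x[t];
    double b = r_exc * v_rev_exc * phi_e[t] + r_inh * v_rev_inh * phi_i[t]
      + r_ext * v_rev_ext * phi_x[t];
    if (!mfm) { b -= a * v_bar; a = 0.0; }
    const double vstar = (v_leak + b) / (1.0 + a);

    // eigenvalues of M: l^2 + (am + as) l + (1 + a) am as = 0
    const std::complex<double> disc =
      std::sqrt(std::complex<double>((am + as) * (am + as)
                                     - 4.0 * (1.0 + a) * am * as, 0.0));
    const std::complex<double> l1 = 0.5 * (-(am + as) + disc);
    const std::complex<double> l2 = 0.5 * (-(am + as) - disc);
    const std::complex<double> e1 = std::exp(l1 * dt);
    const std::complex<double> e2 = std::exp(l2 * dt);
    // exp(M dt) = e1 I + r (M - l1 I), r = (e2 - e1)/(l2 - l1)
    const std::complex<double> r = (std::abs(l2 - l1) > 1e-14)
      ? (e2 - e1) / (l2 - l1) : std::complex<double>(dt, 0.0) * e1;
    const double dV = V - vstar, dU = U - vstar;
    const std::complex<double> nV =
      e1 * dV + r * ((-as - l1) * dV + as * dU);
    const std::complex<double> nU =
      e1 * dU + r * (-a * am * dV + (-am - l1) * dU);
    V = vstar + nV.real();
    U = vstar + nU.real();
    if (!std::isfinite(V)) stop("non-finite mass potential at step %d", t + 1);
    out[t] = V;
  }
  return out;
}
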