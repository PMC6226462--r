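#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hodgkin-Huxley single compartment, forward Euler.
// Units: V in volts, time in seconds, currents in A/cm^2, conductances in
// S/cm^2, capacitance in F/cm^2. Gating rates are in 1/ms as printed and are
// converted to 1/s inside the step.

static inline double rate_alpha_n(double dV, double phi) {
  double den = std::exp(1.0 - 0.1 * dV) - 1.0;
  if (std::fabs(den) < 1e-12) return phi * 0.1;  // removable singularity at dV = 10
  return phi * (0.10 - 0.01 * dV) / den;
}

static inline double rate_alpha_m(double dV, double phi) {
  double den = std::exp(2.5 - 0.1 * dV) - 1.0;
  if (std::fabs(den) < 1e-12) return phi * 1.0;  // removable singularity at dV = 25
  return phi * (2.5 - 0.1 * dV) / den;
}

struct HHP {
  double Vr, E_Na, E_K, E_l, Cm, G_K, G_Na, G_l, J_ext, phi;
  bool transposed;
};

static inline void derivs(const HHP &p, double V, double n, double m, double h,
                          double &dV, double &dn, double &dm, double &dh) {
  double dVmv = (V - p.Vr) * 1000.0;
  double an = rate_alpha_n(dVmv, p.phi);
  double bn = p.phi * 0.125 * std::exp(-dVmv / 80.0);
  double am = rate_alpha_m(dVmv, p.phi);
  double bm = p.phi * 4.0 * std::exp(-dVmv / 18.0);
  double ah = p.phi * 0.07 * std::exp(-dVmv / 20.0);
  double bh = p.phi / (std::exp(3.0 - 0.1 * dVmv) + 1.0);

  double gK, gNa;
  if (p.transposed) {  // literal printed gate assignment, for comparison only
    gK  = p.G_K  * m * m * m * m;
    gNa = p.G_Na * n * n * n * h;
  } else {             // canonical gates
    gK  = p.G_K  * n * n * n * n;
    gNa = p.G_Na * m * m * m * h;
  }
  double J_ion = gNa * (V - p.E_Na) + gK * (V - p.E_K) + p.G_l * (V - p.E_l);
  dV = (p.J_ext - J_ion) / p.Cm;                 // V/s
  dn = 1000.0 * (an * (1.0 - n) - bn * n);       // 1/s
  dm = 1000.0 * (am * (1.0 - m) - bm * m);
  dh = 1000.0 * (ah * (1.0 - h) - bh * h);
}

static inline double clip_gate(double x, int step, const char *name) {
  if (x < 0.0) {
    if (x > -1e-9) return 0.0;
    stop("gating variable %s left [0,1] (%.3e) at step %d", name, x, step);
  }
  if (x > 1.0) {
    if (x < 1.0 + 1e-9) return 1.0;
    stop("gating variable %s left [0,1] (%.3e) at step %d", name, x, step);
  }
  return x;
}

// [[Rcpp::export(name = ".hh_euler_cpp")]]
List hh_euler_cpp(NumericVector par, NumericVector init, double duration,
                  double dt, bool transposed, bool keep_gates) {
  HHP p{par[0], par[1], par[2], par[3], par[4], par[5], par[6], par[7],
        par[8], par[9], transposed};
  int nstep = (int)std::lround(duration / dt);
  int nsamp = nstep + 1;
  NumericVector V(nsamp);
  NumericVector ns, ms, hs;
  if (keep_gates) { ns = NumericVector(nsamp); ms = NumericVector(nsamp); hs = NumericVector(nsamp); }

  double v = init[0], n = init[1], m = init[2], h = init[3];
  V[0] = v;
  if (keep_gates) { ns[0] = n; ms[0] = m; hs[0] = h; }
  double dV, dn, dm, dh;
  for (int i = 1; i < nsamp; ++i) {
    derivs(p, v, n, m, h, dV, dn, dm, dh);
    v += dV * dt;
    n = clip_gate(n + dn * dt, i, "n");
    m = clip_gate(m + dm * dt, i, "m");
    h = clip_gate(h + dh * dt, i, "h");
    if (!std::isfinite(v)) stop("integration diverged (non-finite V) at step %d", i);
    V[i] = v;
    if (keep_gates) { ns[i] = n; ms[i] = m; hs[i] = h; }
  }
  if (keep_gates)
    return List::create(_["v"] = V, _["n"] = ns, _["m"] = ms, _["h"] = hs);
  return List::create(_["v"] = V);
}

// Integrate and count voltage peaks above `thresh` (volts) without storing
// the trace: a peak is a strict local maximum (plateaus counted once).
// [[Rcpp::export(name = ".hh_count_cpp")]]
int hh_count_cpp(NumericVector par, NumericVector init, double duration,
                 double dt, bool transposed, double thresh) {
  HHP p{par[0], par[1], par[2], par[3], par[4], par[5], par[6], par[7],
        par[8], par[9], transposed};
  int nstep = (int)std::lround(duration / dt);
  double v = init[0], n = init[1], m = init[2], h = init[3];
  double dV, dn, dm, dh;
  double prev = v, peak = v;
  bool rising = false;
  int count = 0;
  for (int i = 1; i <= nstep; ++i) {
    derivs(p, v, n, m, h, dV, dn, dm, dh);
    v += dV * dt;
    n = clip_gate(n + dn * dt, i, "n");
    m = clip_gate(m + dm * dt, i, "m");
    h = clip_gate(h + dh * dt, i, "h");
    if (!std::isfinite(v)) stop("integration diverged (non-finite V) at step %d", i);
    if (v > prev) { rising = true; peak = v; }
    else if (v < prev && rising) {
      if (peak > thresh) ++count;
      rising = false;
    }
    prev = v;
  }
  return count;
}

// [[Rcpp::export(name = ".hh_sweep_cpp")]]
IntegerMatrix hh_sweep_cpp(NumericVector par, NumericVector init,
                           NumericVector cm_grid, NumericVector jext_grid,
                           double duration, double dt, bool transposed,
                           double thresh) {
  int nc = cm_grid.size(), nj = jext_grid.size();
  IntegerMatrix rate(nc, nj);
  NumericVector par2 = clone(par);
  for (int i = 0; i < nc; ++i) {
    for (int j = 0; j < nj; ++j) {
      par2[4] = cm_grid[i];
      par2[8] = jext_grid[j];
      rate(i, j) = hh_count_cpp(par2, init, duration, dt, transposed, thresh);
    }
    Rcpp::checkUserInterrupt();
  }
  return rate;
}
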