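#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Leaky integrate-and-fire with instantaneous synaptic charge injection.
// Units: C in pF, R in MOhm, V in mV, time in ms, I in pA. Note
// pF * MOhm = us (so tau_ms = R*C/1000), pA * MOhm = uV (so the steady
// deflection in mV is I*R/1000), and pC/pF = V (so dV_syn = 1000*w/C mV).
// [[Rcpp::export(name = ".lif_sim_cpp")]]
NumericVector lif_sim_cpp(double C, double R, double v_rest, double v_thresh,
                          double v_reset, double t_ref, double syn_weight,
                          double fixed_dv, NumericVector input_times,
                          double duration, double dt, double i_const) {
  double tau = R * C / 1000.0;        // ms
  double dv_syn = (fixed_dv > 0.0) ? fixed_dv : 1000.0 * syn_weight / C;
  int nstep = (int)std::lround(duration / dt);
  int ni = input_times.size();
  std::vector<double> out;
  double v = v_rest;
  double refr_until = -1.0;
  int next_in = 0;
  for (int i = 0; i < nstep; ++i) {
    double t = i * dt;
    bool refractory = (t < refr_until);
    if (!refractory) {
      // i_const [pA] * R [MOhm] = 1e-6 V -> /1000 for mV
      v += dt * (-(v - v_rest) / tau + (i_const * R / 1000.0) / tau);
    }
    // deliver input spikes falling in (t, t+dt]
    while (next_in < ni && input_times[next_in] <= t + dt) {
      if (!refractory) v += dv_syn;
      ++next_in;
    }
    if (!refractory && v >= v_thresh) {
      out.push_back(std::min(t + dt, duration));
      v = v_reset;
      refr_until = t + dt + t_ref;
    }
  }
  return wrap(out);
}
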