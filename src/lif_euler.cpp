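#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of a leaky integrate-and-fire neuron with
// conductance input folded into two per-step traces:
//   g_sum[k]  = sum_n alpha_n * P_n(t_k)            (coefficient on Vm)
//   gv_sum[k] = sum_n alpha_n * P_n(t_k) * Vsyn_n   (drive toward reversals)
// so that the synaptic current term is -(Rm/tau_m)*(g_sum*Vm - gv_sum).
// Units: ms, mV, MOhm, uS, nA. Threshold is tested after the update; the
// spike time is the updated step's grid time and Vm is set to V_reset on
// that step; integration resumes from V_reset on the next step (at most
// one spike per step).
// [[Rcpp::export]]
List lif_euler_cpp(double dt, int n_steps, double v0,
                   double tau_m, double R_m, double V_e,
                   double V_thresh, double V_reset,
                   NumericVector g_sum, NumericVector gv_sum,
                   NumericVector I_inj, bool record_v) {
  NumericVector V(record_v ? n_steps : 1);
  std::vector<double> spikes;
  double v = v0;
  if (record_v) V[0] = v;
  const bool has_g = g_sum.size() > 0;
  const bool has_i = I_inj.size() > 0;
  const double k_leak = dt / tau_m;
  const double k_syn = dt * R_m / tau_m;
  for (int k = 1; k < n_steps; ++k) {
    double dv = -(v - V_e) * k_leak;
    if (has_g) dv += -k_syn * (g_sum[k - 1] * v - gv_sum[k - 1]);
    if (has_i) dv += k_syn * I_inj[k - 1];
    v += dv;
    if (v >= V_thresh) {
      spikes.push_back(k * dt);
      v = V_reset;
    }
    if (record_v) V[k] = v;
  }
  return List::create(_["spike_times"] = wrap(spikes),
                      _["V_m"] = record_v ? V : NumericVector(0));
}
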