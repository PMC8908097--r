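#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of a network of stochastic Izhikevich neurons
// with conductance-based synapses.
//
// Per step (from old state v, u, ge, gi):
//   I_i  = ge_i (V_E - v_i) + gi_i (V_I - v_i)
//   v_i += dt (0.04 v_i^2 + 5 v_i + 140 - u_i + I_i) + alpha sqrt(dt) z_i
//   u_i += dt a_i (b_i v_i - u_i)            [v_i = pre-update value]
//   ge, gi *= exp(-dt / tau)                 [exact inter-spike decay]
//   v_i >= v_thr: spike at t = s*dt, v_i -> c_i, u_i += d_i
//   spikes delivered after decay/reset: targets' ge or gi += |w|, so the
//   conductance sampled at a delivery instant includes the new increment
//   and spikes first affect the synaptic current at the following step.
//
// Connectivity is passed in compressed-sparse-column form over presynaptic
// neurons: column j's edges are tgt_i[p[j]..p[j+1]-1] with magnitudes
// tgt_w and excitatory flags edge_exc.
//
// [[Rcpp::export]]
List izh_run_cpp(IntegerVector col_ptr, IntegerVector tgt_i, NumericVector tgt_w,
                 LogicalVector edge_exc,
                 NumericVector a, NumericVector b, NumericVector c, NumericVector d,
                 NumericVector v0, NumericVector u0,
                 NumericVector ge0, NumericVector gi0, NumericVector I_ext,
                 double dt, int n_steps, double alpha,
                 double v_thr, double V_E, double V_I,
                 double tau_exc, double tau_inh,
                 bool record_g, double v_guard) {
  const int n = v0.size();
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> ge(ge0.begin(), ge0.end());
  std::vector<double> gi(gi0.begin(), gi0.end());
  const double dec_e = std::exp(-dt / tau_exc);
  const double dec_i = std::exp(-dt / tau_inh);
  const double sqrt_dt = std::sqrt(dt);

  std::vector<int> sp_neuron, sp_step, spiked;
  sp_neuron.reserve(1024);
  sp_step.reserve(1024);

  NumericMatrix ge_trace, gi_trace;
  if (record_g) {
    ge_trace = NumericMatrix(n, n_steps + 1);
    gi_trace = NumericMatrix(n, n_steps + 1);
    for (int i = 0; i < n; ++i) {
      ge_trace(i, 0) = ge[i];
      gi_trace(i, 0) = gi[i];
    }
  }

  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i) {
      const double vi = v[i];
      const double I = ge[i] * (V_E - vi) + gi[i] * (V_I - vi) + I_ext[i];
      double vn = vi + dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - u[i] + I);
      if (alpha > 0.0) vn += alpha * sqrt_dt * norm_rand();
      u[i] += dt * a[i] * (b[i] * vi - u[i]);
      v[i] = vn;
    }
    for (int i = 0; i < n; ++i) {
      ge[i] *= dec_e;
      gi[i] *= dec_i;
    }
    spiked.clear();
    for (int i = 0; i < n; ++i) {
      if (v[i] >= v_thr) {
        spiked.push_back(i);
        v[i] = c[i];
        u[i] += d[i];
      } else if (!std::isfinite(v[i]) || std::fabs(v[i]) > v_guard) {
        stop("membrane potential of neuron %d is non-finite or beyond +/-%g mV at t = %g ms: integration diverged",
             i + 1, v_guard, s * dt);
      }
    }
    for (size_t k = 0; k < spiked.size(); ++k) {
      const int j = spiked[k];
      sp_neuron.push_back(j + 1);
      sp_step.push_back(s);
      for (int e = col_ptr[j]; e < col_ptr[j + 1]; ++e) {
        if (edge_exc[e]) ge[tgt_i[e]] += tgt_w[e];
        else gi[tgt_i[e]] += tgt_w[e];
      }
    }
    if (record_g) {
      for (int i = 0; i < n; ++i) {
        ge_trace(i, s) = ge[i];
        gi_trace(i, s) = gi[i];
      }
    }
  }

  List out = List::create(
    _["spike_neuron"] = IntegerVector(sp_neuron.begin(), sp_neuron.end()),
    _["spike_step"] = IntegerVector(sp_step.begin(), sp_step.end()),
    _["v"] = NumericVector(v.begin(), v.end()),
    _["u"] = NumericVector(u.begin(), u.end()),
    _["g_exc"] = NumericVector(ge.begin(), ge.end()),
    _["g_inh"] = NumericVector(gi.begin(), gi.end()));
  if (record_g) {
    out["ge_trace"] = ge_trace;
    out["gi_trace"] = gi_trace;
  }
  return out;
}
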