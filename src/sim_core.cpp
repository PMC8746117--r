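#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// x / (1 - exp(-x/10)) with the removable singularity at x = 0
static inline double expm1_ratio(double x) {
  if (std::fabs(x) < 1e-7) return 10.0;
  return x / (-std::expm1(-x / 10.0));
}

// One network integration run. All indices are 0-based. Connections must be
// sorted by presynaptic neuron, with csr[i]..csr[i+1]-1 the out-edges of
// neuron i. conn_exc[c] == 1 targets the excitatory conductance of the
// postsynaptic neuron, 0 the inhibitory one. Weights in uS, potentials mV,
// currents nA, time ms. Background input: one compound Poisson process per
// neuron with bkg_mean expected events per step, each incrementing the
// background (excitatory) conductance by bkg_w[i].
// [[Rcpp::export]]
List sim_network_cpp(int n_areas,
                     IntegerVector area_of, IntegerVector is_exc,
                     NumericVector cm,
                     IntegerVector conn_post, NumericVector conn_w,
                     IntegerVector conn_delay, IntegerVector conn_exc,
                     IntegerVector csr,
                     NumericVector bkg_w, double bkg_mean,
                     NumericVector v0, NumericVector m0,
                     NumericVector h0, NumericVector n0,
                     double g_na, double g_k, double g_l,
                     double e_na, double e_k, double e_l,
                     double e_exc, double e_inh,
                     double tau_exc, double tau_inh,
                     double i_ext,
                     double dt, int n_steps, int max_delay,
                     double v_thresh, int refrac_steps,
                     bool record_currents) {
  const int n = v0.size();
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> gm(m0.begin(), m0.end());
  std::vector<double> gh(h0.begin(), h0.end());
  std::vector<double> gn(n0.begin(), n0.end());
  std::vector<double> gE(n, 0.0), gI(n, 0.0), gB(n, 0.0);
  std::vector<int> last_spike(n, -refrac_steps - 1);

  const int L = max_delay + 1;
  std::vector<double> incE((size_t)L * n, 0.0), incI((size_t)L * n, 0.0);

  const double dec_e = std::exp(-dt / tau_exc);
  const double dec_i = std::exp(-dt / tau_inh);

  std::vector<double> sp_time;
  std::vector<int> sp_neuron;
  sp_time.reserve(1 << 16);
  sp_neuron.reserve(1 << 16);

  NumericMatrix ie_rec(record_currents ? n_steps : 1,
                       record_currents ? n_areas : 1);
  NumericMatrix ii_rec(record_currents ? n_steps : 1,
                       record_currents ? n_areas : 1);
  NumericMatrix ib_rec(record_currents ? n_steps : 1,
                       record_currents ? n_areas : 1);

  std::vector<double> acc_e(n_areas), acc_i(n_areas), acc_b(n_areas);

  for (int t = 0; t < n_steps; ++t) {
    const size_t slot = (size_t)(t % L) * n;
    // deliver scheduled synaptic increments, then clear the slot
    for (int i = 0; i < n; ++i) {
      gE[i] += incE[slot + i];
      gI[i] += incI[slot + i];
      incE[slot + i] = 0.0;
      incI[slot + i] = 0.0;
    }
    // background Poisson drive
    if (bkg_mean > 0) {
      for (int i = 0; i < n; ++i) {
        double k = R::rpois(bkg_mean);
        if (k > 0) gB[i] += k * bkg_w[i];
      }
    }
    if (record_currents) {
      std::fill(acc_e.begin(), acc_e.end(), 0.0);
      std::fill(acc_i.begin(), acc_i.end(), 0.0);
      std::fill(acc_b.begin(), acc_b.end(), 0.0);
    }
    for (int i = 0; i < n; ++i) {
      const double vi = v[i];
      if (record_currents && is_exc[i]) {
        const int a = area_of[i];
        acc_e[a] += std::fabs(gE[i] * (e_exc - vi));
        acc_i[a] += std::fabs(gI[i] * (e_inh - vi));
        acc_b[a] += std::fabs(gB[i] * (e_exc - vi));
      }
      // gate rates (1/ms)
      const double am = 0.1 * expm1_ratio(vi + 16.0);
      const double bm = 4.0 * std::exp(-(vi + 41.0) / 18.0);
      const double ah = 0.07 * std::exp(-(vi + 30.0) / 20.0);
      const double bh = 1.0 / (1.0 + std::exp(-vi / 10.0));
      const double an = 0.01 * expm1_ratio(vi + 20.0);
      const double bn = 0.125 * std::exp(-(vi + 30.0) / 80.0);
      // membrane update (exponential Euler, gates/conductances frozen)
      const double gna = g_na * gm[i] * gm[i] * gm[i] * gh[i];
      const double gk = g_k * gn[i] * gn[i] * gn[i] * gn[i];
      const double denom = gna + gk + g_l + gE[i] + gI[i] + gB[i];
      const double num = gna * e_na + gk * e_k + g_l * e_l +
        gE[i] * e_exc + gI[i] * e_inh + gB[i] * e_exc + i_ext;
      const double v_inf = num / denom;
      const double v_new = v_inf + (vi - v_inf) * std::exp(-dt * denom / cm[i]);
      // gate updates (exact for frozen V)
      double s = am + bm;
      gm[i] = am / s + (gm[i] - am / s) * std::exp(-dt * s);
      s = ah + bh;
      gh[i] = ah / s + (gh[i] - ah / s) * std::exp(-dt * s);
      s = an + bn;
      gn[i] = an / s + (gn[i] - an / s) * std::exp(-dt * s);
      if (!std::isfinite(v_new)) {
        stop("non-finite membrane potential: area %d, neuron %d, t = %.2f ms",
             area_of[i] + 1, i + 1, t * dt);
      }
      // spike detection: upward threshold crossing with detection refractory
      if (v_new >= v_thresh && vi < v_thresh &&
          (t - last_spike[i]) > refrac_steps) {
        last_spike[i] = t;
        sp_time.push_back((t + 1) * dt);
        sp_neuron.push_back(i);
        for (int c = csr[i]; c < csr[i + 1]; ++c) {
          const size_t tgt = (size_t)((t + conn_delay[c]) % L) * n + conn_post[c];
          if (conn_exc[c]) incE[tgt] += conn_w[c];
          else incI[tgt] += conn_w[c];
        }
      }
      v[i] = v_new;
    }
    if (record_currents) {
      for (int a = 0; a < n_areas; ++a) {
        ie_rec(t, a) = acc_e[a];
        ii_rec(t, a) = acc_i[a];
        ib_rec(t, a) = acc_b[a];
      }
    }
    // conductance decay (exact)
    for (int i = 0; i < n; ++i) {
      gE[i] *= dec_e;
      gI[i] *= dec_i;
      gB[i] *= dec_e;
    }
  }

  return List::create(
    _["spike_time"] = NumericVector(sp_time.begin(), sp_time.end()),
    _["spike_neuron"] = IntegerVector(sp_neuron.begin(), sp_neuron.end()),
    _["i_e"] = ie_rec, _["i_i"] = ii_rec, _["i_bkg"] = ib_rec);
}
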