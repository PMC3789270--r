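#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Clock-driven simulation of the full network for one trial.
//
// State per neuron: Izhikevich (v, u) plus four conductances. Synapses are
// stored in CSR order by presynaptic neuron with two effective weights per
// synapse: the fast channel (AMPA for excitatory sources, GABA-A for
// inhibitory) and the slow channel (NMDA / GABA-B). Neuromodulatory channel
// factors and the 1/scale compensation are already folded into the weights
// by the R side; the per-neuron current gain mu_I is applied to the total
// synaptic current.
//
// Time marches in 1-ms synaptic slots. Per slot: conductances decay by the
// exact exponential factor, spikes from the previous slot (1-ms transmission
// delay) and external drive events for this slot increment conductances, the
// total current is evaluated once, and the membrane equations advance in
// `substeps` Euler half-steps. A neuron whose pre-reset voltage reaches
// 30 mV is reset to c with u incremented by d and contributes one spike to
// the next slot.
//
// The engine draws no random numbers; all stochasticity (connectivity,
// drive events) is generated by the R side, so trials are reproducible from
// R seeds alone.
// [[Rcpp::export]]
List simulate_trial_cpp(int n,
                        NumericVector a, NumericVector b,
                        NumericVector c_reset, NumericVector d_jump,
                        NumericVector mu_i, LogicalVector excitatory,
                        IntegerVector csr_ptr, IntegerVector csr_post,
                        NumericVector w_fast, NumericVector w_slow,
                        IntegerVector drive_ms, IntegerVector drive_target,
                        NumericVector drive_w,
                        int t_ms, int substeps = 2) {
  const double dec_a = std::exp(-1.0 / 5.0);
  const double dec_n = std::exp(-1.0 / 100.0);
  const double dec_ga = std::exp(-1.0 / 6.0);
  const double dec_gb = std::exp(-1.0 / 150.0);
  const double dt = 1.0 / substeps;

  std::vector<double> v(n), u(n), ga(n, 0.0), gn(n, 0.0), gga(n, 0.0),
      ggb(n, 0.0);
  for (int i = 0; i < n; ++i) {
    v[i] = c_reset[i];
    u[i] = b[i] * v[i];
  }

  std::vector<int> prev_spikes, cur_spikes;
  prev_spikes.reserve(n);
  cur_spikes.reserve(n);
  std::vector<int> spike_neuron;
  std::vector<int> spike_time;
  spike_neuron.reserve(16384);
  spike_time.reserve(16384);

  int ev = 0;
  const int n_ev = drive_ms.size();

  for (int t = 0; t < t_ms; ++t) {
    // conductance decay (exact exponential over 1 ms)
    for (int i = 0; i < n; ++i) {
      ga[i] *= dec_a;
      gn[i] *= dec_n;
      gga[i] *= dec_ga;
      ggb[i] *= dec_gb;
    }
    // delayed recurrent spikes from the previous slot
    for (size_t s = 0; s < prev_spikes.size(); ++s) {
      const int j = prev_spikes[s];
      const bool exc = excitatory[j];
      for (int k = csr_ptr[j]; k < csr_ptr[j + 1]; ++k) {
        const int p = csr_post[k];
        if (exc) {
          ga[p] += w_fast[k];
          gn[p] += w_slow[k];
        } else {
          gga[p] += w_fast[k];
          ggb[p] += w_slow[k];
        }
      }
    }
    // external drive events scheduled for this slot (excitatory)
    while (ev < n_ev && drive_ms[ev] == t) {
      const int p = drive_target[ev];
      ga[p] += drive_w[ev];
      gn[p] += drive_w[ev];
      ++ev;
    }
    // membrane update
    cur_spikes.clear();
    for (int i = 0; i < n; ++i) {
      const double vi0 = v[i];
      const double hx = (vi0 + 80.0) / 60.0;
      const double h = hx * hx / (1.0 + hx * hx);
      const double I = ga[i] * vi0 + gn[i] * h * vi0 + gga[i] * (vi0 + 70.0) +
                       ggb[i] * (vi0 + 90.0);
      const double Ieff = mu_i[i] * I;
      double vi = vi0, ui = u[i];
      bool fired = false;
      for (int s = 0; s < substeps; ++s) {
        const double u_in = ui;
        vi = vi + dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui - Ieff);
        if (vi >= 30.0) {
          vi = c_reset[i];
          ui = u_in + d_jump[i];
          fired = true;
        } else {
          ui = ui + dt * a[i] * (b[i] * vi - u_in);
        }
        // conductance inhibition cannot drive v below the most negative
        // reversal potential (-90 mV, GABA-B); without this floor a large
        // inhibitory step can push v past the quadratic's lower root where
        // the model is invalid and the neuron catapults unphysically
        if (vi < -90.0) vi = -90.0;
      }
      v[i] = vi;
      u[i] = ui;
      if (fired) {
        cur_spikes.push_back(i);
        spike_neuron.push_back(i + 1);
        spike_time.push_back(t);
      }
    }
    std::swap(prev_spikes, cur_spikes);
  }

  return List::create(_["neuron"] = wrap(spike_neuron),
                      _["time_ms"] = wrap(spike_time),
                      _["v"] = wrap(v), _["u"] = wrap(u));
}
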