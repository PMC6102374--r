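// Sparsely connected recurrent network of leaky integrate-and-fire
// neurons with current-based delta synapses and external Poisson drive.
// Fixed network: 10000 excitatory / 2500 inhibitory neurons, in-degrees
// 1000 (excitatory) and 250 (inhibitory), tau_m = 20 ms, theta = 20 mV,
// V_reset = 10 mV, refractory 2 ms.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// [[Rcpp::export(name = ".brunel_run")]]
List brunel_run(double eta, double g, double delay, double J,
                double t_sim, double t_record, int n_record,
                uint32_t seed, double dt) {
  const int NE = 10000, NI = 2500, CE = 1000, CI = 250;
  const int N = NE + NI;
  const double tau_m = 20.0, theta = 20.0, V_reset = 10.0, tau_rp = 2.0;
  if (delay < dt) stop("synaptic delay must be at least the step size");

  const int delay_steps = (int)std::lround(delay / dt);
  const int buf_len = delay_steps + 1;
  const int n_steps = (int)std::lround(t_sim / dt);
  const int ref_steps = (int)std::lround(tau_rp / dt);
  const double decay = std::exp(-dt / tau_m);
  // threshold rate nu_thr = theta / (J * CE * tau_m) spikes/ms; each neuron
  // receives external Poisson input of total rate eta * nu_thr * CE, so the
  // count per step has mean eta * nu_thr * CE * dt.
  const double lambda_ext = eta * theta / (J * tau_m) * dt;

  std::mt19937 rng(seed);
  std::uniform_int_distribution<int> pick_e(0, NE - 1);
  std::uniform_int_distribution<int> pick_i(NE, N - 1);
  std::poisson_distribution<int> pois(lambda_ext);

  // Fixed in-degree connectivity (CE excitatory + CI inhibitory sources per
  // neuron), stored as post-synaptic target lists in CSR layout so a spike
  // can be delivered by one sweep over the source's targets.
  std::vector<int32_t> targets((size_t)N * (CE + CI));
  std::vector<size_t> offs(N + 1, 0);
  {
    std::vector<int32_t> src((size_t)N * (CE + CI));
    std::vector<int32_t> deg(N, 0);
    size_t k = 0;
    for (int j = 0; j < N; ++j) {
      for (int c = 0; c < CE; ++c) { int s = pick_e(rng); src[k++] = s; deg[s]++; }
      for (int c = 0; c < CI; ++c) { int s = pick_i(rng); src[k++] = s; deg[s]++; }
    }
    for (int s = 0; s < N; ++s) offs[s + 1] = offs[s] + deg[s];
    std::vector<size_t> fill(offs.begin(), offs.end() - 1);
    k = 0;
    for (int j = 0; j < N; ++j) {
      for (int c = 0; c < CE + CI; ++c) {
        targets[fill[src[k]]++] = j;
        ++k;
      }
    }
  }

  std::vector<double> V(N, 0.0);
  std::vector<int> refractory(N, 0);
  // ring buffer of delayed synaptic input per neuron
  std::vector<double> buf((size_t)N * buf_len, 0.0);
  std::vector<int> spiking;
  spiking.reserve(N);
  std::vector<std::vector<double>> recorded(n_record);

  for (int step = 0; step < n_steps; ++step) {
    const double t = (step + 1) * dt;
    const int slot = step % buf_len;
    spiking.clear();
    for (int i = 0; i < N; ++i) {
      const size_t bi = (size_t)i * buf_len + slot;
      const double input = buf[bi] + J * pois(rng);
      buf[bi] = 0.0;
      if (refractory[i] > 0) {
        --refractory[i];
        continue;
      }
      V[i] = V[i] * decay + input;
      if (V[i] >= theta) {
        V[i] = V_reset;
        refractory[i] = ref_steps;
        spiking.push_back(i);
        if (i < n_record && t >= t_record) recorded[i].push_back(t);
      }
    }
    const int dslot = (step + delay_steps) % buf_len;
    for (int s : spiking) {
      const double w = (s < NE) ? J : -g * J;
      const size_t lo = offs[s], hi = offs[s + 1];
      for (size_t e = lo; e < hi; ++e) {
        buf[(size_t)targets[e] * buf_len + dslot] += w;
      }
    }
  }

  List trains(n_record);
  for (int i = 0; i < n_record; ++i) trains[i] = wrap(recorded[i]);
  return List::create(_["spiketrains"] = trains,
                      _["simulation_end"] = t_sim);
}
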