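// Hodgkin-Huxley membrane model in the original 1952 convention
// (resting potential 0 mV, depolarisation positive). Fixed-step RK4.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rate functions (1/ms); singular points replaced by their limits.
static inline double alpha_n(double V) {
  double x = 10.0 - V;
  if (std::fabs(x) < 1e-7) return 0.1;
  return 0.01 * x / (std::exp(x / 10.0) - 1.0);
}
static inline double beta_n(double V) { return 0.125 * std::exp(-V / 80.0); }
static inline double alpha_m(double V) {
  double x = 25.0 - V;
  if (std::fabs(x) < 1e-7) return 1.0;
  return 0.1 * x / (std::exp(x / 10.0) - 1.0);
}
static inline double beta_m(double V) { return 4.0 * std::exp(-V / 18.0); }
static inline double alpha_h(double V) { return 0.07 * std::exp(-V / 20.0); }
static inline double beta_h(double V) {
  return 1.0 / (std::exp((30.0 - V) / 10.0) + 1.0);
}

struct HHState { double V, n, m, h; };

static inline HHState hh_deriv(const HHState& s, const double* p, double I) {
  // p: Cm, gNa, gK, gL, ENa, EK, EL
  HHState d;
  double iNa = p[1] * s.m * s.m * s.m * s.h * (s.V - p[4]);
  double iK  = p[2] * s.n * s.n * s.n * s.n * (s.V - p[5]);
  double iL  = p[3] * (s.V - p[6]);
  d.V = (I - iNa - iK - iL) / p[0];
  d.n = alpha_n(s.V) * (1.0 - s.n) - beta_n(s.V) * s.n;
  d.m = alpha_m(s.V) * (1.0 - s.m) - beta_m(s.V) * s.m;
  d.h = alpha_h(s.V) * (1.0 - s.h) - beta_h(s.V) * s.h;
  return d;
}

// One trace. params: V0, Cm, gNa, gK, gL, ENa, EK, EL, n0, m0, h0.
// Records V every `record_every` steps from t = 0 to t_end inclusive.
static void hh_integrate(const double* q, double stimulus, double t_end,
                         double dt, int record_every, double* out,
                         int n_out) {
  HHState s = {q[0], q[8], q[9], q[10]};
  const double* p = q + 1; // Cm .. EL
  int n_steps = (int)std::lround(t_end / dt);
  int rec = 0;
  out[rec++] = s.V;
  for (int k = 0; k < n_steps && rec < n_out; ++k) {
    HHState k1 = hh_deriv(s, p, stimulus);
    HHState s2 = {s.V + 0.5 * dt * k1.V, s.n + 0.5 * dt * k1.n,
                  s.m + 0.5 * dt * k1.m, s.h + 0.5 * dt * k1.h};
    HHState k2 = hh_deriv(s2, p, stimulus);
    HHState s3 = {s.V + 0.5 * dt * k2.V, s.n + 0.5 * dt * k2.n,
                  s.m + 0.5 * dt * k2.m, s.h + 0.5 * dt * k2.h};
    HHState k3 = hh_deriv(s3, p, stimulus);
    HHState s4 = {s.V + dt * k3.V, s.n + dt * k3.n,
                  s.m + dt * k3.m, s.h + dt * k3.h};
    HHState k4 = hh_deriv(s4, p, stimulus);
    s.V += dt / 6.0 * (k1.V + 2 * k2.V + 2 * k3.V + k4.V);
    s.n += dt / 6.0 * (k1.n + 2 * k2.n + 2 * k3.n + k4.n);
    s.m += dt / 6.0 * (k1.m + 2 * k2.m + 2 * k3.m + k4.m);
    s.h += dt / 6.0 * (k1.h + 2 * k2.h + 2 * k3.h + k4.h);
    if ((k + 1) % record_every == 0) out[rec++] = s.V;
  }
}

// [[Rcpp::export(name = ".hh_run_batch")]]
List hh_run_batch(NumericMatrix params, double stimulus, double t_end,
                  double dt, int record_every) {
  if (params.ncol() != 11) stop("params must have 11 columns");
  int n_steps = (int)std::lround(t_end / dt);
  int n_out = n_steps / record_every + 1;
  int n = params.nrow();
  NumericMatrix values(n, n_out);
  std::vector<double> trace(n_out), q(11);
  for (int r = 0; r < n; ++r) {
    for (int j = 0; j < 11; ++j) q[j] = params(r, j);
    hh_integrate(q.data(), stimulus, t_end, dt, record_every, trace.data(),
                 n_out);
    bool ok = true;
    for (int j = 0; j < n_out; ++j) {
      if (!std::isfinite(trace[j])) { ok = false; break; }
    }
    for (int j = 0; j < n_out; ++j) {
      values(r, j) = ok ? trace[j] : NA_REAL;
    }
  }
  NumericVector time(n_out);
  for (int j = 0; j < n_out; ++j) time[j] = j * record_every * dt;
  return List::create(_["time"] = time, _["values"] = values);
}
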