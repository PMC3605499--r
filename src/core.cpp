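#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Asymmetric STDP learning window.
//   tau > 0 : a_p exp(-tau/T_p)     - a_D exp(-eta tau/T_p)   (post after pre, mostly LTP)
//   tau < 0 : a_p exp(eta tau/T_D)  - a_D exp(tau/T_D)        (pre after post, mostly LTD)
// Continuous at 0 with value a_p - a_D.
static inline double window_A(double tau, double ap, double aD,
                              double Tp, double TD, double eta) {
  if (tau > 0.0) return ap * std::exp(-tau / Tp) - aD * std::exp(-eta * tau / Tp);
  if (tau < 0.0) return ap * std::exp(eta * tau / TD) - aD * std::exp(tau / TD);
  return ap - aD;
}

// [[Rcpp::export]]
NumericVector stdp_window_cpp(NumericVector tau, double ap, double aD,
                              double Tp, double TD, double eta) {
  R_xlen_t n = tau.size();
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) out[k] = window_A(tau[k], ap, aD, Tp, TD, eta);
  return out;
}

// Periodic pairwise sum sum_n A(dt0 + n T) truncated to |dt0 + n T| <= span.
static inline double periodic_sum(double dt0, double period, double span,
                                  double ap, double aD, double Tp, double TD,
                                  double eta) {
  // n range solving |dt0 + n T| <= span
  int nmin = (int)std::ceil((-span - dt0) / period);
  int nmax = (int)std::floor((span - dt0) / period);
  double s = 0.0;
  for (int n = nmin; n <= nmax; ++n) s += window_A(dt0 + n * period, ap, aD, Tp, TD, eta);
  return s;
}

// [[Rcpp::export]]
NumericVector periodic_weight_cpp(NumericVector dt0, double period, double span,
                                  double ap, double aD, double Tp, double TD,
                                  double eta) {
  R_xlen_t n = dt0.size();
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k)
    out[k] = periodic_sum(dt0[k], period, span, ap, aD, Tp, TD, eta);
  return out;
}

// Full N x N contribution of one phase pattern:
//   J(i,j) = sum_n A(t_i - t_j + n T),   t = phase/(2 pi) * T
// (post-minus-pre lag, the STDP convention of the learning integral: the
// connection j -> i is potentiated when post i fires shortly after pre j,
// which is what lets a cue drive the stored sequence forward).
// Diagonal left at zero (no self-connections).
// [[Rcpp::export]]
NumericMatrix pattern_weights_cpp(NumericVector phases, double period, double span,
                                  double ap, double aD, double Tp, double TD,
                                  double eta) {
  int N = phases.size();
  NumericMatrix J(N, N);
  const double f = period / (2.0 * M_PI);
  std::vector<double> t(N);
  for (int i = 0; i < N; ++i) t[i] = phases[i] * f;
  for (int j = 0; j < N; ++j) {
    double tj = t[j];
    double* col = &J(0, j);
    for (int i = 0; i < N; ++i) {
      if (i == j) continue;
      col[i] = periodic_sum(t[i] - tj, period, span, ap, aD, Tp, TD, eta);
    }
  }
  return J;
}

// Grid-stepped spike-response network simulation.
//
// Membrane potential: h_i(t) = K (Em_i - Es_i) where Em, Es accumulate incoming
// weights and decay with exp(-dt/tau_m), exp(-dt/tau_s). An arrival of weight w
// at step k contributes w * K (e^{-(t-t_k)/tau_m} - e^{-(t-t_k)/tau_s}) at later
// steps, i.e. the double-exponential kernel with epsilon(0) = 0; spikes emitted
// at a step therefore first influence others one step later. Firing resets both
// state variables to zero, discarding all arrivals up to and including the
// unit's own spike time ("only arrivals strictly after the last spike count").
// Cue events are imposed output spikes of the cued units: they reset the unit
// and propagate through J exactly like endogenous spikes. Noise events are
// external arrivals injected into the same kernel states (never propagated).
//
// cue/noise events must be sorted by step. Returns spike steps/units/sources
// (source 0 = network, 1 = cue) and, optionally, the potential trace.
// [[Rcpp::export]]
List simulate_cpp(NumericMatrix J, NumericVector theta, double dt, int n_steps,
                  double tau_m, double tau_s, double K,
                  IntegerVector cue_step, IntegerVector cue_unit,
                  IntegerVector noise_step, IntegerVector noise_unit,
                  NumericVector noise_w, bool record_potentials) {
  int N = J.nrow();
  if (J.ncol() != N) stop("weight matrix must be square");
  if (theta.size() != N) stop("threshold vector length must equal network size");

  const double dm = std::exp(-dt / tau_m);
  const double ds = std::exp(-dt / tau_s);

  std::vector<double> Em(N, 0.0), Es(N, 0.0);
  std::vector<int> spiking;        // units spiking this step
  std::vector<signed char> src(N, 0);

  std::vector<int> ev_step, ev_unit, ev_src;
  ev_step.reserve(4096); ev_unit.reserve(4096); ev_src.reserve(4096);

  R_xlen_t ci = 0, ni = 0;
  const R_xlen_t nc = cue_step.size(), nn = noise_step.size();

  NumericMatrix pot;
  if (record_potentials) pot = NumericMatrix(n_steps, N);

  for (int step = 0; step < n_steps; ++step) {
    // decay of kernel states
    for (int i = 0; i < N; ++i) { Em[i] *= dm; Es[i] *= ds; }

    // threshold crossings on the state carried over from previous steps
    spiking.clear();
    for (int i = 0; i < N; ++i) {
      double h = K * (Em[i] - Es[i]);
      if (record_potentials) pot(step, i) = h;
      if (h >= theta[i]) { spiking.push_back(i); src[i] = 1; }
    }
    // imposed cue spikes scheduled at this step
    for (; ci < nc && cue_step[ci] == step; ++ci) {
      int u = cue_unit[ci];
      if (src[u] == 0) spiking.push_back(u);
      src[u] = 2;                 // cue tag wins if the unit also crossed
    }
    if (!spiking.empty()) {
      std::sort(spiking.begin(), spiking.end());
      for (size_t k = 0; k < spiking.size(); ++k) {
        int u = spiking[k];
        ev_step.push_back(step);
        ev_unit.push_back(u);
        ev_src.push_back(src[u] == 2 ? 1 : 0);
      }
      // propagate this step's spikes to everyone ...
      for (size_t k = 0; k < spiking.size(); ++k) {
        const double* col = &J(0, spiking[k]);
        for (int i = 0; i < N; ++i) { Em[i] += col[i]; Es[i] += col[i]; }
      }
      // ... then reset the spiking units: clears their memory including
      // arrivals at exactly their own spike time (not strictly later).
      for (size_t k = 0; k < spiking.size(); ++k) {
        int u = spiking[k];
        Em[u] = 0.0; Es[u] = 0.0;
      }
    }
    // external noise arrivals at this step (skipped for units that just fired:
    // an arrival at the unit's own spike time is not strictly after it)
    for (; ni < nn && noise_step[ni] == step; ++ni) {
      int u = noise_unit[ni];
      if (src[u] == 0) { Em[u] += noise_w[ni]; Es[u] += noise_w[ni]; }
    }
    for (size_t k = 0; k < spiking.size(); ++k) src[spiking[k]] = 0;
    // also clear cue tags for units that were cued without network spike
    // (they are in `spiking` too, handled above)

    // early exit once nothing can ever fire again: no pending inputs and the
    // residual kernel state is numerically dead
    if (!record_potentials && ci >= nc && ni >= nn && (step % 64 == 0)) {
      double tot = 0.0;
      for (int i = 0; i < N; ++i) tot += std::fabs(Em[i]) + std::fabs(Es[i]);
      if (tot < 1e-12) break;
    }
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["step"] = wrap(ev_step),
    _["unit"] = wrap(ev_unit),
    _["source"] = wrap(ev_src));
  if (record_potentials) out["potentials"] = pot;
  return out;
}

// Most recent spike time per unit at or before each eval time, restricted to
// spikes in (t - T_star, t]. Returns an n_eval x N matrix of times (NaN where
// no spike falls in the window). Spike times must be sorted increasing.
// [[Rcpp::export]]
NumericMatrix last_spike_matrix_cpp(NumericVector times, IntegerVector units,
                                    int n_units, NumericVector eval_times,
                                    double T_star) {
  R_xlen_t n = times.size(), ne = eval_times.size();
  NumericMatrix out(ne, n_units);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (R_xlen_t e = 0; e < ne; ++e) {
    double t = eval_times[e], lo = t - T_star;
    // walk the (sorted) events once per eval time
    for (R_xlen_t k = 0; k < n; ++k) {
      double tk = times[k];
      if (tk > t) break;
      if (tk > lo) out(e, units[k]) = tk;  // later events overwrite: most recent
    }
  }
  return out;
}
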