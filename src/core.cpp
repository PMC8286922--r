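#include <Rcpp.h>
using namespace Rcpp;

// Parameter column layout shared by the single-cell and network integrators.
// 0 C, 1 k, 2 vr, 3 vt, 4 vpeak, 5 a, 6 b, 7 c, 8 d, 9 bias,
// 10 a2, 11 b2, 12 d2 (second slow variable, TC relay cells only),
// 13 da_d_scale (D1: after-spike increment shrinks with phi),
// 14 da_hyper_pA (D2: hyperpolarising current grows with phi)

static const double V_FLOOR = -100.0; // mV

// One forward-Euler step of the extended quadratic (Izhikevich-type) model.
// Returns spike flag; state updated in place.
static inline bool euler_step(double *v, double *u, double *w,
                              const double *p, double I, double phi,
                              double dt, bool has_w) {
  double C = p[0], k = p[1], vr = p[2], vt = p[3], vpeak = p[4];
  double a = p[5], b = p[6], c = p[7], d = p[8];
  double d_eff = d * (1.0 - p[13] * phi);   // D1-type facilitation
  double I_da  = -p[14] * phi;              // D2-type hyperpolarisation
  double v0 = *v;
  double dv = (k * (v0 - vr) * (v0 - vt) - *u - (has_w ? *w : 0.0)
               + p[9] + I + I_da) / C;
  *v += dt * dv;
  // hyperpolarisation floor (inhibitory reversal); keeps the quadratic
  // term well-behaved under strong synchronous inhibition
  if (*v < V_FLOOR) *v = V_FLOOR;
  *u += dt * a * (b * (v0 - vr) - *u);
  if (has_w) *w += dt * p[10] * (p[11] * (v0 - vr) - *w);
  if (*v >= vpeak) {
    *v = c;
    *u += d_eff;
    if (has_w) *w += p[12];
    return true;
  }
  return false;
}

// [[Rcpp::export(name = ".simulate_neuron_cpp")]]
List simulate_neuron_cpp(NumericVector par, NumericVector current,
                         double phi, double dt,
                         double v0, double u0, double w0) {
  int n = current.size();
  bool has_w = par[10] > 0.0;
  NumericVector v_trace(n + 1), u_trace(n + 1), w_trace(n + 1);
  std::vector<double> spikes;
  double v = v0, u = u0, w = w0;
  const double *p = REAL(par);
  v_trace[0] = v; u_trace[0] = u; w_trace[0] = w;
  for (int s = 0; s < n; ++s) {
    bool sp = euler_step(&v, &u, &w, p, current[s], phi, dt, has_w);
    if (sp) spikes.push_back(s * dt); // start-of-step timestamp
    v_trace[s + 1] = v; u_trace[s + 1] = u; w_trace[s + 1] = w;
    if (!R_finite(v))
      stop("membrane potential became non-finite at t = %f ms", s * dt);
  }
  return List::create(_["v"] = v_trace, _["u"] = u_trace, _["w"] = w_trace,
                      _["spike_times"] = wrap(spikes));
}

// Advance the whole network by nsteps. Synapses are delta-current pulses
// delivered through three delay ring buffers: plain edges, cortico-striatal
// edges onto D1 cells (gain g1[t]) and onto D2 cells (gain g2[t]).
// Poisson background arrives as pre-sorted (step, neuron, weight) events.
// No RNG is used here; the chunk is fully deterministic.
// [[Rcpp::export(name = ".step_network_chunk")]]
List step_network_chunk(NumericMatrix state,          // n x 3 (v,u,w)
                        NumericMatrix par,            // 15 x n (column per neuron)
                        LogicalVector has_w,
                        IntegerVector src_ptr,        // CSR over source id, 0-based, length n+1
                        IntegerVector edge_tgt,       // 0-based target ids
                        NumericVector edge_w,
                        IntegerVector edge_delay,     // steps, >= 1
                        IntegerVector edge_class,     // 0 plain, 1 ctx->D1, 2 ctx->D2
                        NumericMatrix buf_plain,      // D x n ring buffers
                        NumericMatrix buf_d1,
                        NumericMatrix buf_d2,
                        int ring_pos,
                        NumericVector phi,            // per step
                        NumericVector g1,
                        NumericVector g2,
                        NumericVector stim,           // per step, pA
                        LogicalVector stim_target,
                        IntegerVector poi_step,       // 0-based step within chunk, sorted
                        IntegerVector poi_neuron,     // 0-based
                        NumericVector poi_w,
                        double dt, int nsteps, double t0) {
  int n = state.nrow();
  int D = buf_plain.nrow();
  std::vector<int> sp_neuron;
  std::vector<double> sp_time;
  int pp = 0, npoi = poi_step.size();
  for (int s = 0; s < nsteps; ++s) {
    int row = (ring_pos + s) % D;
    // deposit Poisson events due this step
    while (pp < npoi && poi_step[pp] == s) {
      buf_plain(row, poi_neuron[pp]) += poi_w[pp];
      ++pp;
    }
    double ph = phi[s], gg1 = g1[s], gg2 = g2[s], st = stim[s];
    for (int i = 0; i < n; ++i) {
      double I = buf_plain(row, i) + gg1 * buf_d1(row, i) + gg2 * buf_d2(row, i);
      if (stim_target[i]) I += st;
      double v = state(i, 0), u = state(i, 1), w = state(i, 2);
      bool sp = euler_step(&v, &u, &w, &par(0, i), I, ph, dt, has_w[i]);
      if (!R_finite(v))
        stop("membrane potential blow-up: neuron %d at step %d", i + 1, s + 1);
      state(i, 0) = v; state(i, 1) = u; state(i, 2) = w;
      if (sp) {
        sp_neuron.push_back(i);
        sp_time.push_back(t0 + s * dt);
        for (int e = src_ptr[i]; e < src_ptr[i + 1]; ++e) {
          int trow = (row + edge_delay[e]) % D;
          int tgt = edge_tgt[e];
          switch (edge_class[e]) {
          case 1: buf_d1(trow, tgt) += edge_w[e]; break;
          case 2: buf_d2(trow, tgt) += edge_w[e]; break;
          default: buf_plain(trow, tgt) += edge_w[e];
          }
        }
      }
    }
    // consumed: clear this row for reuse one full ring revolution later
    for (int i = 0; i < n; ++i) {
      buf_plain(row, i) = 0.0; buf_d1(row, i) = 0.0; buf_d2(row, i) = 0.0;
    }
  }
  return List::create(_["spike_neuron"] = wrap(sp_neuron),
                      _["spike_time"] = wrap(sp_time),
                      _["ring_pos"] = (ring_pos + nsteps) % D);
}

// All-pairs additive STDP increment per edge. pre_spk/post_spk hold spike
// times grouped by source-/target-population local neuron index (1-based
// lists from R). Pairs with dt == 0 contribute nothing.
// [[Rcpp::export(name = ".stdp_delta_cpp")]]
NumericVector stdp_delta_cpp(IntegerVector edge_pre, IntegerVector edge_post,
                             List pre_spk, List post_spk,
                             double a_plus, double a_minus,
                             double tau_plus, double tau_minus) {
  int ne = edge_pre.size();
  NumericVector out(ne);
  for (int e = 0; e < ne; ++e) {
    NumericVector tp = pre_spk[edge_pre[e] - 1];
    NumericVector tq = post_spk[edge_post[e] - 1];
    double acc = 0.0;
    for (int i = 0; i < tp.size(); ++i) {
      for (int j = 0; j < tq.size(); ++j) {
        double dtij = tq[j] - tp[i];
        if (dtij > 0)      acc += a_plus  * std::exp(-dtij / tau_plus);
        else if (dtij < 0) acc -= a_minus * std::exp( dtij / tau_minus);
      }
    }
    out[e] = acc;
  }
  return out;
}
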