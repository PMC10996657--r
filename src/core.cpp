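#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Clock-driven integration of Izhikevich neurons with conductance-based
// Tsodyks-Markram synapses, 1 ms spike delivery, and online symmetric STDP
// on the plastic (recurrent excitatory) synapses.
//
// Conventions:
//  * all indices 0-based, all times in integration steps of dt ms;
//  * synaptic conductances are accumulated per (presynaptic type,
//    postsynaptic neuron) and decay with the connection type's tau_d, so
//    per-synapse state only needs the TM variables (u, x), updated lazily
//    with exact exponentials at each spike arrival;
//  * currents are held constant within a step (piecewise-constant forcing
//    for the classical RK4 step);
//  * STDP uses one exponentially decaying trace per neuron; spikes within a
//    step are processed in ascending neuron order with immediate trace
//    increments, which credits every pre/post spike pair (including exactly
//    coincident ones) exactly once per synapse.

static inline void izh_deriv(double v, double u, double C, double k,
                             double vr, double vt, double a, double b,
                             double I, double &dv, double &du) {
  dv = (k * (v - vr) * (v - vt) - u + I) / C;
  du = a * (b * (v - vr) - u);
}

// [[Rcpp::export]]
List sim_core(NumericVector nC, NumericVector nk, NumericVector nvr,
              NumericVector nvt, NumericVector na, NumericVector nb,
              NumericVector nd, NumericVector nvpeak, NumericVector nvmin,
              IntegerVector ntype, LogicalVector type_exc,
              IntegerVector syn_pre, IntegerVector syn_post,
              NumericVector syn_w_in, LogicalVector syn_plastic,
              NumericMatrix tm_g, NumericMatrix tm_tau_d,
              NumericMatrix tm_tau_r, NumericMatrix tm_tau_f,
              NumericMatrix tm_U,
              NumericMatrix I_base, NumericMatrix I_pres,  // n x K draws
              int bg_interval_steps,      // redraw interval (steps)
              NumericMatrix stim_delta,   // cols: step, neuron, delta_pA
              NumericMatrix forced,       // cols: step, neuron
              NumericMatrix pres_delta,   // cols: step, delta(+1/-1)
              int step_begin, int step_end, double dt, int delay_steps,
              bool plastic_on, double A, double tau_stdp,
              double w_min, double w_max, double E_exc, double E_inh,
              Nullable<List> state_in,
              IntegerVector record_v_idx) {
  const int n = nC.size();
  const int nsyn = syn_pre.size();
  const int T = type_exc.size();
  NumericVector syn_w = clone(syn_w_in);

  // CSR over all synapses by presynaptic neuron (delivery)
  std::vector<int> out_off(n + 1, 0), out_idx(nsyn);
  for (int s = 0; s < nsyn; ++s) out_off[syn_pre[s] + 1]++;
  for (int i = 0; i < n; ++i) out_off[i + 1] += out_off[i];
  {
    std::vector<int> cur(out_off.begin(), out_off.end() - 1);
    for (int s = 0; s < nsyn; ++s) out_idx[cur[syn_pre[s]]++] = s;
  }
  // CSR over plastic synapses by pre and by post (STDP)
  std::vector<int> pl_out_off(n + 1, 0), pl_in_off(n + 1, 0);
  int npl = 0;
  for (int s = 0; s < nsyn; ++s) if (syn_plastic[s]) {
    pl_out_off[syn_pre[s] + 1]++; pl_in_off[syn_post[s] + 1]++; npl++;
  }
  for (int i = 0; i < n; ++i) {
    pl_out_off[i + 1] += pl_out_off[i];
    pl_in_off[i + 1] += pl_in_off[i];
  }
  std::vector<int> pl_out_idx(npl), pl_in_idx(npl);
  {
    std::vector<int> co(pl_out_off.begin(), pl_out_off.end() - 1);
    std::vector<int> ci(pl_in_off.begin(), pl_in_off.end() - 1);
    for (int s = 0; s < nsyn; ++s) if (syn_plastic[s]) {
      pl_out_idx[co[syn_pre[s]]++] = s;
      pl_in_idx[ci[syn_post[s]]++] = s;
    }
  }

  // type-block boundaries (neurons are contiguous by type)
  std::vector<int> blk_begin(T, n), blk_end(T, 0);
  for (int i = 0; i < n; ++i) {
    int t = ntype[i];
    if (i < blk_begin[t]) blk_begin[t] = i;
    if (i + 1 > blk_end[t]) blk_end[t] = i + 1;
  }

  // per (pre type, post type) conductance decay per step
  std::vector<double> gdecay(T * T, 1.0);
  for (int a_ = 0; a_ < T; ++a_)
    for (int b_ = 0; b_ < T; ++b_) {
      double td = tm_tau_d(a_, b_);
      if (R_finite(td) && td > 0) gdecay[a_ * T + b_] = std::exp(-dt / td);
    }
  const double trdecay = std::exp(-dt / tau_stdp);

  // inter-event relaxation factors exp(-k*dt/tau) tabulated over integer
  // step gaps k (the dominant cost of spike delivery); gaps beyond the
  // table fall back to exp()
  const int POWN = 4096;
  std::vector<double> pow_f(T * T * POWN), pow_r(T * T * POWN);
  for (int a_ = 0; a_ < T; ++a_)
    for (int b_ = 0; b_ < T; ++b_) {
      double tf = tm_tau_f(a_, b_), tr = tm_tau_r(a_, b_);
      double ff = (R_finite(tf) && tf > 0) ? std::exp(-dt / tf) : 1.0;
      double fr = (R_finite(tr) && tr > 0) ? std::exp(-dt / tr) : 1.0;
      double cf = 1.0, cr = 1.0;
      double *pf = &pow_f[(a_ * T + b_) * POWN];
      double *pr = &pow_r[(a_ * T + b_) * POWN];
      for (int k = 0; k < POWN; ++k) {
        pf[k] = cf; pr[k] = cr;
        cf *= ff; cr *= fr;
      }
    }

  // mutable state
  NumericVector v(n), u(n), trace(n), syn_u(nsyn), syn_x(nsyn),
      syn_last(nsyn), stim_cur(n);
  NumericMatrix g_acc(T, n);
  std::vector<std::vector<int> > ring(delay_steps);
  int pres_on = 0;
  if (state_in.isNotNull()) {
    List st(state_in);
    v = clone(as<NumericVector>(st["v"]));
    u = clone(as<NumericVector>(st["u"]));
    trace = clone(as<NumericVector>(st["trace"]));
    syn_u = clone(as<NumericVector>(st["syn_u"]));
    syn_x = clone(as<NumericVector>(st["syn_x"]));
    syn_last = clone(as<NumericVector>(st["syn_last"]));
    g_acc = clone(as<NumericMatrix>(st["g_acc"]));
    stim_cur = clone(as<NumericVector>(st["stim_cur"]));
    pres_on = as<int>(st["pres_on"]);
    List pend = st["pending"];
    for (int o = 0; o < delay_steps; ++o) {
      IntegerVector p = pend[o];
      int slot = (step_begin + o) % delay_steps;
      ring[slot] = std::vector<int>(p.begin(), p.end());
    }
  } else {
    for (int i = 0; i < n; ++i) { v[i] = nvr[i]; u[i] = 0.0; }
    for (int s = 0; s < nsyn; ++s) {
      syn_u[s] = 0.0; syn_x[s] = 1.0; syn_last[s] = -1.0;
    }
  }

  std::vector<int> spike_step, spike_neuron, spiking;
  spiking.reserve(256);
  const int n_rec = record_v_idx.size();
  NumericMatrix v_rec(n_rec > 0 ? (step_end - step_begin) : 0, n_rec);
  std::vector<int> rec_slot(n, -1);
  for (int r = 0; r < n_rec; ++r) rec_slot[record_v_idx[r]] = r;

  int i_stim = 0, i_forced = 0, i_pres = 0;
  const int n_stim = stim_delta.nrow(), n_forced = forced.nrow(),
      n_presd = pres_delta.nrow();
  std::vector<char> is_forced(n, 0);

  for (int t = step_begin; t < step_end; ++t) {
    // scheduled current steps and forced spikes becoming active at t
    while (i_stim < n_stim && (int)stim_delta(i_stim, 0) == t) {
      stim_cur[(int)stim_delta(i_stim, 1)] += stim_delta(i_stim, 2);
      ++i_stim;
    }
    int forced_from = i_forced;
    while (i_forced < n_forced && (int)forced(i_forced, 0) == t) {
      is_forced[(int)forced(i_forced, 1)] = 1;
      ++i_forced;
    }
    while (i_pres < n_presd && (int)pres_delta(i_pres, 0) == t) {
      pres_on += (int)pres_delta(i_pres, 1);
      ++i_pres;
    }

    // decay conductance accumulators and STDP traces
    for (int pt = 0; pt < T; ++pt)
      for (int ty = 0; ty < T; ++ty) {
        double f = gdecay[pt * T + ty];
        if (f == 1.0) continue;
        for (int i = blk_begin[ty]; i < blk_end[ty]; ++i)
          g_acc(pt, i) *= f;
      }
    for (int i = 0; i < n; ++i) trace[i] *= trdecay;

    // deliver spikes arriving at t (emitted delay_steps ago)
    {
      int slot = t % delay_steps;
      std::vector<int> &arr = ring[slot];
      for (size_t a_ = 0; a_ < arr.size(); ++a_) {
        int j = arr[a_];
        int tj = ntype[j];
        for (int c = out_off[j]; c < out_off[j + 1]; ++c) {
          int s = out_idx[c];
          int pk = syn_post[s];
          int tk = ntype[pk];
          double U = tm_U(tj, tk);
          double uu, xx;
          if (syn_last[s] >= 0.0) {
            double gap = t - syn_last[s];
            double rf, rr;
            if (gap < POWN) {
              int gi = (int)gap;
              rf = pow_f[(tj * T + tk) * POWN + gi];
              rr = pow_r[(tj * T + tk) * POWN + gi];
            } else {
              double el = gap * dt;
              rf = std::exp(-el / tm_tau_f(tj, tk));
              rr = std::exp(-el / tm_tau_r(tj, tk));
            }
            uu = syn_u[s] * rf;
            xx = 1.0 - (1.0 - syn_x[s]) * rr;
          } else { uu = 0.0; xx = 1.0; }
          double uplus = uu + U * (1.0 - uu);
          g_acc(tj, pk) += syn_w[s] * tm_g(tj, tk) * uplus * xx;
          syn_x[s] = xx - uplus * xx;
          syn_u[s] = uplus;
          syn_last[s] = t;
        }
      }
      arr.clear();
    }

    // integrate all neurons (RK4, currents frozen at step start)
    spiking.clear();
    int bgi = t / bg_interval_steps;
    if (bgi >= I_base.ncol()) bgi = I_base.ncol() - 1;
    for (int i = 0; i < n; ++i) {
      double I = (pres_on > 0 ? I_pres(i, bgi) : I_base(i, bgi)) +
          stim_cur[i];
      double vi = v[i];
      for (int pt = 0; pt < T; ++pt) {
        double g = g_acc(pt, i);
        if (g != 0.0) I += g * ((type_exc[pt] ? E_exc : E_inh) - vi);
      }
      double C = nC[i], k = nk[i], vr = nvr[i], vt = nvt[i], a = na[i],
          b = nb[i];
      double ui = u[i];
      double k1v, k1u, k2v, k2u, k3v, k3u, k4v, k4u;
      izh_deriv(vi, ui, C, k, vr, vt, a, b, I, k1v, k1u);
      izh_deriv(vi + 0.5 * dt * k1v, ui + 0.5 * dt * k1u, C, k, vr, vt, a, b,
                I, k2v, k2u);
      izh_deriv(vi + 0.5 * dt * k2v, ui + 0.5 * dt * k2u, C, k, vr, vt, a, b,
                I, k3v, k3u);
      izh_deriv(vi + dt * k3v, ui + dt * k3u, C, k, vr, vt, a, b, I, k4v,
                k4u);
      double vn = vi + dt / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
      double un = ui + dt / 6.0 * (k1u + 2.0 * k2u + 2.0 * k3u + k4u);
      if (!R_finite(vn) || !R_finite(un))
        stop("non-finite dynamics at step %d (t = %.1f ms), neuron %d",
             t, t * dt, i + 1);
      bool sp = (vn >= nvpeak[i]) || is_forced[i];
      if (n_rec > 0 && rec_slot[i] >= 0)
        v_rec(t - step_begin, rec_slot[i]) = sp ? nvpeak[i] : vn;
      if (sp) {
        vn = nvmin[i];
        un += nd[i];
        spiking.push_back(i);
      }
      v[i] = vn;
      u[i] = un;
    }
    for (int f = forced_from; f < i_forced; ++f)
      is_forced[(int)forced(f, 1)] = 0;

    // record spikes, apply STDP, queue deliveries
    for (size_t a_ = 0; a_ < spiking.size(); ++a_) {
      int i = spiking[a_];
      spike_step.push_back(t);
      spike_neuron.push_back(i);
      if (plastic_on && A > 0.0) {
        for (int c = pl_out_off[i]; c < pl_out_off[i + 1]; ++c) {
          int s = pl_out_idx[c];
          double w = syn_w[s] + A * trace[syn_post[s]];
          syn_w[s] = w < w_min ? w_min : (w > w_max ? w_max : w);
        }
        for (int c = pl_in_off[i]; c < pl_in_off[i + 1]; ++c) {
          int s = pl_in_idx[c];
          double w = syn_w[s] + A * trace[syn_pre[s]];
          syn_w[s] = w < w_min ? w_min : (w > w_max ? w_max : w);
        }
      }
      trace[i] += 1.0;
      ring[(t + delay_steps) % delay_steps].push_back(i);
    }
  }

  // export pending deliveries for steps step_end .. step_end + delay - 1
  List pending(delay_steps);
  for (int o = 0; o < delay_steps; ++o) {
    std::vector<int> &slot = ring[(step_end + o) % delay_steps];
    pending[o] = IntegerVector(slot.begin(), slot.end());
  }

  List state = List::create(
      _["v"] = v, _["u"] = u, _["trace"] = trace, _["syn_u"] = syn_u,
      _["syn_x"] = syn_x, _["syn_last"] = syn_last, _["g_acc"] = g_acc,
      _["stim_cur"] = stim_cur, _["pres_on"] = pres_on,
      _["pending"] = pending, _["next_step"] = step_end,
      _["weights"] = syn_w);

  return List::create(
      _["spike_step"] = IntegerVector(spike_step.begin(), spike_step.end()),
      _["spike_neuron"] =
          IntegerVector(spike_neuron.begin(), spike_neuron.end()),
      _["weights"] = syn_w, _["state"] = state, _["v_rec"] = v_rec);
}
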