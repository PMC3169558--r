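// Network integrator for the two-field model: somatic Izhikevich lattice,
// dendritic Morris-Lecar lattice with truncated after-hyperpolarization,
// first-order synaptic drive, and one global inhibitory unit.
//
// The full continuous state (v, u, V, w, S) is advanced with classical RK4;
// the inhibitory potential, external currents (noise held constant within a
// step) and the dendro-somatic adjacency are frozen during each step, then
// spike resets, synaptic increments, inhibitory increments and dendritic
// truncation are applied at the step boundary.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// parameter vector layouts (kept in step with the R wrappers in R/simulate.R)
// soma_par:  a, b, c, d, v_peak, E_inh
// dend_par:  C_d, g_Ca, g_K, g_L, V_Ca, V_K, V_L, V1, V2, V3, V4,
//            tau_d, kappa, tau_syn, g_syn, E_syn, V_rest, w_rest
// inh_par:   tau_I, drive_gain, g_I

struct DendPar {
  double C_d, g_Ca, g_K, g_L, V_Ca, V_K, V_L, V1, V2, V3, V4;
  double tau_d, kappa, tau_syn, g_syn, E_syn, V_rest, w_rest;
};

static DendPar unpack_dend(const NumericVector& p) {
  DendPar d;
  d.C_d = p[0]; d.g_Ca = p[1]; d.g_K = p[2]; d.g_L = p[3];
  d.V_Ca = p[4]; d.V_K = p[5]; d.V_L = p[6];
  d.V1 = p[7]; d.V2 = p[8]; d.V3 = p[9]; d.V4 = p[10];
  d.tau_d = p[11]; d.kappa = p[12]; d.tau_syn = p[13];
  d.g_syn = p[14]; d.E_syn = p[15]; d.V_rest = p[16]; d.w_rest = p[17];
  return d;
}

static inline double m_inf(double V, const DendPar& p) {
  return 0.5 * (1.0 + std::tanh((V - p.V1) / p.V2));
}
static inline double w_inf(double V, const DendPar& p) {
  return 0.5 * (1.0 + std::tanh((V - p.V3) / p.V4));
}
static inline double lam(double V, const DendPar& p) {
  return std::cosh((V - p.V3) / (2.0 * p.V4));
}

static inline double dend_dV(double V, double w, double S, double Iext,
                             const DendPar& p) {
  return (-p.g_Ca * m_inf(V, p) * (V - p.V_Ca)
          - p.g_K * w * (V - p.V_K)
          - p.g_L * (V - p.V_L)
          + p.g_syn * S * (p.E_syn - p.kappa * V)
          + Iext) / p.C_d;
}
static inline double dend_dw(double V, double w, const DendPar& p) {
  return lam(V, p) * (w_inf(V, p) - w) / p.tau_d;
}

// Segment table layout (built by compile_protocol() in R): one row per
// segment, columns t0, t1, kind (0 constant, 1 white noise), amplitude,
// sd_sample (noise sd per dt sample); idx holds 0-based unit indices.
struct SegTab {
  NumericMatrix tab;          // n_seg x 5
  std::vector<IntegerVector> idx;
};

static SegTab build_segtab(List segs) {
  SegTab s;
  int n = segs.size();
  s.tab = NumericMatrix(n, 5);
  for (int i = 0; i < n; ++i) {
    List sg = segs[i];
    s.tab(i, 0) = as<double>(sg["t0"]);
    s.tab(i, 1) = as<double>(sg["t1"]);
    s.tab(i, 2) = as<double>(sg["kind"]);
    s.tab(i, 3) = as<double>(sg["amp"]);
    s.tab(i, 4) = as<double>(sg["sd_sample"]);
    s.idx.push_back(as<IntegerVector>(sg["idx"]));
  }
  return s;
}

static void fill_current(std::vector<double>& I, const SegTab& s, double t) {
  std::fill(I.begin(), I.end(), 0.0);
  int n = s.tab.nrow();
  for (int k = 0; k < n; ++k) {
    if (t < s.tab(k, 0) || t >= s.tab(k, 1)) continue;
    const IntegerVector& id = s.idx[k];
    int kind = (int) s.tab(k, 2);
    if (kind == 0) {
      double a = s.tab(k, 3);
      for (int j = 0; j < id.size(); ++j) I[id[j]] += a;
    } else {
      double sd = s.tab(k, 4);
      for (int j = 0; j < id.size(); ++j) I[id[j]] += sd * norm_rand();
    }
  }
}

// [[Rcpp::export]]
List sim_network_cpp(int n_soma, int n_dend,
                     IntegerVector axon_ptr, IntegerVector axon_idx,
                     IntegerVector branch_ptr, IntegerVector branch_idx,
                     NumericVector soma_par, NumericVector dend_par,
                     NumericVector inh_par, double g_ds,
                     List seg_soma, List seg_dend,
                     double t_start, double duration, double dt,
                     NumericVector v0, NumericVector u0,
                     NumericVector V0, NumericVector w0,
                     NumericVector S0, double VI0,
                     double snapshot_dt,
                     IntegerVector trace_soma, IntegerVector trace_dend) {
  const double a = soma_par[0], b = soma_par[1], creset = soma_par[2],
               dinc = soma_par[3], v_peak = soma_par[4], E_inh = soma_par[5];
  const DendPar dp = unpack_dend(dend_par);
  const double tau_I = inh_par[0], drive_gain = inh_par[1], g_I = inh_par[2];

  const int n_steps = (int) std::lround(duration / dt);
  const int snap_every = snapshot_dt > 0 ? (int) std::lround(snapshot_dt / dt) : 0;
  const int n_snap = snap_every > 0 ? n_steps / snap_every : 0;

  std::vector<double> v(v0.begin(), v0.end()), u(u0.begin(), u0.end());
  std::vector<double> V(V0.begin(), V0.end()), w(w0.begin(), w0.end());
  std::vector<double> S(S0.begin(), S0.end());
  double VI = VI0;

  SegTab ss = build_segtab(seg_soma), sd = build_segtab(seg_dend);
  std::vector<double> Is(n_soma), Id(n_dend);

  // RK4 work space
  std::vector<double> kv(n_soma), ku(n_soma), kV(n_dend), kw(n_dend), kS(n_dend);
  std::vector<double> av(n_soma), au(n_soma), aV(n_dend), aw(n_dend), aS(n_dend);
  std::vector<double> tv(n_soma), tu(n_soma), tV(n_dend), tw(n_dend), tS(n_dend);

  std::vector<double> sp_t; std::vector<int> sp_i;
  NumericMatrix snap_u(n_snap, n_soma), snap_V(n_snap, n_dend),
                snap_w(n_snap, n_dend);
  NumericVector snap_t(n_snap);
  int n_ts = trace_soma.size(), n_td = trace_dend.size();
  NumericMatrix tr_v(n_steps, n_ts), tr_u(n_steps, n_ts),
                tr_V(n_steps, n_td), tr_w(n_steps, n_td), tr_S(n_steps, n_td);
  NumericVector tr_VI(n_steps), tr_t(n_steps);

  const double decay_VI = std::exp(-dt / tau_I);

  for (int step = 0; step < n_steps; ++step) {
    double t = t_start + step * dt;
    fill_current(Is, ss, t);
    fill_current(Id, sd, t);
    double G_inh = g_I * std::max(VI, 0.0);

    // one RHS evaluation at state (xv,xu,xV,xw,xS) -> (kv,ku,kV,kw,kS)
    auto rhs = [&](const std::vector<double>& xv, const std::vector<double>& xu,
                   const std::vector<double>& xV, const std::vector<double>& xw,
                   const std::vector<double>& xS) {
      for (int j = 0; j < n_dend; ++j) {
        kV[j] = dend_dV(xV[j], xw[j], xS[j], Id[j], dp);
        kw[j] = dend_dw(xV[j], xw[j], dp);
        kS[j] = -xS[j] / dp.tau_syn;
      }
      for (int i = 0; i < n_soma; ++i) {
        double sumV = 0.0; int p0 = branch_ptr[i], p1 = branch_ptr[i + 1];
        for (int k = p0; k < p1; ++k) sumV += xV[branch_idx[k]];
        double ID = g_ds * (dp.kappa * sumV - (p1 - p0) * xv[i]);
        kv[i] = 0.04 * xv[i] * xv[i] + 5.0 * xv[i] + 140.0 - xu[i]
                + ID + Is[i] - G_inh * (xv[i] - E_inh);
        ku[i] = a * (b * xv[i] - xu[i]);
      }
    };

    // RK4
    rhs(v, u, V, w, S);
    for (int i = 0; i < n_soma; ++i) { av[i] = kv[i]; au[i] = ku[i];
      tv[i] = v[i] + 0.5 * dt * kv[i]; tu[i] = u[i] + 0.5 * dt * ku[i]; }
    for (int j = 0; j < n_dend; ++j) { aV[j] = kV[j]; aw[j] = kw[j]; aS[j] = kS[j];
      tV[j] = V[j] + 0.5 * dt * kV[j]; tw[j] = w[j] + 0.5 * dt * kw[j];
      tS[j] = S[j] + 0.5 * dt * kS[j]; }
    rhs(tv, tu, tV, tw, tS);
    for (int i = 0; i < n_soma; ++i) { av[i] += 2.0 * kv[i]; au[i] += 2.0 * ku[i];
      tv[i] = v[i] + 0.5 * dt * kv[i]; tu[i] = u[i] + 0.5 * dt * ku[i]; }
    for (int j = 0; j < n_dend; ++j) { aV[j] += 2.0 * kV[j]; aw[j] += 2.0 * kw[j];
      aS[j] += 2.0 * kS[j];
      tV[j] = V[j] + 0.5 * dt * kV[j]; tw[j] = w[j] + 0.5 * dt * kw[j];
      tS[j] = S[j] + 0.5 * dt * kS[j]; }
    rhs(tv, tu, tV, tw, tS);
    for (int i = 0; i < n_soma; ++i) { av[i] += 2.0 * kv[i]; au[i] += 2.0 * ku[i];
      tv[i] = v[i] + dt * kv[i]; tu[i] = u[i] + dt * ku[i]; }
    for (int j = 0; j < n_dend; ++j) { aV[j] += 2.0 * kV[j]; aw[j] += 2.0 * kw[j];
      aS[j] += 2.0 * kS[j];
      tV[j] = V[j] + dt * kV[j]; tw[j] = w[j] + dt * kw[j];
      tS[j] = S[j] + dt * kS[j]; }
    rhs(tv, tu, tV, tw, tS);
    for (int i = 0; i < n_soma; ++i) {
      v[i] += dt / 6.0 * (av[i] + kv[i]);
      u[i] += dt / 6.0 * (au[i] + ku[i]);
    }
    for (int j = 0; j < n_dend; ++j) {
      V[j] += dt / 6.0 * (aV[j] + kV[j]);
      w[j] += dt / 6.0 * (aw[j] + kw[j]);
      S[j] += dt / 6.0 * (aS[j] + kS[j]);
    }

    VI *= decay_VI;
    double t_next = t + dt;

    // spike detection, reset, synaptic and inhibitory increments
    int nsp = 0;
    for (int i = 0; i < n_soma; ++i) {
      if (v[i] >= v_peak) {
        sp_t.push_back(t_next); sp_i.push_back(i + 1);
        v[i] = creset; u[i] += dinc; ++nsp;
        for (int k = axon_ptr[i]; k < axon_ptr[i + 1]; ++k) S[axon_idx[k]] += 1.0;
      }
      if (!std::isfinite(v[i]) || std::fabs(v[i]) > 1e3)
        stop("numerical divergence at t=%.3f ms (|v| > 1e3 mV); reduce dt (%g ms) or input amplitudes", t_next, dt);
    }
    VI += drive_gain * nsp;

    // truncate dendritic after-hyperpolarization
    for (int j = 0; j < n_dend; ++j) {
      if (V[j] < dp.V_rest) { V[j] = dp.V_rest; w[j] = dp.w_rest; }
    }

    if (snap_every > 0 && (step + 1) % snap_every == 0) {
      int k = (step + 1) / snap_every - 1;
      snap_t[k] = t_next;
      for (int i = 0; i < n_soma; ++i) snap_u(k, i) = u[i];
      for (int j = 0; j < n_dend; ++j) { snap_V(k, j) = V[j]; snap_w(k, j) = w[j]; }
    }
    tr_t[step] = t_next; tr_VI[step] = VI;
    for (int k = 0; k < n_ts; ++k) { tr_v(step, k) = v[trace_soma[k]];
      tr_u(step, k) = u[trace_soma[k]]; }
    for (int k = 0; k < n_td; ++k) { tr_V(step, k) = V[trace_dend[k]];
      tr_w(step, k) = w[trace_dend[k]]; tr_S(step, k) = S[trace_dend[k]]; }
  }

  return List::create(
    _["spike_time"] = NumericVector(sp_t.begin(), sp_t.end()),
    _["spike_unit"] = IntegerVector(sp_i.begin(), sp_i.end()),
    _["state"] = List::create(_["v"] = NumericVector(v.begin(), v.end()),
                              _["u"] = NumericVector(u.begin(), u.end()),
                              _["V"] = NumericVector(V.begin(), V.end()),
                              _["w"] = NumericVector(w.begin(), w.end()),
                              _["S"] = NumericVector(S.begin(), S.end()),
                              _["V_I"] = VI,
                              _["t"] = t_start + n_steps * dt),
    _["snap_t"] = snap_t, _["snap_u"] = snap_u,
    _["snap_V"] = snap_V, _["snap_w"] = snap_w,
    _["trace_t"] = tr_t, _["trace_VI"] = tr_VI,
    _["trace_v"] = tr_v, _["trace_u"] = tr_u,
    _["trace_V"] = tr_V, _["trace_w"] = tr_w, _["trace_S"] = tr_S);
}

// Single isolated dendritic unit driven by a square current pulse and/or an
// initial synaptic drive; used for plateau threshold and duration studies.
// [[Rcpp::export]]
List sim_dendrite_cpp(NumericVector dend_par, double duration, double dt,
                      double pulse_amp, double pulse_t0, double pulse_t1,
                      double S_init) {
  const DendPar dp = unpack_dend(dend_par);
  const int n_steps = (int) std::lround(duration / dt);
  double V = dp.V_rest, w = dp.w_rest, S = S_init;
  NumericVector tt(n_steps), VV(n_steps), ww(n_steps), SS(n_steps);
  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    double I = (t >= pulse_t0 && t < pulse_t1) ? pulse_amp : 0.0;
    double k1V = dend_dV(V, w, S, I, dp), k1w = dend_dw(V, w, dp), k1S = -S / dp.tau_syn;
    double V2 = V + 0.5 * dt * k1V, w2 = w + 0.5 * dt * k1w, S2 = S + 0.5 * dt * k1S;
    double k2V = dend_dV(V2, w2, S2, I, dp), k2w = dend_dw(V2, w2, dp), k2S = -S2 / dp.tau_syn;
    double V3 = V + 0.5 * dt * k2V, w3 = w + 0.5 * dt * k2w, S3 = S + 0.5 * dt * k2S;
    double k3V = dend_dV(V3, w3, S3, I, dp), k3w = dend_dw(V3, w3, dp), k3S = -S3 / dp.tau_syn;
    double V4 = V + dt * k3V, w4 = w + dt * k3w, S4 = S + dt * k3S;
    double k4V = dend_dV(V4, w4, S4, I, dp), k4w = dend_dw(V4, w4, dp), k4S = -S4 / dp.tau_syn;
    V += dt / 6.0 * (k1V + 2 * k2V + 2 * k3V + k4V);
    w += dt / 6.0 * (k1w + 2 * k2w + 2 * k3w + k4w);
    S += dt / 6.0 * (k1S + 2 * k2S + 2 * k3S + k4S);
    if (V < dp.V_rest) { V = dp.V_rest; w = dp.w_rest; }
    tt[step] = t + dt; VV[step] = V; ww[step] = w; SS[step] = S;
  }
  return List::create(_["t"] = tt, _["V"] = VV, _["w"] = ww, _["S"] = SS);
}
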