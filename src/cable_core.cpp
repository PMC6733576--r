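// Compartmental cable integrator for an unbranched axon chain.
//
// Voltage update: theta-method (theta = 0.5 Crank-Nicolson, theta = 1
// backward Euler) on the cable equation; ionic currents are ohmic in V at
// fixed gate values, so each step is one tridiagonal solve (Thomas
// algorithm). Gates advance by the exact exponential update of the linear
// gate ODE at the pre-step voltage. Membrane pathways are kept separate
// (NaV, KV, Na leak, K leak, HCN-Na, HCN-K) so that Na charge influx can
// be decomposed for ATP accounting.
//
// Units: mV, ms, pF, nS, pA (nS * mV = pA); charge integrals in pA*ms (fC).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double gate_relax(double x, double xinf, double dt, double tau) {
  return xinf + (x - xinf) * std::exp(-dt / tau);
}

// [[Rcpp::export]]
List cable_integrate_cpp(
    NumericVector cm,          // pF per segment
    NumericVector g_nav, NumericVector g_kv,
    NumericVector g_leak_na, NumericVector g_leak_k,
    NumericVector g_hcn_na, NumericVector g_hcn_k,   // nS per segment
    double e_na, double e_k,
    NumericVector hcn_par,     // A (1/ms), v_half, v_alpha, v_beta
    NumericVector nav_m_par,   // vh, k, tau_min, tau_amp, tau_vh, tau_k
    NumericVector nav_h_par,   // vh, k, tau_min, tau_amp, tau_vh, tau_k
    NumericVector kv_n_par,    // vh, k, tau_min, tau_amp, tau_vh, tau_k
    double kv_power,
    NumericVector g_axial,     // nS, between segment i and i+1 (n-1)
    NumericVector v0,
    NumericMatrix gates0,      // n x 4: m_hcn, nav_m, nav_h, kv_n
    double dt, int n_steps, double theta,
    NumericMatrix stim,        // rows: seg (1-based), t_on, t_off, amp (pA)
    IntegerVector record_idx,  // 1-based
    LogicalVector chain_mask,
    bool record_pathways) {

  const int n = cm.size();
  const int nrec = record_idx.size();
  const int NPATH = 7;  // nav kv leak_na leak_k hcn_na hcn_k stim

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> mh(n), mna(n), hna(n), nk(n);
  for (int i = 0; i < n; ++i) {
    mh[i] = gates0(i, 0); mna[i] = gates0(i, 1);
    hna[i] = gates0(i, 2); nk[i] = gates0(i, 3);
  }

  const double hA = hcn_par[0], hvh = hcn_par[1],
               hva = hcn_par[2], hvb = hcn_par[3];

  NumericMatrix vm(n_steps + 1, nrec);
  NumericVector tgrid(n_steps + 1);
  for (int r = 0; r < nrec; ++r) vm(0, r) = v[record_idx[r] - 1];

  NumericMatrix charge_seg(n, NPATH);
  NumericMatrix path_chain, path_wm;
  if (record_pathways) {
    path_chain = NumericMatrix(n_steps, NPATH);
    path_wm = NumericMatrix(n_steps, NPATH);
  }

  std::vector<double> a_lo(n), a_di(n), a_up(n), rhs(n), gtot(n), ssum(n);
  std::vector<double> cp(n), dp(n);

  bool diverged = false; double t_fail = NA_REAL;

  for (int s = 0; s < n_steps; ++s) {
    const double t0 = s * dt;

    // --- gate update (exponential, at pre-step voltage) ---
    for (int i = 0; i < n; ++i) {
      const double V = v[i];
      if (g_hcn_na[i] + g_hcn_k[i] > 0.0) {
        const double al = hA * std::exp(-(V - hvh) / hva);
        const double be = hA * std::exp((V - hvh) / hvb);
        mh[i] = gate_relax(mh[i], al / (al + be), dt, 1.0 / (al + be));
      }
      if (g_nav[i] > 0.0) {
        const double minf = 1.0 / (1.0 + std::exp(-(V - nav_m_par[0]) / nav_m_par[1]));
        const double tm = nav_m_par[2] + nav_m_par[3] /
          std::cosh((V - nav_m_par[4]) / nav_m_par[5]);
        mna[i] = gate_relax(mna[i], minf, dt, tm);
        const double hinf = 1.0 / (1.0 + std::exp((V - nav_h_par[0]) / nav_h_par[1]));
        const double th = nav_h_par[2] + nav_h_par[3] /
          std::cosh((V - nav_h_par[4]) / nav_h_par[5]);
        hna[i] = gate_relax(hna[i], hinf, dt, th);
      }
      if (g_kv[i] > 0.0) {
        const double ninf = 1.0 / (1.0 + std::exp(-(V - kv_n_par[0]) / kv_n_par[1]));
        const double tn = kv_n_par[2] + kv_n_par[3] /
          std::cosh((V - kv_n_par[4]) / kv_n_par[5]);
        nk[i] = gate_relax(nk[i], ninf, dt, tn);
      }
    }

    // --- assemble tridiagonal system ---
    for (int i = 0; i < n; ++i) {
      const double gna_v = g_nav[i] * mna[i] * mna[i] * mna[i] * hna[i];
      const double gkv_v = g_kv[i] * std::pow(nk[i], kv_power);
      const double ghn = g_hcn_na[i] * mh[i];
      const double ghk = g_hcn_k[i] * mh[i];
      gtot[i] = gna_v + gkv_v + g_leak_na[i] + g_leak_k[i] + ghn + ghk;
      ssum[i] = (gna_v + g_leak_na[i] + ghn) * e_na +
                (gkv_v + g_leak_k[i] + ghk) * e_k;
    }

    for (int i = 0; i < n; ++i) {
      double ga = 0.0, ax_flux = 0.0;
      if (i > 0)     { ga += g_axial[i - 1]; ax_flux += g_axial[i - 1] * (v[i - 1] - v[i]); }
      if (i < n - 1) { ga += g_axial[i];     ax_flux += g_axial[i] * (v[i + 1] - v[i]); }
      a_di[i] = cm[i] / dt + theta * (gtot[i] + ga);
      a_lo[i] = (i > 0) ? -theta * g_axial[i - 1] : 0.0;
      a_up[i] = (i < n - 1) ? -theta * g_axial[i] : 0.0;
      rhs[i] = cm[i] / dt * v[i] + ssum[i] - (1.0 - theta) * gtot[i] * v[i] +
               (1.0 - theta) * ax_flux;
    }

    // stimulus currents: exact overlap of [t0, t0+dt] with [on, off] so the
    // delivered charge is independent of the step size
    for (int k = 0; k < stim.nrow(); ++k) {
      const double ov = std::max(0.0,
        std::min(t0 + dt, stim(k, 2)) - std::max(t0, stim(k, 1)));
      if (ov > 0.0) rhs[(int)stim(k, 0) - 1] += stim(k, 3) * ov / dt;
    }

    // --- Thomas solve ---
    cp[0] = a_up[0] / a_di[0];
    dp[0] = rhs[0] / a_di[0];
    for (int i = 1; i < n; ++i) {
      const double m = a_di[i] - a_lo[i] * cp[i - 1];
      cp[i] = a_up[i] / m;
      dp[i] = (rhs[i] - a_lo[i] * dp[i - 1]) / m;
    }
    std::vector<double> vnew(n);
    vnew[n - 1] = dp[n - 1];
    for (int i = n - 2; i >= 0; --i) vnew[i] = dp[i] - cp[i] * vnew[i + 1];

    // --- record pathway currents at the midpoint voltage ---
    double acc_chain[NPATH] = {0, 0, 0, 0, 0, 0, 0};
    double acc_wm[NPATH] = {0, 0, 0, 0, 0, 0, 0};
    for (int i = 0; i < n; ++i) {
      const double vmid = theta * vnew[i] + (1.0 - theta) * v[i];
      const double gna_v = g_nav[i] * mna[i] * mna[i] * mna[i] * hna[i];
      const double gkv_v = g_kv[i] * std::pow(nk[i], kv_power);
      double ipath[NPATH];
      ipath[0] = gna_v * (vmid - e_na);
      ipath[1] = gkv_v * (vmid - e_k);
      ipath[2] = g_leak_na[i] * (vmid - e_na);
      ipath[3] = g_leak_k[i] * (vmid - e_k);
      ipath[4] = g_hcn_na[i] * mh[i] * (vmid - e_na);
      ipath[5] = g_hcn_k[i] * mh[i] * (vmid - e_k);
      ipath[6] = 0.0;
      for (int p = 0; p < 6; ++p) {
        charge_seg(i, p) += ipath[p] * dt;
        if (record_pathways) {
          if (chain_mask[i]) acc_chain[p] += ipath[p];
          else acc_wm[p] += ipath[p];
        }
      }
    }
    for (int k = 0; k < stim.nrow(); ++k) {
      const double ov = std::max(0.0,
        std::min(t0 + dt, stim(k, 2)) - std::max(t0, stim(k, 1)));
      if (ov > 0.0) {
        const int i = (int)stim(k, 0) - 1;
        charge_seg(i, 6) += stim(k, 3) * ov;
        if (record_pathways) {
          if (chain_mask[i]) acc_chain[6] += stim(k, 3) * ov / dt;
          else acc_wm[6] += stim(k, 3) * ov / dt;
        }
      }
    }
    if (record_pathways) {
      for (int p = 0; p < NPATH; ++p) {
        path_chain(s, p) = acc_chain[p];
        path_wm(s, p) = acc_wm[p];
      }
    }

    v.swap(vnew);
    tgrid[s + 1] = (s + 1) * dt;
    for (int r = 0; r < nrec; ++r) vm(s + 1, r) = v[record_idx[r] - 1];

    bool bad = false;
    for (int i = 0; i < n; ++i)
      if (!std::isfinite(v[i]) || std::fabs(v[i]) > 2000.0) { bad = true; break; }
    if (bad) { diverged = true; t_fail = (s + 1) * dt; break; }
  }

  NumericVector v_final(n);
  NumericMatrix gates_final(n, 4);
  for (int i = 0; i < n; ++i) {
    v_final[i] = v[i];
    gates_final(i, 0) = mh[i]; gates_final(i, 1) = mna[i];
    gates_final(i, 2) = hna[i]; gates_final(i, 3) = nk[i];
  }

  return List::create(
    _["t"] = tgrid, _["vm"] = vm,
    _["v_final"] = v_final, _["gates_final"] = gates_final,
    _["charge_seg"] = charge_seg,
    _["path_chain"] = path_chain, _["path_wm"] = path_wm,
    _["diverged"] = diverged, _["t_fail"] = t_fail);
}
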