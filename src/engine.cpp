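// Double-cable integrator: axolemma + myelin sheath per compartment, with a
// longitudinal peri-axonal electrical pathway, Rush-Larsen gate updates and a
// semi-implicit (backward Euler) tridiagonal solve for peri-axonal [K+]o.
//
// Unknowns per time step are absolute intracellular potentials (all
// compartments) and absolute peri-axonal potentials (myelinated
// compartments), interleaved along the axon so the implicit system is banded
// with half-bandwidth 2.  The extracellular potential phi(t) from the point
// source is a known forcing: nodes face phi directly (negligible shell
// resistance); myelinated compartments face it through the myelin RC layer.
//
// Units: mV, ms, nA, uS, nF, um, um^2, um^3, mM.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double FARADAY = 96485.33212;

struct Gate {
  double vhalf, slope, tau_min, tau_amp, tau_vhalf, tau_slope, expo;
};

static inline double gate_inf(const Gate& g, double V) {
  return 1.0 / (1.0 + std::exp(-(V - g.vhalf) / g.slope));
}
static inline double gate_tau(const Gate& g, double V) {
  return g.tau_min + g.tau_amp / std::cosh((V - g.tau_vhalf) / g.tau_slope);
}
static inline double gpow(double x, double p) {
  if (p == 1.0) return x;
  if (p == 3.0) return x * x * x;
  if (p == 4.0) { double x2 = x * x; return x2 * x2; }
  if (p == 6.0) { double x2 = x * x; return x2 * x2 * x2; }
  return std::pow(x, p);
}

static Gate as_gate(List g) {
  Gate out;
  out.vhalf = g["vhalf"]; out.slope = g["slope"];
  out.tau_min = g["tau_min"]; out.tau_amp = g["tau_amp"];
  out.tau_vhalf = g["tau_vhalf"]; out.tau_slope = g["tau_slope"];
  out.expo = g["exponent"];
  return out;
}

// Banded LU solve, half-bandwidth 2, no pivoting (rows are diagonally
// dominant for backward-Euler cable systems).  B is row-major n x 5 with
// B[i][j - i + 2] = A(i, j).
static void band_solve(std::vector<double>& B, std::vector<double>& rhs,
                       int n) {
  double* b = B.data();
  double* r = rhs.data();
  for (int k = 0; k < n - 1; ++k) {
    const double piv = b[5 * k + 2];
    const double b3 = b[5 * k + 3], b4 = b[5 * k + 4], rk = r[k];
    {                                   // row k+1 (col k at offset 1)
      const double f = b[5 * (k + 1) + 1] / piv;
      if (f != 0.0) {
        b[5 * (k + 1) + 2] -= f * b3;
        b[5 * (k + 1) + 3] -= f * b4;
        r[k + 1] -= f * rk;
      }
    }
    if (k + 2 < n) {                    // row k+2 (col k at offset 0)
      const double f = b[5 * (k + 2)] / piv;
      if (f != 0.0) {
        b[5 * (k + 2) + 1] -= f * b3;
        b[5 * (k + 2) + 2] -= f * b4;
        r[k + 2] -= f * rk;
      }
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = r[i];
    if (i + 1 < n) s -= b[5 * i + 3] * r[i + 1];
    if (i + 2 < n) s -= b[5 * i + 4] * r[i + 2];
    r[i] = s / b[5 * i + 2];
  }
}

struct Model {
  int n;
  std::vector<int> kind;              // 0 NODE, 1 PNJ, 2 JXP, 3 IND
  std::vector<double> cm_ax, cm_my, g_my, g_lk, gna, gkm, gkf;
  std::vector<double> area_um2, vol_um3;
  std::vector<double> g_ax, g_pax;    // length n-1 (link i <-> i+1)
  std::vector<double> g_diff;         // um^3/ms, length n-1
  std::vector<double> g_bath;         // um^3/ms, per compartment (0 off-node)
  std::vector<double> phi_unit;       // mV during a pulse, per compartment
  std::vector<double> ibal;           // balancing current, nA
  Gate gm, gh, gkmn, gkfn;
  double ELk, ENa, inakmax, kmk, kmna, nai, ki, bath, RTF, theta;
  double pump_pref;   // I_NaKmax x (constant Na saturation factor)
  bool fixed_ko;
  std::vector<int> iV, iP;            // unknown indices; iP = -1 at nodes
  int nun;
  std::vector<int> act_na, act_kf;    // node / JXP compartment lists
};

struct State {
  std::vector<double> Vm, Vp, m, h, nkm, nkf, ko, EK;
  double t;
};

static inline double pump_density(const Model& M, double ko, double V) {
  return M.pump_pref * (ko / (ko + M.kmk)) *
         ((V + 150.0) / (V + 200.0));
}

// One implicit theta-scheme electrical step of size dt with stimulus scale
// s (0/1).  theta = 1 is backward Euler; theta = 0.5 is Crank-Nicolson
// (second order).  Membrane voltages Vm/Vp are the true state; absolute
// potentials are reconstructed with the CURRENT stimulus value, so the
// discontinuity at a pulse edge is treated as happening at the step start
// (steps are aligned to pulse edges).
static void electrical_step(const Model& M, State& S, double dt, double s,
                            std::vector<double>& B, std::vector<double>& rhs,
                            std::vector<double>& ipump_nA,
                            std::vector<double>& PhiI,
                            std::vector<double>& PhiP) {
  const int n = M.n;
  const double th = M.theta, om = 1.0 - M.theta;
  std::fill(B.begin(), B.end(), 0.0);
  std::fill(rhs.begin(), rhs.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    const double phe = s * M.phi_unit[i];
    PhiP[i] = (M.iP[i] >= 0) ? S.Vp[i] + phe : phe;
    PhiI[i] = S.Vm[i] + PhiP[i];
  }

  for (int i = 0; i < n; ++i) {
    const double phe = s * M.phi_unit[i];
    const double gna_eff = M.gna[i] > 0
      ? M.gna[i] * gpow(S.m[i], M.gm.expo) * gpow(S.h[i], M.gh.expo) : 0.0;
    const double gkm_eff = M.gkm[i] > 0
      ? M.gkm[i] * gpow(S.nkm[i], M.gkmn.expo) : 0.0;
    const double gkf_eff = M.gkf[i] > 0
      ? M.gkf[i] * gpow(S.nkf[i], M.gkfn.expo) : 0.0;
    const double Gm = M.g_lk[i] + gna_eff + gkm_eff + gkf_eff;
    ipump_nA[i] = pump_density(M, S.ko[i], S.Vm[i]) * M.area_um2[i] * 1e-5;
    const double Se = M.g_lk[i] * M.ELk + gna_eff * M.ENa +
      (gkm_eff + gkf_eff) * S.EK[i] - ipump_nA[i] + M.ibal[i];
    const double a = M.cm_ax[i] / dt;
    const int u = M.iV[i];

    // axolemma row:
    //   a (Vm' - Vm) + th (Gm Vm' - Se) + om (Gm Vm - Se) + axial = 0
    B[5 * u + 2] += a + th * Gm;
    rhs[u] += a * S.Vm[i] - om * Gm * S.Vm[i] + Se;
    if (M.iP[i] >= 0) {
      B[5 * u + (M.iP[i] - u + 2)] -= a + th * Gm;
    } else {
      rhs[u] += (a + th * Gm) * phe;   // node: Vm' = Phi_i' - phi_e
    }

    // peri-axonal row (myelinated only): myelin RC minus axolemma current
    if (M.iP[i] >= 0) {
      const int u2 = M.iP[i];
      const double amy = M.cm_my[i] / dt;
      B[5 * u2 + 2] += amy + th * M.g_my[i] + (a + th * Gm);
      B[5 * u2 + (u - u2 + 2)] -= a + th * Gm;
      rhs[u2] += (amy + th * M.g_my[i]) * phe + amy * S.Vp[i]
                 - om * M.g_my[i] * S.Vp[i]
                 - a * S.Vm[i] + om * Gm * S.Vm[i] - Se;
    }
  }

  // axial intracellular and peri-axonal couplings (theta-weighted; the
  // explicit part enters through the old absolute potentials)
  for (int i = 0; i < n - 1; ++i) {
    const int u = M.iV[i], v = M.iV[i + 1];
    const double g = M.g_ax[i];
    const double gt = th * g;
    B[5 * u + 2] += gt; B[5 * v + 2] += gt;
    B[5 * u + (v - u + 2)] -= gt; B[5 * v + (u - v + 2)] -= gt;
    const double iold = om * g * (PhiI[i] - PhiI[i + 1]);
    rhs[u] -= iold; rhs[v] += iold;

    const double gp = M.g_pax[i];
    if (gp > 0) {
      const int pa = M.iP[i], pb = M.iP[i + 1];
      const double gpt = th * gp;
      const double pold = om * gp * (PhiP[i] - PhiP[i + 1]);
      if (pa >= 0 && pb >= 0) {
        B[5 * pa + 2] += gpt; B[5 * pb + 2] += gpt;
        B[5 * pa + (pb - pa + 2)] -= gpt; B[5 * pb + (pa - pb + 2)] -= gpt;
        rhs[pa] -= pold; rhs[pb] += pold;
      } else if (pa >= 0) {         // neighbour is a node: ground at phi_e
        B[5 * pa + 2] += gpt;
        rhs[pa] += gpt * s * M.phi_unit[i + 1] - pold;
      } else if (pb >= 0) {
        B[5 * pb + 2] += gpt;
        rhs[pb] += gpt * s * M.phi_unit[i] + pold;
      }
    }
  }

  band_solve(B, rhs, M.nun);

  for (int i = 0; i < n; ++i) {
    const double phe = s * M.phi_unit[i];
    if (M.iP[i] >= 0) {
      S.Vm[i] = rhs[M.iV[i]] - rhs[M.iP[i]];
      S.Vp[i] = rhs[M.iP[i]] - phe;
    } else {
      S.Vm[i] = rhs[M.iV[i]] - phe;
      S.Vp[i] = 0.0;
    }
    if (!std::isfinite(S.Vm[i]))
      stop("non-finite membrane potential at t = %f ms (compartment %d)",
           S.t, i + 1);
  }
}

static inline void rush_larsen(double& x, const Gate& g, double V,
                               double dt) {
  const double xi = gate_inf(g, V);
  x = xi + (x - xi) * std::exp(-dt / gate_tau(g, V));
  if (x < 0) x = 0; else if (x > 1) x = 1;
}

static void gate_step(const Model& M, State& S, double dt) {
  for (int i : M.act_na) {
    rush_larsen(S.m[i], M.gm, S.Vm[i], dt);
    rush_larsen(S.h[i], M.gh, S.Vm[i], dt);
    rush_larsen(S.nkm[i], M.gkmn, S.Vm[i], dt);
  }
  for (int i : M.act_kf) rush_larsen(S.nkf[i], M.gkfn, S.Vm[i], dt);
}

// Backward-Euler potassium step on the axial chain + bath links (Thomas
// algorithm).  Sources held fixed; step halved if positivity would fail.
struct KScratch {
  std::vector<double> sub, dia, sup, d, ko;
  explicit KScratch(int n) : sub(n), dia(n), sup(n), d(n), ko(n) {}
};

static void k_step(const Model& M, State& S,
                   const std::vector<double>& src, double dt, int depth,
                   KScratch& W) {
  const int n = M.n;
  std::vector<double>& sub = W.sub; std::vector<double>& dia = W.dia;
  std::vector<double>& sup = W.sup; std::vector<double>& d = W.d;
  std::fill(sub.begin(), sub.end(), 0.0);
  std::fill(sup.begin(), sup.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    dia[i] = M.vol_um3[i] / dt + M.g_bath[i];
    d[i] = M.vol_um3[i] / dt * S.ko[i] + M.g_bath[i] * M.bath;
    // positive sources explicit; sinks implicit (scaled by ko_new/ko_old)
    // so the update cannot cross zero
    if (src[i] >= 0) d[i] += src[i] * M.vol_um3[i];
    else dia[i] += -src[i] * M.vol_um3[i] / S.ko[i];
  }
  for (int i = 0; i < n - 1; ++i) {
    dia[i] += M.g_diff[i]; dia[i + 1] += M.g_diff[i];
    sup[i] = -M.g_diff[i]; sub[i + 1] = -M.g_diff[i];
  }
  std::vector<double>& ko = W.ko;
  for (int i = 1; i < n; ++i) {
    const double w = sub[i] / dia[i - 1];
    dia[i] -= w * sup[i - 1];
    d[i] -= w * d[i - 1];
  }
  ko[n - 1] = d[n - 1] / dia[n - 1];
  for (int i = n - 2; i >= 0; --i)
    ko[i] = (d[i] - sup[i] * ko[i + 1]) / dia[i];

  for (int i = 0; i < n; ++i) {
    if (ko[i] <= 0) {
      if (depth >= 12)
        stop("potassium positivity failure at compartment %d after maximal step reduction",
             i + 1);
      k_step(M, S, src, dt / 2, depth + 1, W);
      k_step(M, S, src, dt / 2, depth + 1, W);
      return;
    }
  }
  for (int i = 0; i < n; ++i) {
    S.ko[i] = ko[i];
    S.EK[i] = M.RTF * std::log(ko[i] / M.ki);
  }
}

static Model build_model(List ml) {
  Model M;
  M.n = as<int>(ml["n"]);
  M.kind = as<std::vector<int>>(ml["kind"]);
  M.cm_ax = as<std::vector<double>>(ml["cm_ax"]);
  M.cm_my = as<std::vector<double>>(ml["cm_my"]);
  M.g_my = as<std::vector<double>>(ml["g_my"]);
  M.g_lk = as<std::vector<double>>(ml["g_lk"]);
  M.gna = as<std::vector<double>>(ml["gna"]);
  M.gkm = as<std::vector<double>>(ml["gkm"]);
  M.gkf = as<std::vector<double>>(ml["gkf"]);
  M.area_um2 = as<std::vector<double>>(ml["area_um2"]);
  M.vol_um3 = as<std::vector<double>>(ml["vol_um3"]);
  M.g_ax = as<std::vector<double>>(ml["g_ax"]);
  M.g_pax = as<std::vector<double>>(ml["g_pax"]);
  M.g_diff = as<std::vector<double>>(ml["g_diff"]);
  M.g_bath = as<std::vector<double>>(ml["g_bath"]);
  M.phi_unit = as<std::vector<double>>(ml["phi_unit"]);
  M.ibal = as<std::vector<double>>(ml["ibal"]);
  List gates = ml["gates"];
  M.gm = as_gate(gates["m"]); M.gh = as_gate(gates["h"]);
  M.gkmn = as_gate(gates["nkm"]); M.gkfn = as_gate(gates["nkf"]);
  M.ELk = ml["ELk"]; M.ENa = ml["ENa"];
  M.inakmax = ml["inakmax"]; M.kmk = ml["kmk"]; M.kmna = ml["kmna"];
  M.nai = ml["nai"]; M.ki = ml["ki"]; M.bath = ml["bath"];
  M.RTF = ml["RTF"];
  M.theta = ml.containsElementNamed("theta") ? as<double>(ml["theta"]) : 1.0;
  M.fixed_ko = as<bool>(ml["fixed_ko"]);
  const double na32 = std::pow(M.nai, 1.5);
  M.pump_pref = M.inakmax * na32 / (na32 + std::pow(M.kmna, 1.5));

  M.iV.resize(M.n); M.iP.assign(M.n, -1);
  int u = 0;
  for (int i = 0; i < M.n; ++i) {
    M.iV[i] = u++;
    if (M.kind[i] != 0) M.iP[i] = u++;
  }
  M.nun = u;
  for (int i = 0; i < M.n; ++i) {
    if (M.gna[i] > 0 || M.gkm[i] > 0) M.act_na.push_back(i);
    if (M.gkf[i] > 0) M.act_kf.push_back(i);
  }
  return M;
}

static State build_state(List sl, int n) {
  State S;
  S.Vm = as<std::vector<double>>(sl["Vm"]);
  S.Vp = as<std::vector<double>>(sl["Vp"]);
  S.m = as<std::vector<double>>(sl["m"]);
  S.h = as<std::vector<double>>(sl["h"]);
  S.nkm = as<std::vector<double>>(sl["nkm"]);
  S.nkf = as<std::vector<double>>(sl["nkf"]);
  S.ko = as<std::vector<double>>(sl["ko"]);
  S.EK = as<std::vector<double>>(sl["EK"]);
  S.t = as<double>(sl["t"]);
  if ((int)S.Vm.size() != n) stop("state size mismatch");
  return S;
}

static List state_to_list(const State& S) {
  return List::create(_["Vm"] = S.Vm, _["Vp"] = S.Vp, _["m"] = S.m,
                      _["h"] = S.h, _["nkm"] = S.nkm, _["nkf"] = S.nkf,
                      _["ko"] = S.ko, _["EK"] = S.EK, _["t"] = S.t);
}

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List model, List state, NumericVector pulse_starts,
                double pulse_width, double t_end, double dt,
                double record_dt, IntegerVector rec_v_idx,
                IntegerVector rec_ko_idx) {
  Model M = build_model(model);
  State S = build_state(state, M.n);

  // event times: pulse edges, so the integrator lands exactly on them
  std::vector<double> edges;
  for (double ts : pulse_starts) {
    if (ts >= S.t && ts <= S.t + t_end) edges.push_back(ts);
    double te = ts + pulse_width;
    if (te >= S.t && te <= S.t + t_end) edges.push_back(te);
  }
  std::sort(edges.begin(), edges.end());
  size_t next_edge = 0;

  const double t_stop = S.t + t_end;
  const int n_rec_est = (int)(t_end / record_dt) + 2;
  std::vector<double> rec_t; rec_t.reserve(n_rec_est);
  std::vector<std::vector<double>> rec_v(rec_v_idx.size()),
      rec_ko(rec_ko_idx.size()), rec_g(4);
  for (auto& v : rec_v) v.reserve(n_rec_est);
  for (auto& v : rec_ko) v.reserve(n_rec_est);

  std::vector<double> B(5 * M.nun), rhs(M.nun), ipump(M.n), src(M.n),
      Vm_old(M.n), nkm_old(M.n), nkf_old(M.n), PhiI(M.n), PhiP(M.n);
  KScratch kw(M.n);
  long nsteps = 0;
  double next_rec = S.t;
  const double eps = 1e-9;

  auto record = [&]() {
    rec_t.push_back(S.t);
    for (int j = 0; j < rec_v_idx.size(); ++j)
      rec_v[j].push_back(S.Vm[rec_v_idx[j] - 1]);
    for (int j = 0; j < rec_ko_idx.size(); ++j)
      rec_ko[j].push_back(S.ko[rec_ko_idx[j] - 1]);
    if (rec_v_idx.size() > 0) {
      const int g0 = rec_v_idx[0] - 1;
      rec_g[0].push_back(S.m[g0]); rec_g[1].push_back(S.h[g0]);
      rec_g[2].push_back(S.nkm[g0]); rec_g[3].push_back(S.nkf[g0]);
    }
  };
  record();
  next_rec += record_dt;

  while (S.t < t_stop - eps) {
    double h = std::min(dt, t_stop - S.t);
    while (next_edge < edges.size() && edges[next_edge] <= S.t + eps)
      ++next_edge;
    if (next_edge < edges.size() && edges[next_edge] < S.t + h - eps)
      h = edges[next_edge] - S.t;
    if (next_rec > S.t + eps && next_rec < S.t + h - eps)
      h = next_rec - S.t;

    // stimulus on/off for this step (constant: edges are step boundaries)
    const double tm = S.t + h / 2;
    double s = 0.0;
    {
      int np = pulse_starts.size();
      // binary search for the last start <= tm
      int lo = 0, hi = np - 1, best = -1;
      while (lo <= hi) {
        int mid = (lo + hi) / 2;
        if (pulse_starts[mid] <= tm) { best = mid; lo = mid + 1; }
        else hi = mid - 1;
      }
      if (best >= 0 && tm < pulse_starts[best] + pulse_width) s = 1.0;
    }

    Vm_old = S.Vm;
    if (!M.fixed_ko) { nkm_old = S.nkm; nkf_old = S.nkf; }
    electrical_step(M, S, h, s, B, rhs, ipump, PhiI, PhiP);
    gate_step(M, S, h);

    if (!M.fixed_ko) {
      // potassium source evaluated at the step midpoint (mean of old and
      // new voltage/gate values) to keep the operator splitting accurate
      for (int i = 0; i < M.n; ++i)
        src[i] = -2.0 * ipump[i] * 1e6 / (FARADAY * M.vol_um3[i]);
      for (int i : M.act_na) {
        const double nk = 0.5 * (gpow(S.nkm[i], M.gkmn.expo) +
                                 gpow(nkm_old[i], M.gkmn.expo));
        const double vm = 0.5 * (S.Vm[i] + Vm_old[i]);
        src[i] += M.gkm[i] * nk * (vm - S.EK[i]) * 1e6 /
                  (FARADAY * M.vol_um3[i]);
      }
      for (int i : M.act_kf) {
        const double nk = 0.5 * (gpow(S.nkf[i], M.gkfn.expo) +
                                 gpow(nkf_old[i], M.gkfn.expo));
        const double vm = 0.5 * (S.Vm[i] + Vm_old[i]);
        src[i] += M.gkf[i] * nk * (vm - S.EK[i]) * 1e6 /
                  (FARADAY * M.vol_um3[i]);
      }
      k_step(M, S, src, h, 0, kw);
    }

    S.t += h;
    ++nsteps;
    if (S.t >= next_rec - eps) {
      record();
      next_rec += record_dt;
    }
    if (nsteps % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  List rv(rec_v.size()), rk(rec_ko.size()), rg(4);
  for (size_t j = 0; j < rec_v.size(); ++j) rv[j] = rec_v[j];
  for (size_t j = 0; j < rec_ko.size(); ++j) rk[j] = rec_ko[j];
  for (size_t j = 0; j < 4; ++j) rg[j] = rec_g[j];
  return List::create(
    _["time"] = rec_t, _["v"] = rv, _["ko"] = rk, _["gates"] = rg,
    _["state"] = state_to_list(S), _["nsteps"] = nsteps);
}
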