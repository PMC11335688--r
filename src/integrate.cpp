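// Fixed-step RK4 integrator for the coupled striatal network.
//
// State layout: one flat vector, variable-major blocks of length n:
//   [V | m_Na | h_Na | m_K | g1 | g2 | s] (+ optional trailing scalar A_DBS)
// where g1 = m_M (MSN) or m_D (FS), g2 unused (MSN) or h_D (FS).
// The incoming adjacency is CSR over postsynaptic neurons: in_ptr[i] ..
// in_ptr[i+1]-1 index the presynaptic sources of neuron i (0-based).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct Kind {
  double g_leak, g_K, g_Na, g_slow;   // g_slow: g_M (MSN) or g_D (FS)
  double E_leak, E_K, E_Na, E_slow;   // E_slow: E_K (MSN M-current) or E_D
  double C;
  // D-gate kinetics (FS only)
  double mD_half, mD_slope, mD_tau, hD_half, hD_slope, hD_tau;
};

static inline double ratio_exp(double c0, double u, double d) {
  // c0 * u / (1 - exp(-u/d)), analytic limit c0*d at u = 0
  if (std::fabs(u) < 1e-7) return c0 * d;
  return c0 * u / (1.0 - std::exp(-u / d));
}

struct Model {
  int n;
  std::vector<int> msn;            // 1 if MSN
  std::vector<int> in_ptr, in_src; // CSR incoming edges
  Kind km, kf;
  // synapse
  double alpha_M, beta_M, alpha_F, beta_F;
  double g_MM, g_MF, g_FF, g_FM, E_GABA;
  // drive
  double I0;
  int i0_msn_only;
  std::vector<double> I_ext;       // static per-neuron extra current (may be empty)
  // DBS
  std::vector<double> dbs_w;       // A-independent spatial weights (may be empty)
  double dbs_omega, dbs_delta;
  int ctrl_on;
  double kp, s_target, t_on, a_min, a_max;

  // scratch
  mutable std::vector<double> sumM, sumF;

  double pulse(double t) const {
    double s1 = std::sin(dbs_omega * t);
    double s2 = std::sin(dbs_omega * t + dbs_delta);
    double h1 = s1 > 0.0 ? 1.0 : 0.0;
    double h2 = s2 > 0.0 ? 1.0 : 0.0;
    return h1 * (1.0 - h2);
  }

  double restrict_S(const double* y) const {
    const double* s = y + 6 * n;
    double acc = 0.0; int nm = 0;
    for (int i = 0; i < n; ++i) if (msn[i]) { acc += s[i]; ++nm; }
    return nm > 0 ? acc / nm : 0.0;
  }

  void rhs(const double* y, double t, double* dy) const {
    const double* V  = y;
    const double* mna = y + n;
    const double* hna = y + 2 * n;
    const double* mk  = y + 3 * n;
    const double* g1  = y + 4 * n;
    const double* g2  = y + 5 * n;
    const double* s   = y + 6 * n;
    double* dV  = dy;
    double* dmna = dy + n;
    double* dhna = dy + 2 * n;
    double* dmk  = dy + 3 * n;
    double* dg1  = dy + 4 * n;
    double* dg2  = dy + 5 * n;
    double* ds   = dy + 6 * n;

    // presynaptic sums split by source class
    for (int i = 0; i < n; ++i) { sumM[i] = 0.0; sumF[i] = 0.0; }
    for (int i = 0; i < n; ++i) {
      double accM = 0.0, accF = 0.0;
      for (int e = in_ptr[i]; e < in_ptr[i + 1]; ++e) {
        int j = in_src[e];
        if (msn[j]) accM += s[j]; else accF += s[j];
      }
      sumM[i] = accM; sumF[i] = accF;
    }

    // controller amplitude (trailing state when control enabled)
    double A = 0.0;
    bool has_dbs = !dbs_w.empty();
    if (has_dbs) {
      A = y[7 * n];
      if (A < a_min) A = a_min;
      if (A > a_max) A = a_max;
    }
    double pl = has_dbs ? pulse(t) : 0.0;

    for (int i = 0; i < n; ++i) {
      const Kind& k = msn[i] ? km : kf;
      double v = V[i];
      double drive = v - E_GABA;
      double Isyn = msn[i]
        ? drive * (g_MM * sumM[i] + g_MF * sumF[i])
        : drive * (g_FM * sumM[i] + g_FF * sumF[i]);
      double Ina = k.g_Na * mna[i] * mna[i] * mna[i] * hna[i] * (v - k.E_Na);
      double mk2 = mk[i] * mk[i];
      double Ik = k.g_K * mk2 * mk2 * (v - k.E_K);
      double Il = k.g_leak * (v - k.E_leak);
      double Islow = msn[i]
        ? k.g_slow * g1[i] * (v - k.E_slow)
        : k.g_slow * g1[i] * g1[i] * g1[i] * g2[i] * (v - k.E_slow);
      double Iapp = (i0_msn_only && !msn[i]) ? 0.0 : I0;
      if (!I_ext.empty()) Iapp += I_ext[i];
      if (has_dbs) Iapp += A * dbs_w[i] * pl;
      dV[i] = (-Il - Ik - Ina - Islow - Isyn + Iapp) / k.C;

      // Na/K gating rates (shared functional forms for both classes)
      double a_mna = ratio_exp(0.32, v + 54.0, 4.0);
      double u = v + 27.0;
      double b_mna = std::fabs(u) < 1e-7 ? 1.4
        : 0.28 * u / (std::exp(u / 5.0) - 1.0);
      double a_hna = 0.128 * std::exp(-(v + 50.0) / 18.0);
      double b_hna = 4.0 / (1.0 + std::exp(-(v + 27.0) / 5.0));
      double a_mk = ratio_exp(0.032, v + 52.0, 5.0);
      double b_mk = 0.5 * std::exp(-(v + 57.0) / 40.0);
      dmna[i] = a_mna * (1.0 - mna[i]) - b_mna * mna[i];
      dhna[i] = a_hna * (1.0 - hna[i]) - b_hna * hna[i];
      dmk[i]  = a_mk * (1.0 - mk[i]) - b_mk * mk[i];
      if (msn[i]) {
        // M-gate: rates printed identical to the delayed-rectifier gate
        dg1[i] = a_mk * (1.0 - g1[i]) - b_mk * g1[i];
        dg2[i] = 0.0;
      } else {
        double minf = 1.0 / (1.0 + std::exp(-(v - k.mD_half) / k.mD_slope));
        double hinf = 1.0 / (1.0 + std::exp(-(v - k.hD_half) / k.hD_slope));
        dg1[i] = (minf - g1[i]) / k.mD_tau;
        dg2[i] = (hinf - g2[i]) / k.hD_tau;
      }
      // synaptic activation driven by the neuron's own (presynaptic) V
      double H = msn[i] ? 1.0 + std::tanh(v / 4.0) : 1.0 + std::tanh(v / 10.0);
      double al = msn[i] ? alpha_M : alpha_F;
      double be = msn[i] ? beta_M : beta_F;
      ds[i] = al * (1.0 - s[i]) * H - be * s[i];
    }

    if (has_dbs) {
      double dA = 0.0;
      if (ctrl_on && t >= t_on) dA = -kp * (restrict_S(y) - s_target);
      dy[7 * n] = dA;
    }
  }
};

static Kind kind_from(const List& p, bool is_msn) {
  Kind k;
  k.C = as<double>(p["C"]);
  k.g_leak = as<double>(p["g_leak"]);
  k.g_K = as<double>(p["g_K"]);
  k.g_Na = as<double>(p["g_Na"]);
  k.E_leak = as<double>(p["E_leak"]);
  k.E_K = as<double>(p["E_K"]);
  k.E_Na = as<double>(p["E_Na"]);
  if (is_msn) {
    k.g_slow = as<double>(p["g_M"]);
    k.E_slow = k.E_K;   // M-current reverses at E_K
    k.mD_half = k.mD_slope = k.mD_tau = k.hD_half = k.hD_slope = k.hD_tau = 0.0;
  } else {
    k.g_slow = as<double>(p["g_D"]);
    k.E_slow = as<double>(p["E_D"]);
    k.mD_half = as<double>(p["mD_half"]);
    k.mD_slope = as<double>(p["mD_slope"]);
    k.mD_tau = as<double>(p["mD_tau"]);
    k.hD_half = as<double>(p["hD_half"]);
    k.hD_slope = as<double>(p["hD_slope"]);
    k.hD_tau = as<double>(p["hD_tau"]);
  }
  return k;
}

// [[Rcpp::export(name = ".net_integrate_cpp")]]
List net_integrate_cpp(NumericMatrix state0, IntegerVector is_msn,
                       IntegerVector in_ptr, IntegerVector in_src,
                       List msn_par, List fs_par, List syn_par,
                       double dt, int n_steps, int record_every,
                       double t0, double I0, int i0_msn_only,
                       NumericVector I_ext,
                       NumericVector dbs_w, double dbs_omega,
                       double dbs_delta, double dbs_A0,
                       int ctrl_on, double kp, double s_target,
                       double t_on, double a_min, double a_max,
                       double spike_threshold,
                       bool store_v, bool store_s) {
  Model M;
  M.n = state0.nrow();
  if (state0.ncol() != 7) stop("state matrix must have 7 columns");
  M.msn.assign(is_msn.begin(), is_msn.end());
  M.in_ptr.assign(in_ptr.begin(), in_ptr.end());
  M.in_src.assign(in_src.begin(), in_src.end());
  M.km = kind_from(msn_par, true);
  M.kf = kind_from(fs_par, false);
  M.alpha_M = as<double>(syn_par["alpha_M"]);
  M.beta_M = as<double>(syn_par["beta_M"]);
  M.alpha_F = as<double>(syn_par["alpha_F"]);
  M.beta_F = as<double>(syn_par["beta_F"]);
  M.g_MM = as<double>(syn_par["g_MM"]);
  M.g_MF = as<double>(syn_par["g_MF"]);
  M.g_FF = as<double>(syn_par["g_FF"]);
  M.g_FM = as<double>(syn_par["g_FM"]);
  M.E_GABA = as<double>(syn_par["E_GABA"]);
  M.I0 = I0;
  M.i0_msn_only = i0_msn_only;
  if (I_ext.size() > 0) M.I_ext.assign(I_ext.begin(), I_ext.end());
  if (dbs_w.size() > 0) M.dbs_w.assign(dbs_w.begin(), dbs_w.end());
  M.dbs_omega = dbs_omega;
  M.dbs_delta = dbs_delta;
  M.ctrl_on = ctrl_on;
  M.kp = kp; M.s_target = s_target; M.t_on = t_on;
  M.a_min = a_min; M.a_max = a_max;
  M.sumM.assign(M.n, 0.0);
  M.sumF.assign(M.n, 0.0);

  const int n = M.n;
  const bool has_dbs = !M.dbs_w.empty();
  const int dim = 7 * n + (has_dbs ? 1 : 0);
  std::vector<double> y(dim), k1(dim), k2(dim), k3(dim), k4(dim), yt(dim);
  for (int c = 0; c < 7; ++c)
    for (int i = 0; i < n; ++i) y[c * n + i] = state0(i, c);
  if (has_dbs) y[7 * n] = dbs_A0;

  int n_rec = n_steps / record_every + 1;
  NumericVector rec_t(n_rec), rec_vbar(n_rec), rec_S(n_rec), rec_A(n_rec);
  NumericMatrix vmat = store_v ? NumericMatrix(n_rec, n) : NumericMatrix(0, 0);
  NumericMatrix smat = store_s ? NumericMatrix(n_rec, n) : NumericMatrix(0, 0);
  std::vector<double> spike_t;
  std::vector<int> spike_i;
  // running bounds over every step for the bounded variables (cols 1..6)
  NumericVector gate_min(6, 1e300), gate_max(6, -1e300);

  std::vector<double> v_prev(y.begin(), y.begin() + n);

  auto record = [&](int r, double t) {
    rec_t[r] = t;
    double vb = 0.0;
    for (int i = 0; i < n; ++i) vb += y[i];
    rec_vbar[r] = vb / n;
    rec_S[r] = M.restrict_S(y.data());
    double A = has_dbs ? std::min(M.a_max, std::max(M.a_min, y[7 * n])) : 0.0;
    rec_A[r] = A;
    if (store_v) for (int i = 0; i < n; ++i) vmat(r, i) = y[i];
    if (store_s) for (int i = 0; i < n; ++i) smat(r, i) = y[6 * n + i];
  };

  record(0, t0);
  int r_next = 1;
  double t = t0;
  for (int step = 0; step < n_steps; ++step) {
    M.rhs(y.data(), t, k1.data());
    for (int d = 0; d < dim; ++d) yt[d] = y[d] + 0.5 * dt * k1[d];
    M.rhs(yt.data(), t + 0.5 * dt, k2.data());
    for (int d = 0; d < dim; ++d) yt[d] = y[d] + 0.5 * dt * k2[d];
    M.rhs(yt.data(), t + 0.5 * dt, k3.data());
    for (int d = 0; d < dim; ++d) yt[d] = y[d] + dt * k3[d];
    M.rhs(yt.data(), t + dt, k4.data());
    for (int d = 0; d < dim; ++d)
      y[d] += dt / 6.0 * (k1[d] + 2.0 * k2[d] + 2.0 * k3[d] + k4[d]);
    t = t0 + (step + 1) * dt;
    if (has_dbs) {
      if (y[7 * n] < M.a_min) y[7 * n] = M.a_min;
      if (y[7 * n] > M.a_max) y[7 * n] = M.a_max;
    }
    // spikes: upward threshold crossings at full resolution
    for (int i = 0; i < n; ++i) {
      if (v_prev[i] < spike_threshold && y[i] >= spike_threshold) {
        spike_t.push_back(t);
        spike_i.push_back(i + 1);
      }
      v_prev[i] = y[i];
    }
    // sanity + bound tracking
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(y[i])) {
        stop("non-finite membrane potential at t = %f ms, neuron %d",
             t, i + 1);
      }
    }
    for (int c = 1; c <= 6; ++c) {
      double mn = gate_min[c - 1], mx = gate_max[c - 1];
      const double* blk = y.data() + c * n;
      for (int i = 0; i < n; ++i) {
        if (blk[i] < mn) mn = blk[i];
        if (blk[i] > mx) mx = blk[i];
      }
      gate_min[c - 1] = mn; gate_max[c - 1] = mx;
    }
    if ((step + 1) % record_every == 0 && r_next < n_rec) {
      record(r_next, t);
      ++r_next;
    }
  }

  NumericMatrix final_state(n, 7);
  for (int c = 0; c < 7; ++c)
    for (int i = 0; i < n; ++i) final_state(i, c) = y[c * n + i];

  List out = List::create(
    _["times"] = rec_t,
    _["v_mean"] = rec_vbar,
    _["S"] = rec_S,
    _["A_dbs"] = rec_A,
    _["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
    _["spike_i"] = IntegerVector(spike_i.begin(), spike_i.end()),
    _["final_state"] = final_state,
    _["gate_min"] = gate_min,
    _["gate_max"] = gate_max
  );
  if (store_v) out["V"] = vmat;
  if (store_s) out["s"] = smat;
  return out;
}
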