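// Model right-hand sides and deterministic integrators.
//
// Variants and state packing (documented, versioned; must match R/sim.R):
//  1 neuron        (13): v, m_Na, h_Na, m_K, m_CL, h_CL, m_CT, h_CTf, h_CTs,
//                        C_L, C_m, C_c, C_r
//  2 astrocyte     (10): P, h_P, m_CL, h_CL, m_CN, h_CN, C_L, C_N, C_m, C_c
//  3 abeta         (10): C_c, C_r, P_c, m_T, h_Tf, h_Ts, m_L, m_N, m_R, h_R
//  4 abeta_release (17): abeta(10) + m_CL, h_CL, m_CN, h_CN, C_L, C_N, C_m
//  5 coupled       (30): neuron(13) + abeta(10) + m_CL, h_CL, m_CN, h_CN,
//                        C_L, C_N, C_m (astrocytic microdomain block)
//
// Time base: milliseconds. Table constants printed per second are converted
// here (factor 1e-3). Voltages mV, concentrations uM, membrane currents
// uA/cm2, per-channel currents pA, single-channel VGCC currents fA.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double clamp700(double z) {
  return z > 700.0 ? 700.0 : (z < -700.0 ? -700.0 : z);
}
static inline double boltz(double x, double shift, double scale) {
  return 1.0 / (1.0 + std::exp(clamp700(-(x - shift) / scale)));
}
static inline double hillf(double x, double K, double n) {
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x, n), Kn = std::pow(K, n);
  return xn / (xn + Kn);
}
static inline double sq(double x) { return x * x; }
// a*u/(1-exp(-u/s)) with limit a*s at u=0
static inline double lin_exp(double a, double u, double s) {
  if (std::fabs(u) < 1e-7) return a * s;
  return a * u / (1.0 - std::exp(clamp700(-u / s)));
}
static inline double bellt(double v, double tauV, double Vt, double St, double tau0) {
  double u = clamp700((v - Vt) / St);
  return tauV / (std::exp(-u) + std::exp(u)) + tau0;
}

struct Pars {
  double V_K, V_Na, V_L, V_C, g_K_bar, g_Na_bar, g_L, c_m;
  double f, alpha, lambda_ud, lambda_m, lambda_c, lambda_r, B_ud, B_m,
         k_PMCA, k_SERCA, p_leak, N_L, N_N, g_CT, g_CL, g_CN,
         K_L, K_m, K_N, n_L, n_m, n_N;
  double V_m_CL, S_m_CL, V_h_CL, S_h_CL, tau_m_V_CL, tau_m0_V_CL,
         V_tau_m_CL, S_tau_m_CL, tau_h_V_CL, tau_h0_V_CL, V_tau_h_CL, S_tau_h_CL;
  double V_m_CT, S_m_CT, V_h_CT, S_h_CT, tau_m_V_CT, tau_m0_V_CT,
         V_tau_m_CT, S_tau_m_CT, tau_h_V_CT, tau_h0_V_CT, V_tau_h_CT, S_tau_h_CT;
  double V_m_CN, S_m_CN, V_h_CN, S_h_CN, tau_m_V_CN, tau_m0_V_CN,
         V_tau_m_CN, S_tau_m_CN, tau_h_V_CN, tau_h0_V_CN, V_tau_h_CN, S_tau_h_CN;
  double IP3_0, r_P, tau_P, V_m_ast, c0, c1, v1, v2, v3, k3,
         d1, d2, d3, d5, d6, a2_ip3r, A_astro;
  double A_VL, A_RyR, A_m, A_in, k1, k2, k_d, n1, n2, n3, n4, n5,
         a1, a2_in, lambda_PM, lambda_ast, M_SERCA, M_CICR, M_PLC,
         P_SERCA, P_PC, P_CA, P_CI, P_IP3, P_deg, P_f, K_pm,
         g_T_bar, g_L_bar, g_N_bar, g_R_bar;
  double DeltaH, DeltaS, z_gate, z_Ca, R_gas, F, g_m8, V_m8;
  double gK_max_amp, gK_max_mid, gK_max_sig, gNa_max_amp, gNa_max_mid, gNa_max_sig;
  double phi_mK_a, phi_mK_q, phi_mNa_a, phi_mNa_q, phi_hNa_a, phi_hNa_q;
  // precomputed ratios
  double acoef_ud;   // alpha / lambda_ud (uM/ms per pA)
  double acoef_m;    // alpha / lambda_m
  double kexL, kexN; // N_x lambda_ud B_ud / lambda_m (ms^-1)
  double lc_lm, lc_lr;
  double jfac;       // 1e-9 / (z_Ca F lambda_ast): fA -> uM/s
};

static double getp(const NumericVector& nv, const char* name) {
  NumericVector v = nv;
  CharacterVector nm = v.names();
  for (int i = 0; i < v.size(); ++i)
    if (std::strcmp(nm[i], name) == 0) return v[i];
  stop("parameter '%s' missing from parameter vector", name);
  return NA_REAL;
}

static Pars make_pars(const NumericVector& nv) {
  Pars P;
#define GP(x) P.x = getp(nv, #x)
  GP(V_K); GP(V_Na); GP(V_L); GP(V_C); GP(g_K_bar); GP(g_Na_bar); GP(g_L); GP(c_m);
  GP(f); GP(alpha); GP(lambda_ud); GP(lambda_m); GP(lambda_c); GP(lambda_r);
  GP(B_ud); GP(B_m); GP(k_PMCA); GP(k_SERCA); GP(p_leak); GP(N_L); GP(N_N);
  GP(g_CT); GP(g_CL); GP(g_CN); GP(K_L); GP(K_m); GP(K_N); GP(n_L); GP(n_m); GP(n_N);
  GP(V_m_CL); GP(S_m_CL); GP(V_h_CL); GP(S_h_CL); GP(tau_m_V_CL); GP(tau_m0_V_CL);
  GP(V_tau_m_CL); GP(S_tau_m_CL); GP(tau_h_V_CL); GP(tau_h0_V_CL); GP(V_tau_h_CL); GP(S_tau_h_CL);
  GP(V_m_CT); GP(S_m_CT); GP(V_h_CT); GP(S_h_CT); GP(tau_m_V_CT); GP(tau_m0_V_CT);
  GP(V_tau_m_CT); GP(S_tau_m_CT); GP(tau_h_V_CT); GP(tau_h0_V_CT); GP(V_tau_h_CT); GP(S_tau_h_CT);
  GP(V_m_CN); GP(S_m_CN); GP(V_h_CN); GP(S_h_CN); GP(tau_m_V_CN); GP(tau_m0_V_CN);
  GP(V_tau_m_CN); GP(S_tau_m_CN); GP(tau_h_V_CN); GP(tau_h0_V_CN); GP(V_tau_h_CN); GP(S_tau_h_CN);
  GP(IP3_0); GP(r_P); GP(tau_P); GP(V_m_ast); GP(c0); GP(c1); GP(v1); GP(v2); GP(v3); GP(k3);
  GP(d1); GP(d2); GP(d3); GP(d5); GP(d6); GP(a2_ip3r); GP(A_astro);
  GP(A_VL); GP(A_RyR); GP(A_m); GP(A_in); GP(k1); GP(k2); GP(k_d);
  GP(n1); GP(n2); GP(n3); GP(n4); GP(n5); GP(a1); GP(a2_in);
  GP(lambda_PM); GP(lambda_ast); GP(M_SERCA); GP(M_CICR); GP(M_PLC);
  GP(P_SERCA); GP(P_PC); GP(P_CA); GP(P_CI); GP(P_IP3); GP(P_deg); GP(P_f); GP(K_pm);
  GP(g_T_bar); GP(g_L_bar); GP(g_N_bar); GP(g_R_bar);
  GP(DeltaH); GP(DeltaS); GP(z_gate); GP(z_Ca); GP(R_gas); GP(F); GP(g_m8); GP(V_m8);
  GP(gK_max_amp); GP(gK_max_mid); GP(gK_max_sig);
  GP(gNa_max_amp); GP(gNa_max_mid); GP(gNa_max_sig);
  GP(phi_mK_a); GP(phi_mK_q); GP(phi_mNa_a); GP(phi_mNa_q); GP(phi_hNa_a); GP(phi_hNa_q);
#undef GP
  P.acoef_ud = P.alpha / P.lambda_ud;
  P.acoef_m  = P.alpha / P.lambda_m;
  P.kexL = P.N_L * P.lambda_ud * P.B_ud / P.lambda_m;
  P.kexN = P.N_N * P.lambda_ud * P.B_ud / P.lambda_m;
  P.lc_lm = P.lambda_c / P.lambda_m;
  P.lc_lr = P.lambda_c / P.lambda_r;
  P.jfac = 1e-9 / (P.z_Ca * P.F * P.lambda_ast);
  return P;
}

struct Drive {
  std::vector<double> p_start, p_dur, p_amp;     // I_ind pulses (uA/cm2)
  std::vector<double> v_start, v_dur, v_amp;     // v_ind steps (mV)
  int thermal_mode;                              // 0 off, 1 constant, 2 ramp
  double T_const, T_start, T_end, ramp_dur;      // ramp: start->end->start (legs=2)
  int ramp_legs;
  int trpm8;                                     // TRPM8 channel enabled
  double g_m8;                                   // conductance override (mS/cm2)
  int literal_rates, literal_signs, literal_heaviside, literal_gmax;
  double l;                                      // amyloid-beta level
  double vm_clamp;                               // drive voltage for clamped variants
  int rp_scale;                                  // scale r_P with v_ind amplitude / 20 mV
};

static std::vector<double> as_dvec(const List& L, const char* name) {
  if (!L.containsElementNamed(name)) return std::vector<double>();
  return as<std::vector<double> >(L[name]);
}
static double as_dbl(const List& L, const char* name, double def) {
  if (!L.containsElementNamed(name)) return def;
  return as<double>(L[name]);
}
static int as_int(const List& L, const char* name, int def) {
  if (!L.containsElementNamed(name)) return def;
  return as<int>(L[name]);
}

static Drive make_drive(const List& L) {
  Drive D;
  D.p_start = as_dvec(L, "pulse_start"); D.p_dur = as_dvec(L, "pulse_dur");
  D.p_amp = as_dvec(L, "pulse_amp");
  D.v_start = as_dvec(L, "vind_start"); D.v_dur = as_dvec(L, "vind_dur");
  D.v_amp = as_dvec(L, "vind_amp");
  D.thermal_mode = as_int(L, "thermal_mode", 0);
  D.T_const = as_dbl(L, "T_const", 20.0);
  D.T_start = as_dbl(L, "T_start", 30.0);
  D.T_end = as_dbl(L, "T_end", 5.0);
  D.ramp_dur = as_dbl(L, "ramp_dur", 2000.0);
  D.ramp_legs = as_int(L, "ramp_legs", 2);
  D.trpm8 = as_int(L, "trpm8", 0);
  D.g_m8 = as_dbl(L, "g_m8", 0.0);
  D.literal_rates = as_int(L, "literal_rates", 0);
  D.literal_signs = as_int(L, "literal_signs", 0);
  D.literal_heaviside = as_int(L, "literal_heaviside", 0);
  D.literal_gmax = as_int(L, "literal_gmax", 0);
  D.l = as_dbl(L, "l", 0.0);
  D.vm_clamp = as_dbl(L, "vm_clamp", -70.0);
  D.rp_scale = as_int(L, "rp_scale", 0);
  return D;
}

// half-open pulse windows with a tiny tolerance so integrator stage times that
// land on an edge (up to rounding) are classified identically for every step
// size (keeps the RK4 convergence order across grid refinements)
static const double EDGE_EPS = 1e-9; // ms
// Stages that sit exactly on a step's right endpoint must see the forcing of
// the step they belong to (its left limit), not the post-edge value; the
// integrators therefore evaluate the drive of a step-final stage at
// t_end - STAGE_NUDGE. Both constants are < 1e-6 of any step used.
static const double STAGE_NUDGE = 4e-9; // ms
static inline double iind_at(const Drive& D, double t) {
  double out = 0.0;
  for (size_t i = 0; i < D.p_start.size(); ++i)
    if (t >= D.p_start[i] - EDGE_EPS && t < D.p_start[i] + D.p_dur[i] - EDGE_EPS)
      out += D.p_amp[i];
  return out;
}
static inline double vind_at(const Drive& D, double t) {
  double out = 0.0;
  for (size_t i = 0; i < D.v_start.size(); ++i)
    if (t >= D.v_start[i] - EDGE_EPS && t < D.v_start[i] + D.v_dur[i] - EDGE_EPS)
      out += D.v_amp[i];
  return out;
}
static inline double temp_at(const Drive& D, double t) {
  if (D.thermal_mode == 1) return D.T_const;
  if (D.thermal_mode == 2) {
    double leg = D.ramp_dur;
    if (D.ramp_legs <= 1) {
      double u = std::min(std::max(t / leg, 0.0), 1.0);
      return D.T_start + (D.T_end - D.T_start) * u;
    }
    double tt = std::min(std::max(t, 0.0), 2.0 * leg);
    if (tt <= leg) return D.T_start + (D.T_end - D.T_start) * (tt / leg);
    return D.T_end + (D.T_start - D.T_end) * ((tt - leg) / leg);
  }
  return D.T_const;
}

// ---- shared gate kernels (core-table Boltzmann/bell parameterization) ------
struct GateIT { double inf, tau; };
static inline GateIT g_mCL(const Pars& P, double v) {
  GateIT g; g.inf = boltz(v, P.V_m_CL, P.S_m_CL);
  g.tau = bellt(v, P.tau_m_V_CL, P.V_tau_m_CL, P.S_tau_m_CL, P.tau_m0_V_CL); return g;
}
static inline GateIT g_hCL(const Pars& P, double v) {
  GateIT g; g.inf = boltz(v, P.V_h_CL, P.S_h_CL);
  g.tau = bellt(v, P.tau_h_V_CL, P.V_tau_h_CL, P.S_tau_h_CL, P.tau_h0_V_CL); return g;
}
static inline GateIT g_mCT(const Pars& P, double v) {
  GateIT g; g.inf = boltz(v, P.V_m_CT, P.S_m_CT);
  g.tau = bellt(v, P.tau_m_V_CT, P.V_tau_m_CT, P.S_tau_m_CT, P.tau_m0_V_CT);
  if (g.tau < 1e-3) g.tau = 1e-3; // tau_m0_V_CT = 0: keep strictly positive
  return g;
}
static inline GateIT g_hCTf(const Pars& P, double v) {
  GateIT g; g.inf = boltz(v, P.V_h_CT, P.S_h_CT);
  g.tau = bellt(v, P.tau_h_V_CT, P.V_tau_h_CT, P.S_tau_h_CT, P.tau_h0_V_CT); return g;
}
static inline GateIT g_hCTs(const Pars& P, double v) {
  // slow inactivation: shares the fast gate's steady state, slow Gaussian tau
  GateIT g; g.inf = boltz(v, P.V_h_CT, P.S_h_CT);
  g.tau = 400.0 * std::exp(-sq((v + 100.0) / 10.0)) + 400.0; return g;
}
static inline GateIT g_mCN(const Pars& P, double v) {
  GateIT g; g.inf = boltz(v, P.V_m_CN, P.S_m_CN);
  g.tau = bellt(v, P.tau_m_V_CN, P.V_tau_m_CN, P.S_tau_m_CN, P.tau_m0_V_CN); return g;
}
static inline GateIT g_hCN(const Pars& P, double v) {
  GateIT g; g.inf = boltz(v, P.V_h_CN, P.S_h_CN);
  g.tau = bellt(v, P.tau_h_V_CN, P.V_tau_h_CN, P.S_tau_h_CN, P.tau_h0_V_CN); return g;
}

// ---- neuron (variant 1) -----------------------------------------------------
static void neuron_rhs_c(double t, const double* y, double* dy,
                         const Pars& P, const Drive& D, double I_extra) {
  const double v = y[0], mNa = y[1], hNa = y[2], mK = y[3];
  const double mCL = y[4], hCL = y[5], mCT = y[6], hCTf = y[7], hCTs = y[8];
  const double CL = y[9], Cm = y[10], Cc = y[11], Cr = y[12];

  double phiK = 1.0, phiNa = 1.0, phiH = 1.0;
  double gKb = P.g_K_bar, gNab = P.g_Na_bar;
  double T = 0.0;
  if (D.thermal_mode) {
    T = temp_at(D, t);
    phiK  = P.phi_mK_a  * std::pow(P.phi_mK_q,  (T - 20.0) / 10.0);
    phiNa = P.phi_mNa_a * std::pow(P.phi_mNa_q, (T - 20.0) / 10.0);
    phiH  = P.phi_hNa_a * std::pow(P.phi_hNa_q, (T - 20.0) / 10.0);
    double fK  = std::exp(-sq((T - P.gK_max_mid) / P.gK_max_sig));
    double fNa = std::exp(-sq((T - P.gNa_max_mid) / P.gNa_max_sig));
    if (D.literal_gmax) { gKb = P.gK_max_amp * fK; gNab = P.gNa_max_amp * fNa; }
    else { gKb = P.g_K_bar * fK; gNab = P.g_Na_bar * fNa; }
  }

  // HH rates
  double amNa, bmNa, ahNa, bhNa, amK, bmK;
  if (D.literal_rates) {
    amNa = 0.1 * (v + 40.0) * boltz(v, -40.0, 10.0);
    bmNa = 4.0 * std::exp(clamp700(-(v + 65.0) / 18.0));
    ahNa = 0.07 * std::exp(clamp700(-(v + 65.0) / 20.0));
    bhNa = boltz(v, -35.0, 10.0);
    amK  = 0.01 * (v + 55.0) * boltz(v, -55.0, 10.0);
    bmK  = 0.125 * std::exp(clamp700(-(v + 65.0) / 18.0));
  } else {
    amNa = lin_exp(0.1, v + 40.0, 10.0);
    bmNa = 4.0 * std::exp(clamp700(-(v + 65.0) / 18.0));
    ahNa = 0.07 * std::exp(clamp700(-(v + 65.0) / 20.0));
    bhNa = boltz(v, -35.0, 10.0);
    amK  = lin_exp(0.01, v + 55.0, 10.0);
    bmK  = 0.125 * std::exp(clamp700(-(v + 65.0) / 80.0));
  }
  dy[1] = phiNa * (amNa * (1.0 - mNa) - bmNa * mNa);
  dy[2] = phiH  * (ahNa * (1.0 - hNa) - bhNa * hNa);
  dy[3] = phiK  * (amK  * (1.0 - mK)  - bmK  * mK);

  GateIT g;
  g = g_mCL(P, v);  dy[4] = (g.inf - mCL)  / g.tau;
  g = g_hCL(P, v);  dy[5] = (g.inf - hCL)  / g.tau;
  g = g_mCT(P, v);  dy[6] = (g.inf - mCT)  / g.tau;
  g = g_hCTf(P, v); dy[7] = (g.inf - hCTf) / g.tau;
  g = g_hCTs(P, v); dy[8] = (g.inf - hCTs) / g.tau;

  const double iCL = P.g_CL * (v - P.V_C) / P.N_L;                       // pA
  const double ICT = P.g_CT * mCT * (hCTf + 0.04 * hCTs) * (v - P.V_C); // pA
  const double w = mCL * mCL * hCL;

  if (D.literal_signs)
    dy[9] = -P.f * (P.acoef_ud * iCL - P.B_ud * (CL - Cm));
  else
    dy[9] = -P.f * (P.acoef_ud * iCL + P.B_ud * (CL - Cm));

  dy[10] = P.f * (-P.acoef_m * ICT + P.kexL * w * (CL - Cm)
                  - P.lc_lm * (P.k_PMCA * Cm + P.B_m * (Cm - Cc)));
  dy[11] = P.f * (P.B_m * (Cm - Cc) + P.p_leak * (Cr - Cc) - P.k_SERCA * Cc);
  const double er = P.p_leak * (Cr - Cc) - P.k_SERCA * Cc;
  dy[12] = D.literal_signs ? (P.f * P.lc_lr * er) : (-P.f * P.lc_lr * er);

  double I = iind_at(D, t) + I_extra;
  if (D.thermal_mode && D.trpm8) {
    double a = boltz((T + 273.15) * P.DeltaS,
                     P.DeltaH - P.z_gate * P.F * (v * 1e-3),
                     P.R_gas * (T + 273.15));
    double gm8 = (D.g_m8 > 0.0) ? D.g_m8 : P.g_m8;
    I += gm8 * a * (P.V_m8 - v);
  }
  dy[0] = (gKb * std::pow(mK, 4) * (P.V_K - v)
           + gNab * mNa * mNa * mNa * hNa * (P.V_Na - v)
           + P.g_L * (P.V_L - v) + I) / P.c_m;
}

// ---- astrocyte (variant 2) --------------------------------------------------
static void astro_rhs_c(double t, const double* y, double* dy,
                        const Pars& P, const Drive& D) {
  const double Pip = y[0], hP = y[1];
  const double mCL = y[2], hCL = y[3], mCN = y[4], hCN = y[5];
  const double CL = y[6], CN = y[7], Cm = y[8], Cc = y[9];
  const double vi = vind_at(D, t);
  const double v = P.V_m_ast + vi;

  double gate = (vi != 0.0) ? 1.0 : 0.0;
  if (D.rp_scale && gate > 0.0) gate = vi / 20.0;
  dy[0] = (P.IP3_0 - Pip) / P.tau_P + (P.r_P * 1e-3) * gate;

  const double Q = P.d2 * (Pip + P.d1) / (Pip + P.d3);
  const double hPinf = Q / (Q + Cc);
  const double tau_hP = 1000.0 / (P.a2_ip3r * (Q + Cc));
  dy[1] = (hPinf - hP) / tau_hP;

  const double mPinf = (Pip / (Pip + P.d1)) * (Cc / (Cc + P.d5));
  const double er = (P.c0 - Cc) / P.c1;
  dy[9] = 1e-3 * (-P.c1 * P.v1 * std::pow(mPinf, 3) * std::pow(hP, 3) * (Cc - er)
                  - P.c1 * P.v2 * (Cc - er)
                  - P.v3 * hillf(Cc, P.k3, P.n4));

  GateIT g;
  g = g_mCL(P, v); dy[2] = (g.inf - mCL) / g.tau;
  g = g_hCL(P, v); dy[3] = (g.inf - hCL) / g.tau;
  g = g_mCN(P, v); dy[4] = (g.inf - mCN) / g.tau;
  g = g_hCN(P, v); dy[5] = (g.inf - hCN) / g.tau;

  const double iCL = P.g_CL * (v - P.V_C) / P.N_L;
  const double iCN = P.g_CN * (v - P.V_C) / P.N_N;
  if (D.literal_signs) {
    dy[6] = -P.f * (P.acoef_ud * iCL - P.B_ud * (CL - Cm));
    dy[7] = -P.f * (P.acoef_ud * iCN - P.B_ud * (CN - Cm));
  } else {
    dy[6] = -P.f * (P.acoef_ud * iCL + P.B_ud * (CL - Cm));
    dy[7] = -P.f * (P.acoef_ud * iCN + P.B_ud * (CN - Cm));
  }
  const double wL = mCL * mCL * hCL;
  const double wN = mCN * hCN;
  dy[8] = P.f * (P.kexL * wL * (CL - Cm) + P.kexN * wN * (CN - Cm)
                 - P.lc_lm * (P.k_PMCA * Cm + P.B_m * (Cm - Cc)));
}

// ---- amyloid-beta flux network (variant 3 core) -----------------------------
// y offset layout: Cc, Cr, Pc, m_T, h_Tf, h_Ts, m_L, m_N, m_R, h_R
static void abeta_core(double v, const double* y, double* dy,
                       const Pars& P, const Drive& D) {
  const double Cc = y[0], Cr = y[1], Pc = y[2];
  const double mT = y[3], hTf = y[4], hTs = y[5];
  const double mL = y[6], mN = y[7], mR = y[8], hR = y[9];

  dy[3] = (boltz(v, -63.5, 1.5) - mT) / (65.0 * std::exp(-sq((v + 68.0) / 6.0)) + 12.0);
  dy[4] = (boltz(v, -76.2, -3.0) - hTf) / (50.0 * std::exp(-sq((v + 72.0) / 10.0)) + 10.0);
  dy[5] = (boltz(v, -76.2, -3.0) - hTs) / (400.0 * std::exp(-sq((v + 100.0) / 10.0)) + 400.0);
  dy[6] = (boltz(v, -50.0, 3.0) - mL) / (18.0 * std::exp(-sq((v + 45.0) / 20.0)) + 1.5);
  dy[7] = (boltz(v, -45.0, 7.0) - mN) / (18.0 * std::exp(-sq((v + 70.0) / 25.0)) + 0.3);
  dy[8] = (boltz(v, -10.0, 10.0) - mR) / (0.1 * std::exp(-sq((v + 62.0) / 13.0)) + 0.05);
  dy[9] = (boltz(v, -48.0, -5.0) - hR) / (0.5 * std::exp(-sq((v + 55.6) / 18.0)) + 0.5);

  const double hL = 0.00045 / (0.00045 + Cc / 1000.0);
  const double hN = 0.0001 / (0.0001 + Cc / 1000.0);
  const double drv = v - P.V_C;
  const double IT = P.g_T_bar * mT * (hTf + 0.04 * hTs) * drv;
  const double IL = P.g_L_bar * mL * hL * drv;
  const double IN = P.g_N_bar * mN * hN * drv;
  const double IR = P.g_R_bar * mR * hR * drv;
  const double Jvgcc = -(IT + (1.0 + P.A_VL * D.l) * IL + IN + IR) * P.jfac;
  // jfac: fA -> uM/s (1e-15 A * 1e6 uM/M / (z F lambda) = 1e-9/(z F lambda))

  const double H_PCA = std::pow(P.P_CA, P.n1) / (std::pow(P.P_CA, P.n1) + std::pow(Cc, P.n1));
  const double Jcicr = 4.0 * P.M_CICR * H_PCA * hillf(Cc, P.P_CI, P.n1)
                       * hillf(Pc, P.P_IP3, P.n2) * (Cr - Cc);
  const double Jserca = P.M_SERCA * hillf(Cc, P.P_SERCA, P.n4);
  const double Jryr = (P.k1 + P.k2 * hillf(Cc, P.k_d + P.A_RyR * D.l, P.n3)) * (Cr - Cc);
  const double Jr = P.P_f * (Cr - Cc);
  const double Jin = P.a1 + P.a2_in * Pc + P.A_in * std::pow(D.l, P.n5);
  const double Jpm = P.lambda_PM * hillf(Cc, P.K_pm, P.n4);
  const double Jplc = (1.0 + P.A_m * D.l) * P.M_PLC * hillf(Cc, P.P_PC, P.n4);

  dy[0] = 1e-3 * (Jvgcc + Jin + Jryr + Jcicr + Jr - Jserca - Jpm);
  dy[1] = 1e-3 * (Jserca - Jcicr - Jryr - Jr);
  dy[2] = 1e-3 * (Jplc - P.P_deg * Pc);
}

// ---- astrocytic microdomain release block (7 states) ------------------------
// offset layout: m_CL, h_CL, m_CN, h_CN, C_L, C_N, C_m; bulk Cc supplied.
static void microblock(double v, const double* y, double* dy, double Cc_bulk,
                       const Pars& P, const Drive& D) {
  const double mCL = y[0], hCL = y[1], mCN = y[2], hCN = y[3];
  const double CL = y[4], CN = y[5], Cm = y[6];
  GateIT g;
  g = g_mCL(P, v); dy[0] = (g.inf - mCL) / g.tau;
  g = g_hCL(P, v); dy[1] = (g.inf - hCL) / g.tau;
  g = g_mCN(P, v); dy[2] = (g.inf - mCN) / g.tau;
  g = g_hCN(P, v); dy[3] = (g.inf - hCN) / g.tau;
  const double iCL = P.g_CL * (v - P.V_C) / P.N_L;
  const double iCN = P.g_CN * (v - P.V_C) / P.N_N;
  if (D.literal_signs) {
    dy[4] = -P.f * (P.acoef_ud * iCL - P.B_ud * (CL - Cm));
    dy[5] = -P.f * (P.acoef_ud * iCN - P.B_ud * (CN - Cm));
  } else {
    dy[4] = -P.f * (P.acoef_ud * iCL + P.B_ud * (CL - Cm));
    dy[5] = -P.f * (P.acoef_ud * iCN + P.B_ud * (CN - Cm));
  }
  const double wL = mCL * mCL * hCL;
  const double wN = mCN * hCN;
  dy[6] = P.f * (P.kexL * wL * (CL - Cm) + P.kexN * wN * (CN - Cm)
                 - P.lc_lm * (P.k_PMCA * Cm + P.B_m * (Cm - Cc_bulk)));
}

static inline double i_astro_c(double Cc, const Pars& P, const Drive& D) {
  const double yv = 1000.0 * Cc - 196.69;
  if (D.literal_heaviside) return (yv > 0.0) ? P.A_astro * std::log(yv) : 0.0;
  return (yv > 1.0) ? P.A_astro * std::log(yv) : 0.0;
}

// ---- dispatch ---------------------------------------------------------------
static int variant_dim(int variant) {
  switch (variant) {
    case 1: return 13; case 2: return 10; case 3: return 10;
    case 4: return 17; case 5: return 30;
  }
  stop("unknown variant id %d", variant);
  return 0;
}

static void rhs_dispatch(int variant, double t, const double* y, double* dy,
                         const Pars& P, const Drive& D) {
  switch (variant) {
    case 1:
      neuron_rhs_c(t, y, dy, P, D, 0.0);
      break;
    case 2:
      astro_rhs_c(t, y, dy, P, D);
      break;
    case 3: {
      const double v = D.vm_clamp + vind_at(D, t);
      abeta_core(v, y, dy, P, D);
      break;
    }
    case 4: {
      const double v = D.vm_clamp + vind_at(D, t);
      abeta_core(v, y, dy, P, D);
      microblock(v, y + 10, dy + 10, y[0], P, D);
      break;
    }
    case 5: {
      const double Ia = i_astro_c(y[13], P, D); // abeta block Cc
      neuron_rhs_c(t, y, dy, P, D, Ia);
      const double v = y[0];
      abeta_core(v, y + 13, dy + 13, P, D);
      microblock(v, y + 23, dy + 23, y[13], P, D);
      break;
    }
    default:
      stop("unknown variant id %d", variant);
  }
}

// [[Rcpp::export]]
NumericVector cpp_rhs(int variant, double t, NumericVector y,
                      NumericVector params, List drive) {
  const int dim = variant_dim(variant);
  if (y.size() != dim) stop("state has %d elements; variant %d needs %d",
                            (int)y.size(), variant, dim);
  for (int i = 0; i < dim; ++i)
    if (!std::isfinite(y[i])) stop("non-finite state rejected (component %d)", i + 1);
  Pars P = make_pars(params);
  Drive D = make_drive(drive);
  NumericVector dy(dim);
  rhs_dispatch(variant, t, &y[0], &dy[0], P, D);
  return dy;
}

// collect stimulus discontinuity times in (t0, tmax)
static std::vector<double> breakpoints(const Drive& D, double t0, double tmax) {
  std::vector<double> b;
  for (size_t i = 0; i < D.p_start.size(); ++i) {
    b.push_back(D.p_start[i]); b.push_back(D.p_start[i] + D.p_dur[i]);
  }
  for (size_t i = 0; i < D.v_start.size(); ++i) {
    b.push_back(D.v_start[i]); b.push_back(D.v_start[i] + D.v_dur[i]);
  }
  if (D.thermal_mode == 2) {
    b.push_back(D.ramp_dur);
    if (D.ramp_legs > 1) b.push_back(2.0 * D.ramp_dur);
  }
  std::vector<double> out;
  for (size_t i = 0; i < b.size(); ++i)
    if (b[i] > t0 && b[i] < tmax) out.push_back(b[i]);
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return out;
}

static void check_finite(const std::vector<double>& y, double t) {
  for (size_t i = 0; i < y.size(); ++i)
    if (!std::isfinite(y[i]))
      stop("integration became unstable: non-finite state at t = %g ms", t);
}

// Cash-Karp RK45 coefficients
static const double ck_b21 = 1.0 / 5.0;
static const double ck_b31 = 3.0 / 40.0, ck_b32 = 9.0 / 40.0;
static const double ck_b41 = 3.0 / 10.0, ck_b42 = -9.0 / 10.0, ck_b43 = 6.0 / 5.0;
static const double ck_b51 = -11.0 / 54.0, ck_b52 = 5.0 / 2.0,
                    ck_b53 = -70.0 / 27.0, ck_b54 = 35.0 / 27.0;
static const double ck_b61 = 1631.0 / 55296.0, ck_b62 = 175.0 / 512.0,
                    ck_b63 = 575.0 / 13824.0, ck_b64 = 44275.0 / 110592.0,
                    ck_b65 = 253.0 / 4096.0;
static const double ck_c1 = 37.0 / 378.0, ck_c3 = 250.0 / 621.0,
                    ck_c4 = 125.0 / 594.0, ck_c6 = 512.0 / 1771.0;
static const double ck_d1 = 2825.0 / 27648.0, ck_d3 = 18575.0 / 48384.0,
                    ck_d4 = 13525.0 / 55296.0, ck_d5 = 277.0 / 14336.0,
                    ck_d6 = 1.0 / 4.0;

// [[Rcpp::export]]
List cpp_integrate(int variant, NumericVector y0, double t0, double tmax,
                   double dt, double out_dt, std::string method,
                   double rtol, double atol, double max_step,
                   NumericVector params, List drive) {
  const int dim = variant_dim(variant);
  if (y0.size() != dim) stop("initial state has %d elements; variant %d needs %d",
                             (int)y0.size(), variant, dim);
  Pars P = make_pars(params);
  Drive D = make_drive(drive);

  if (tmax < t0) stop("tmax must be >= t0");
  const int n_out = (tmax > t0) ? (int)std::floor((tmax - t0) / out_dt + 1e-9) + 1 : 1;
  NumericMatrix out(n_out, dim);
  NumericVector tout(n_out);
  std::vector<double> y(y0.begin(), y0.end());
  for (int j = 0; j < dim; ++j) out(0, j) = y[j];
  tout[0] = t0;
  if (n_out == 1) return List::create(_["time"] = tout, _["states"] = out);

  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), k5(dim), k6(dim),
                      yt(dim), yerr(dim);

  if (method == "rk4") {
    // fixed-step classic RK4; output rows at multiples of out_dt
    const long nstep_out = (long)std::max(1.0, std::floor(out_dt / dt + 0.5));
    const double dt_eff = out_dt / (double)nstep_out;
    double t = t0;
    for (int r = 1; r < n_out; ++r) {
      for (long s = 0; s < nstep_out; ++s) {
        rhs_dispatch(variant, t, y.data(), k1.data(), P, D);
        for (int j = 0; j < dim; ++j) yt[j] = y[j] + 0.5 * dt_eff * k1[j];
        rhs_dispatch(variant, t + 0.5 * dt_eff, yt.data(), k2.data(), P, D);
        for (int j = 0; j < dim; ++j) yt[j] = y[j] + 0.5 * dt_eff * k2[j];
        rhs_dispatch(variant, t + 0.5 * dt_eff, yt.data(), k3.data(), P, D);
        for (int j = 0; j < dim; ++j) yt[j] = y[j] + dt_eff * k3[j];
        rhs_dispatch(variant, t + dt_eff - STAGE_NUDGE, yt.data(), k4.data(), P, D);
        for (int j = 0; j < dim; ++j)
          y[j] += dt_eff / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
        t += dt_eff;
      }
      t = t0 + (double)r * out_dt; // avoid drift
      check_finite(y, t);
      for (int j = 0; j < dim; ++j) out(r, j) = y[j];
      tout[r] = t;
      if (r % 256 == 0) Rcpp::checkUserInterrupt();
    }
  } else if (method == "adaptive") {
    std::vector<double> bp = breakpoints(D, t0, tmax);
    size_t bp_i = 0;
    double t = t0;
    double h = std::min(dt, max_step);
    for (int r = 1; r < n_out; ++r) {
      const double t_target = t0 + (double)r * out_dt;
      while (t < t_target - 1e-12) {
        while (bp_i < bp.size() && bp[bp_i] <= t + 1e-12) ++bp_i;
        double h_try = std::min(h, t_target - t);
        if (bp_i < bp.size() && t + h_try > bp[bp_i]) h_try = bp[bp_i] - t;
        if (h_try > max_step) h_try = max_step;
        if (h_try < 1e-12) stop("adaptive step underflow at t = %g ms", t);

        // attempt a Cash-Karp step of size h_try
        for (;;) {
          rhs_dispatch(variant, t, y.data(), k1.data(), P, D);
          for (int j = 0; j < dim; ++j) yt[j] = y[j] + h_try * ck_b21 * k1[j];
          rhs_dispatch(variant, t + 0.2 * h_try, yt.data(), k2.data(), P, D);
          for (int j = 0; j < dim; ++j)
            yt[j] = y[j] + h_try * (ck_b31 * k1[j] + ck_b32 * k2[j]);
          rhs_dispatch(variant, t + 0.3 * h_try, yt.data(), k3.data(), P, D);
          for (int j = 0; j < dim; ++j)
            yt[j] = y[j] + h_try * (ck_b41 * k1[j] + ck_b42 * k2[j] + ck_b43 * k3[j]);
          rhs_dispatch(variant, t + 0.6 * h_try, yt.data(), k4.data(), P, D);
          for (int j = 0; j < dim; ++j)
            yt[j] = y[j] + h_try * (ck_b51 * k1[j] + ck_b52 * k2[j]
                                    + ck_b53 * k3[j] + ck_b54 * k4[j]);
          rhs_dispatch(variant, t + h_try - STAGE_NUDGE, yt.data(), k5.data(), P, D);
          for (int j = 0; j < dim; ++j)
            yt[j] = y[j] + h_try * (ck_b61 * k1[j] + ck_b62 * k2[j] + ck_b63 * k3[j]
                                    + ck_b64 * k4[j] + ck_b65 * k5[j]);
          rhs_dispatch(variant, t + 0.875 * h_try, yt.data(), k6.data(), P, D);

          double errmax = 0.0;
          for (int j = 0; j < dim; ++j) {
            const double y5 = y[j] + h_try * (ck_c1 * k1[j] + ck_c3 * k3[j]
                                              + ck_c4 * k4[j] + ck_c6 * k6[j]);
            const double y4 = y[j] + h_try * (ck_d1 * k1[j] + ck_d3 * k3[j]
                                              + ck_d4 * k4[j] + ck_d5 * k5[j]
                                              + ck_d6 * k6[j]);
            yerr[j] = y5 - y4;
            yt[j] = y5;
            const double sc = atol + rtol * std::fabs(y[j]);
            const double e = std::fabs(yerr[j]) / sc;
            if (!std::isfinite(e)) { errmax = 1e30; break; }
            if (e > errmax) errmax = e;
          }
          if (errmax <= 1.0) {
            t += h_try;
            y.assign(yt.begin(), yt.end());
            double grow = (errmax > 1e-30) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
            if (grow > 5.0) grow = 5.0;
            h = std::min(h_try * grow, max_step);
            break;
          }
          double shrink = 0.9 * std::pow(errmax, -0.25);
          if (shrink < 0.1) shrink = 0.1;
          h_try *= shrink;
          if (h_try < 1e-12)
            stop("integration became unstable: adaptive step underflow at t = %g ms", t);
        }
      }
      t = t_target;
      check_finite(y, t);
      for (int j = 0; j < dim; ++j) out(r, j) = y[j];
      tout[r] = t;
      if (r % 64 == 0) Rcpp::checkUserInterrupt();
    }
  } else {
    stop("unknown method '%s' (use 'rk4' or 'adaptive')", method.c_str());
  }
  return List::create(_["time"] = tout, _["states"] = out);
}
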