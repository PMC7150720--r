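#ifndef CARDIOEM_MODEL_H
#define CARDIOEM_MODEL_H

#include <Rcpp.h>
#include <cmath>
#include <vector>

// ten Tusscher & Panfilov (2006) human ventricular myocyte, with the inward
// rectifier current replaced by one of three Kir2.1 formulations (wild type,
// heterozygous E299V, pure E299V). State layout shared by the single-cell and
// monodomain tissue integrators.

namespace cardioem {

// state vector indices
enum StateIdx {
  S_V = 0, S_M, S_H, S_J, S_D, S_F, S_F2, S_FCASS, S_R, S_S,
  S_XR1, S_XR2, S_XS, S_RBAR, S_CAI, S_CASR, S_CASS, S_NAI, S_KI,
  N_STATE
};

// parameter vector indices (order fixed; built by cell_parameters() in R)
enum ParIdx {
  P_GNA = 0, P_GK1, P_GTO, P_GKR, P_GKS, P_GCAL, P_GBNA, P_GBCA,
  P_GPCA, P_KPCA, P_GPK, P_PNAK, P_KMK, P_KMNA, P_KNACA, P_KSAT,
  P_ALPHA, P_GAMMA, P_KMNAI, P_KMCA, P_VMAXUP, P_KUP, P_VREL,
  P_VLEAK, P_VXFER, P_K1P, P_K2P, P_K3, P_K4, P_EC, P_MAXSR,
  P_MINSR, P_BUFC, P_KBUFC, P_BUFSR, P_KBUFSR, P_BUFSS, P_KBUFSS,
  P_VC, P_VSR, P_VSS, P_CM, P_KO, P_NAO, P_CAO,
  N_PAR
};

const double FARADAY = 96485.3415; // C/mmol
const double GASCONST = 8314.472;  // mJ/(mol K)
const double TEMP = 310.0;         // K
const double RTONF = GASCONST * TEMP / FARADAY; // mV

// mutation condition codes
enum Condition { COND_WT = 0, COND_HET = 1, COND_E299V = 2 };

// I_K1 voltage dependence for driving force u = V - E_K (pA/pF before the
// per-condition conductance scale stored in P_GK1)
inline double ik1_shape(double u, int cond) {
  switch (cond) {
  case COND_WT:
    return 0.24731 * u / (0.86426 + std::exp(0.0904 * u - 0.06519));
  case COND_HET:
    return 0.11905 * (u + 2.4) / (0.04092 + std::exp(0.01732 * u - 0.36212));
  default: // pure E299V: rectification lost, quasi-ohmic quadratic
    return 0.06634 * (u + 6.5) - 2.44009e-4 * u * u - 0.51383;
  }
}

// ---- voltage-dependent rate tables -----------------------------------------
// One table per run (depends on dt through the Rush-Larsen factors).
struct Lut {
  double vmin, vmax, dv, inv_dv;
  int n;
  // per-gate: steady state value and Rush-Larsen factor exp(-dt/tau)
  std::vector<double> m_inf, m_rl, h_inf, h_rl, j_inf, j_rl;
  std::vector<double> d_inf, d_rl, f_inf, f_rl, f2_inf, f2_rl;
  std::vector<double> r_inf, r_rl;
  std::vector<double> s_inf_endo, s_rl_endo, s_inf_epi, s_rl_epi;
  std::vector<double> xr1_inf, xr1_rl, xr2_inf, xr2_rl, xs_inf, xs_rl;
  // assembled voltage factors
  std::vector<double> cal_a, cal_b;     // ICaL = gCaL*d*f*f2*fcass*(A*Cass - B)
  std::vector<double> naca_e1, naca_e2; // exchanger exponentials
  std::vector<double> nak_rec;          // NaK rectification
  std::vector<double> pk_rec;           // IpK rectification
};

inline void build_lut(Lut &lut, double dt, double Cao) {
  lut.vmin = -120.0; lut.vmax = 90.0; lut.dv = 0.05;
  lut.inv_dv = 1.0 / lut.dv;
  lut.n = (int)((lut.vmax - lut.vmin) / lut.dv) + 1;
  int n = lut.n;
  std::vector<double> *all[] = {
    &lut.m_inf, &lut.m_rl, &lut.h_inf, &lut.h_rl, &lut.j_inf, &lut.j_rl,
    &lut.d_inf, &lut.d_rl, &lut.f_inf, &lut.f_rl, &lut.f2_inf, &lut.f2_rl,
    &lut.r_inf, &lut.r_rl, &lut.s_inf_endo, &lut.s_rl_endo,
    &lut.s_inf_epi, &lut.s_rl_epi,
    &lut.xr1_inf, &lut.xr1_rl, &lut.xr2_inf, &lut.xr2_rl,
    &lut.xs_inf, &lut.xs_rl, &lut.cal_a, &lut.cal_b,
    &lut.naca_e1, &lut.naca_e2, &lut.nak_rec, &lut.pk_rec };
  for (auto v : all) v->resize(n);

  for (int i = 0; i < n; ++i) {
    double V = lut.vmin + i * lut.dv;

    // INa gates
    double m_inf = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2);
    double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
    double tau_m = am * bm;
    double h_inf = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2);
    double ah, bh, aj, bj;
    if (V >= -40.0) {
      ah = 0.0;
      bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
      aj = 0.0;
      bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
      bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
      aj = (-2.5428e4 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V)) *
           (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.02424 * std::exp(-0.01052 * V) /
           (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    double tau_h = 1.0 / (ah + bh);
    double tau_j = 1.0 / (aj + bj);

    // ICaL voltage gates
    double d_inf = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
    double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
    double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
    double gd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
    double tau_d = ad * bd + gd;
    double f_inf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
    double tau_f = 1102.5 * std::exp(-std::pow(V + 27.0, 2) / 225.0) +
                   200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
                   180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
    double f2_inf = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
    double tau_f2 = 562.0 * std::exp(-std::pow(V + 27.0, 2) / 240.0) +
                    31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
                    80.0 / (1.0 + std::exp((V + 30.0) / 10.0));

    // Ito gates
    double r_inf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
    double tau_r = 9.5 * std::exp(-std::pow(V + 40.0, 2) / 1800.0) + 0.8;
    double s_inf_endo = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
    double tau_s_endo = 1000.0 * std::exp(-std::pow(V + 67.0, 2) / 1000.0) + 8.0;
    double s_inf_epi = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
    double tau_s_epi = 85.0 * std::exp(-std::pow(V + 45.0, 2) / 320.0) +
                       5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;

    // IKr gates
    double xr1_inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
    double axr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
    double bxr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
    double tau_xr1 = axr1 * bxr1;
    double xr2_inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
    double axr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
    double bxr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
    double tau_xr2 = axr2 * bxr2;

    // IKs gate
    double xs_inf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
    double axs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
    double bxs = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
    double tau_xs = axs * bxs + 80.0;

    lut.m_inf[i] = m_inf;  lut.m_rl[i] = std::exp(-dt / tau_m);
    lut.h_inf[i] = h_inf;  lut.h_rl[i] = std::exp(-dt / tau_h);
    lut.j_inf[i] = h_inf;  lut.j_rl[i] = std::exp(-dt / tau_j);
    lut.d_inf[i] = d_inf;  lut.d_rl[i] = std::exp(-dt / tau_d);
    lut.f_inf[i] = f_inf;  lut.f_rl[i] = std::exp(-dt / tau_f);
    lut.f2_inf[i] = f2_inf; lut.f2_rl[i] = std::exp(-dt / tau_f2);
    lut.r_inf[i] = r_inf;  lut.r_rl[i] = std::exp(-dt / tau_r);
    lut.s_inf_endo[i] = s_inf_endo; lut.s_rl_endo[i] = std::exp(-dt / tau_s_endo);
    lut.s_inf_epi[i] = s_inf_epi;   lut.s_rl_epi[i] = std::exp(-dt / tau_s_epi);
    lut.xr1_inf[i] = xr1_inf; lut.xr1_rl[i] = std::exp(-dt / tau_xr1);
    lut.xr2_inf[i] = xr2_inf; lut.xr2_rl[i] = std::exp(-dt / tau_xr2);
    lut.xs_inf[i] = xs_inf;   lut.xs_rl[i] = std::exp(-dt / tau_xs);

    // ICaL driving terms: ICaL = gCaL*d*f*f2*fcass*(A(V)*Cass - B(V))
    double w = 2.0 * (V - 15.0) / RTONF;
    double A, B;
    if (std::fabs(w) < 1e-7) {
      A = 0.5 * FARADAY;
      B = 2.0 * FARADAY * Cao;
    } else {
      double ew = std::exp(w);
      A = 2.0 * FARADAY * w * 0.25 * ew / (ew - 1.0);
      B = 2.0 * FARADAY * w * Cao / (ew - 1.0);
    }
    lut.cal_a[i] = A;
    lut.cal_b[i] = B;

    lut.naca_e1[i] = std::exp(0.35 * V / RTONF);
    lut.naca_e2[i] = std::exp((0.35 - 1.0) * V / RTONF);
    lut.nak_rec[i] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTONF) +
                            0.0353 * std::exp(-V / RTONF));
    lut.pk_rec[i] = 1.0 / (1.0 + std::exp((25.0 - V) / 5.98));
  }
}

// linear interpolation helpers into a table
struct LutPos { int i; double frac; };
inline LutPos lut_pos(const Lut &lut, double V) {
  double x = (V - lut.vmin) * lut.inv_dv;
  if (!(x > 0.0)) x = 0.0; // also catches NaN (flagged by the state check)
  if (x > lut.n - 1.000001) x = lut.n - 1.000001;
  int i = (int)x;
  return LutPos{i, x - i};
}
inline double lut_at(const std::vector<double> &tab, const LutPos &p) {
  return tab[p.i] + p.frac * (tab[p.i + 1] - tab[p.i]);
}

struct Currents {
  double INa, IK1, Ito, IKr, IKs, ICaL, INaCa, INaK, IpCa, IpK, IbCa, IbNa;
  double Iion, Ileak, Iup, Irel, Ixfer, EK, ENa, ECa, EKs;
};

// membrane currents + SR fluxes at the given state (no table; exact formulas)
inline Currents eval_currents(const double *s, const double *p,
                              int celltype, int cond) {
  Currents c;
  double V = s[S_V];
  double EK = RTONF * std::log(p[P_KO] / s[S_KI]);
  double ENa = RTONF * std::log(p[P_NAO] / s[S_NAI]);
  double ECa = 0.5 * RTONF * std::log(p[P_CAO] / s[S_CAI]);
  double EKs = RTONF * std::log((p[P_KO] + 0.03 * p[P_NAO]) /
                                (s[S_KI] + 0.03 * s[S_NAI]));
  c.EK = EK; c.ENa = ENa; c.ECa = ECa; c.EKs = EKs;

  c.INa = p[P_GNA] * s[S_M] * s[S_M] * s[S_M] * s[S_H] * s[S_J] * (V - ENa);
  c.IK1 = p[P_GK1] * ik1_shape(V - EK, cond);
  c.Ito = p[P_GTO] * s[S_R] * s[S_S] * (V - EK);
  c.IKr = p[P_GKR] * std::sqrt(p[P_KO] / 5.4) * s[S_XR1] * s[S_XR2] * (V - EK);
  c.IKs = p[P_GKS] * s[S_XS] * s[S_XS] * (V - EKs);

  double w = 2.0 * (V - 15.0) / RTONF;
  double A, B;
  if (std::fabs(w) < 1e-7) {
    A = 0.5 * FARADAY; B = 2.0 * FARADAY * p[P_CAO];
  } else {
    double ew = std::exp(w);
    A = 2.0 * FARADAY * w * 0.25 * ew / (ew - 1.0);
    B = 2.0 * FARADAY * w * p[P_CAO] / (ew - 1.0);
  }
  c.ICaL = p[P_GCAL] * s[S_D] * s[S_F] * s[S_F2] * s[S_FCASS] *
           (A * s[S_CASS] - B);

  double e1 = std::exp(p[P_GAMMA] * V / RTONF);
  double e2 = std::exp((p[P_GAMMA] - 1.0) * V / RTONF);
  double Nai3 = s[S_NAI] * s[S_NAI] * s[S_NAI];
  double Nao3 = p[P_NAO] * p[P_NAO] * p[P_NAO];
  c.INaCa = p[P_KNACA] *
            (e1 * Nai3 * p[P_CAO] - e2 * Nao3 * s[S_CAI] * p[P_ALPHA]) /
            ((std::pow(p[P_KMNAI], 3) + Nao3) * (p[P_KMCA] + p[P_CAO]) *
             (1.0 + p[P_KSAT] * e2));
  c.INaK = p[P_PNAK] * (p[P_KO] / (p[P_KO] + p[P_KMK])) *
           (s[S_NAI] / (s[S_NAI] + p[P_KMNA])) /
           (1.0 + 0.1245 * std::exp(-0.1 * V / RTONF) +
            0.0353 * std::exp(-V / RTONF));
  c.IpCa = p[P_GPCA] * s[S_CAI] / (p[P_KPCA] + s[S_CAI]);
  c.IpK = p[P_GPK] * (V - EK) / (1.0 + std::exp((25.0 - V) / 5.98));
  c.IbNa = p[P_GBNA] * (V - ENa);
  c.IbCa = p[P_GBCA] * (V - ECa);

  c.Iion = c.INa + c.IK1 + c.Ito + c.IKr + c.IKs + c.ICaL + c.INaCa +
           c.INaK + c.IpCa + c.IpK + c.IbCa + c.IbNa;

  c.Ileak = p[P_VLEAK] * (s[S_CASR] - s[S_CAI]);
  c.Iup = p[P_VMAXUP] / (1.0 + std::pow(p[P_KUP] / s[S_CAI], 2));
  double kcasr = p[P_MAXSR] - (p[P_MAXSR] - p[P_MINSR]) /
                 (1.0 + std::pow(p[P_EC] / s[S_CASR], 2));
  double k1 = p[P_K1P] / kcasr;
  double O = k1 * s[S_CASS] * s[S_CASS] * s[S_RBAR] /
             (p[P_K3] + k1 * s[S_CASS] * s[S_CASS]);
  c.Irel = p[P_VREL] * O * (s[S_CASR] - s[S_CASS]);
  c.Ixfer = p[P_VXFER] * (s[S_CASS] - s[S_CAI]);
  return c;
}

// equilibrium potentials, refreshed on a coarse cadence: the underlying
// concentrations drift by < 1e-3 mM per ms, so E values recomputed every
// 0.2 ms are exact to ~1e-4 mV
struct Epots { double EK, ENa, ECa, EKs; };
const int EPOT_REFRESH_STEPS = 10;

inline void refresh_epots(const double *s, const double *p, Epots &e) {
  e.EK = RTONF * std::log(p[P_KO] / s[S_KI]);
  e.ENa = RTONF * std::log(p[P_NAO] / s[S_NAI]);
  e.ECa = 0.5 * RTONF * std::log(p[P_CAO] / s[S_CAI]);
  e.EKs = RTONF * std::log((p[P_KO] + 0.03 * p[P_NAO]) /
                           (s[S_KI] + 0.03 * s[S_NAI]));
}

// one operator-split step: Rush-Larsen gates (via LUT), forward Euler for V
// and concentrations. istim in pA/pF (negative depolarizes).
inline void reaction_step(double *s, const double *p, int celltype, int cond,
                          double istim, double dt, const Lut &lut,
                          double diffusion_term /* dV contribution, mV */,
                          const Epots &ep) {
  double V = s[S_V];
  LutPos pos = lut_pos(lut, V);

  double EK = ep.EK, ENa = ep.ENa, ECa = ep.ECa, EKs = ep.EKs;

  double INa = p[P_GNA] * s[S_M] * s[S_M] * s[S_M] * s[S_H] * s[S_J] * (V - ENa);
  double IK1 = p[P_GK1] * ik1_shape(V - EK, cond);
  double Ito = p[P_GTO] * s[S_R] * s[S_S] * (V - EK);
  double IKr = p[P_GKR] * std::sqrt(p[P_KO] / 5.4) * s[S_XR1] * s[S_XR2] * (V - EK);
  double IKs = p[P_GKS] * s[S_XS] * s[S_XS] * (V - EKs);
  double ICaL = p[P_GCAL] * s[S_D] * s[S_F] * s[S_F2] * s[S_FCASS] *
                (lut_at(lut.cal_a, pos) * s[S_CASS] - lut_at(lut.cal_b, pos));
  double e1 = lut_at(lut.naca_e1, pos);
  double e2 = lut_at(lut.naca_e2, pos);
  double Nai3 = s[S_NAI] * s[S_NAI] * s[S_NAI];
  double Nao3 = p[P_NAO] * p[P_NAO] * p[P_NAO];
  double kmnai3 = p[P_KMNAI] * p[P_KMNAI] * p[P_KMNAI];
  double INaCa = p[P_KNACA] *
                 (e1 * Nai3 * p[P_CAO] - e2 * Nao3 * s[S_CAI] * p[P_ALPHA]) /
                 ((kmnai3 + Nao3) * (p[P_KMCA] + p[P_CAO]) *
                  (1.0 + p[P_KSAT] * e2));
  double INaK = p[P_PNAK] * (p[P_KO] / (p[P_KO] + p[P_KMK])) *
                (s[S_NAI] / (s[S_NAI] + p[P_KMNA])) * lut_at(lut.nak_rec, pos);
  double IpCa = p[P_GPCA] * s[S_CAI] / (p[P_KPCA] + s[S_CAI]);
  double IpK = p[P_GPK] * (V - EK) * lut_at(lut.pk_rec, pos);
  double IbNa = p[P_GBNA] * (V - ENa);
  double IbCa = p[P_GBCA] * (V - ECa);

  double Iion = INa + IK1 + Ito + IKr + IKs + ICaL + INaCa + INaK +
                IpCa + IpK + IbCa + IbNa;

  // SR fluxes
  double Ileak = p[P_VLEAK] * (s[S_CASR] - s[S_CAI]);
  double kup_r = p[P_KUP] / s[S_CAI];
  double Iup = p[P_VMAXUP] / (1.0 + kup_r * kup_r);
  double ec_r = p[P_EC] / s[S_CASR];
  double kcasr = p[P_MAXSR] - (p[P_MAXSR] - p[P_MINSR]) /
                 (1.0 + ec_r * ec_r);
  double k1 = p[P_K1P] / kcasr;
  double k2 = p[P_K2P] * kcasr;
  double O = k1 * s[S_CASS] * s[S_CASS] * s[S_RBAR] /
             (p[P_K3] + k1 * s[S_CASS] * s[S_CASS]);
  double Irel = p[P_VREL] * O * (s[S_CASR] - s[S_CASS]);
  double Ixfer = p[P_VXFER] * (s[S_CASS] - s[S_CAI]);

  double dRbar = -k2 * s[S_CASS] * s[S_RBAR] + p[P_K4] * (1.0 - s[S_RBAR]);
  s[S_RBAR] += dt * dRbar;

  // concentration balances (buffered)
  double Cm = p[P_CM];
  double inVcF2 = 1.0 / (2.0 * p[P_VC] * FARADAY);
  double inVcF = 1.0 / (p[P_VC] * FARADAY);
  double inVssF2 = 1.0 / (2.0 * p[P_VSS] * FARADAY);

  double cb = s[S_CAI] + p[P_KBUFC];
  double bc = 1.0 / (1.0 + p[P_BUFC] * p[P_KBUFC] / (cb * cb));
  double sb = s[S_CASR] + p[P_KBUFSR];
  double bsr = 1.0 / (1.0 + p[P_BUFSR] * p[P_KBUFSR] / (sb * sb));
  double ssb = s[S_CASS] + p[P_KBUFSS];
  double bss = 1.0 / (1.0 + p[P_BUFSS] * p[P_KBUFSS] / (ssb * ssb));

  double dCai = bc * (-(IbCa + IpCa - 2.0 * INaCa) * inVcF2 * Cm -
                      (Iup - Ileak) * (p[P_VSR] / p[P_VC]) + Ixfer);
  double dCaSR = bsr * (Iup - Irel - Ileak);
  double dCaSS = bss * (-ICaL * inVssF2 * Cm +
                        Irel * p[P_VSR] / p[P_VSS] -
                        Ixfer * p[P_VC] / p[P_VSS]);
  double dNai = -(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * inVcF * Cm;
  double dKi = -(istim + IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK) * inVcF * Cm;

  s[S_CAI] += dt * dCai;
  s[S_CASR] += dt * dCaSR;
  s[S_CASS] += dt * dCaSS;
  s[S_NAI] += dt * dNai;
  s[S_KI] += dt * dKi;

  // Rush-Larsen gate updates
  bool endo = (celltype == 0);
  auto rl_update = [&](int idx, const std::vector<double> &inf,
                       const std::vector<double> &rl) {
    double gi = lut_at(inf, pos);
    s[idx] = gi + (s[idx] - gi) * lut_at(rl, pos);
  };
  rl_update(S_M, lut.m_inf, lut.m_rl);
  rl_update(S_H, lut.h_inf, lut.h_rl);
  rl_update(S_J, lut.j_inf, lut.j_rl);
  rl_update(S_D, lut.d_inf, lut.d_rl);
  rl_update(S_F, lut.f_inf, lut.f_rl);
  rl_update(S_F2, lut.f2_inf, lut.f2_rl);
  rl_update(S_R, lut.r_inf, lut.r_rl);
  if (endo) {
    rl_update(S_S, lut.s_inf_endo, lut.s_rl_endo);
  } else {
    rl_update(S_S, lut.s_inf_epi, lut.s_rl_epi);
  }
  rl_update(S_XR1, lut.xr1_inf, lut.xr1_rl);
  rl_update(S_XR2, lut.xr2_inf, lut.xr2_rl);
  rl_update(S_XS, lut.xs_inf, lut.xs_rl);

  // fcass depends on subspace calcium, not voltage
  double cass_ratio = s[S_CASS] / 0.05;
  double den = 1.0 + cass_ratio * cass_ratio;
  double fcass_inf = 0.6 / den + 0.4;
  double tau_fcass = 80.0 / den + 2.0;
  s[S_FCASS] = fcass_inf + (s[S_FCASS] - fcass_inf) * std::exp(-dt / tau_fcass);

  s[S_V] = V + dt * (-(Iion + istim)) / 1.0 + diffusion_term;
}

// default initial (resting) state; paced runs equilibrate from here
inline void default_state(double *s) {
  s[S_V] = -86.2;
  s[S_M] = 0.0; s[S_H] = 0.75; s[S_J] = 0.75;
  s[S_D] = 0.0; s[S_F] = 1.0; s[S_F2] = 1.0; s[S_FCASS] = 1.0;
  s[S_R] = 0.0; s[S_S] = 1.0;
  s[S_XR1] = 0.0; s[S_XR2] = 1.0; s[S_XS] = 0.0;
  s[S_RBAR] = 1.0;
  s[S_CAI] = 7e-5; s[S_CASR] = 1.3; s[S_CASS] = 7e-5;
  s[S_NAI] = 7.67; s[S_KI] = 138.3;
}

} // namespace cardioem

#endif
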