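#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closed-loop lumped circulation: LV and RV are time-varying elastance
// chambers driven by sampled E(t) waveforms; LA/RA and the four vascular
// compartments are linear compliances; the four valves are pressure-gated
// diodes with series resistance. Volume moves strictly pairwise, so total
// blood volume is conserved to round-off.

enum { C_LV = 0, C_LA, C_RV, C_RA, C_SA, C_SV, C_PA, C_PV, NCOMP };
// parameter order built by circulation_parameters() in R
enum {
  Q_V0LV = 0, Q_V0LA, Q_V0RV, Q_V0RA, Q_V0SA, Q_V0SV, Q_V0PA, Q_V0PV,
  Q_CLA, Q_CRA, Q_CSA, Q_CSV, Q_CPA, Q_CPV,
  Q_RMI, Q_RAO, Q_RSYS, Q_RVR, Q_RTR, Q_RPU, Q_RPUL, Q_RPV,
  Q_NPAR
};

// [[Rcpp::export]]
List cpp_run_circulation(NumericVector vol0, NumericVector params,
                         NumericVector e_lv, NumericVector e_rv,
                         double e_dt, double duration, double dt,
                         double record_dt) {
  std::vector<double> V(vol0.begin(), vol0.end());
  const double *p = REAL(params);
  long n = (long)std::llround(duration / dt);
  long rec_every = std::max(1L, (long)std::llround(record_dt / dt));
  long n_rec = n / rec_every + 1;
  // t, 8 pressures, 8 volumes, total, 4 valve flows
  NumericMatrix tr(n_rec, 1 + 8 + 8 + 1 + 4);
  long row = 0;
  int ne = e_lv.size();

  auto esample = [&](const NumericVector &e, double t) {
    double x = t / e_dt;
    if (x <= 0) return e[0];
    if (x >= ne - 1) return e[ne - 1];
    int i = (int)x;
    double f = x - i;
    return e[i] + f * (e[i + 1] - e[i]);
  };

  double P[NCOMP], Q[8];
  for (long i = 0; i <= n; ++i) {
    double t = i * dt;
    double Elv = esample(e_lv, t), Erv = esample(e_rv, t);
    P[C_LV] = Elv * (V[C_LV] - p[Q_V0LV]);
    P[C_RV] = Erv * (V[C_RV] - p[Q_V0RV]);
    P[C_LA] = (V[C_LA] - p[Q_V0LA]) / p[Q_CLA];
    P[C_RA] = (V[C_RA] - p[Q_V0RA]) / p[Q_CRA];
    P[C_SA] = (V[C_SA] - p[Q_V0SA]) / p[Q_CSA];
    P[C_SV] = (V[C_SV] - p[Q_V0SV]) / p[Q_CSV];
    P[C_PA] = (V[C_PA] - p[Q_V0PA]) / p[Q_CPA];
    P[C_PV] = (V[C_PV] - p[Q_V0PV]) / p[Q_CPV];

    // flows, mL/s (R in mmHg*s/mL); valves are diodes
    double q_mi = std::max(P[C_LA] - P[C_LV], 0.0) / p[Q_RMI];
    double q_ao = std::max(P[C_LV] - P[C_SA], 0.0) / p[Q_RAO];
    double q_sys = (P[C_SA] - P[C_SV]) / p[Q_RSYS];
    double q_vr = (P[C_SV] - P[C_RA]) / p[Q_RVR];
    double q_tr = std::max(P[C_RA] - P[C_RV], 0.0) / p[Q_RTR];
    double q_pu = std::max(P[C_RV] - P[C_PA], 0.0) / p[Q_RPU];
    double q_pul = (P[C_PA] - P[C_PV]) / p[Q_RPUL];
    double q_pv = (P[C_PV] - P[C_LA]) / p[Q_RPV];
    Q[0] = q_mi; Q[1] = q_ao; Q[2] = q_sys; Q[3] = q_vr;
    Q[4] = q_tr; Q[5] = q_pu; Q[6] = q_pul; Q[7] = q_pv;

    if (i % rec_every == 0 && row < n_rec) {
      tr(row, 0) = t;
      double tot = 0;
      for (int k = 0; k < NCOMP; ++k) {
        tr(row, 1 + k) = P[k];
        tr(row, 9 + k) = V[k];
        tot += V[k];
      }
      tr(row, 17) = tot;
      tr(row, 18) = q_mi; tr(row, 19) = q_ao;
      tr(row, 20) = q_tr; tr(row, 21) = q_pu;
      ++row;
    }
    if (i == n) break;

    double h = dt / 1000.0; // ms -> s
    V[C_LA] += h * (q_pv - q_mi);
    V[C_LV] += h * (q_mi - q_ao);
    V[C_SA] += h * (q_ao - q_sys);
    V[C_SV] += h * (q_sys - q_vr);
    V[C_RA] += h * (q_vr - q_tr);
    V[C_RV] += h * (q_tr - q_pu);
    V[C_PA] += h * (q_pu - q_pul);
    V[C_PV] += h * (q_pul - q_pv);
    for (int k = 0; k < NCOMP; ++k)
      if (!(V[k] > 0.0))
        stop("circulation failure: compartment %d volume %.2f mL at t = %.0f ms",
             k + 1, V[k], t);
  }

  colnames(tr) = CharacterVector::create(
    "t", "P_lv", "P_la", "P_rv", "P_ra", "P_sa", "P_sv", "P_pa", "P_pv",
    "V_lv", "V_la", "V_rv", "V_ra", "V_sa", "V_sv", "V_pa", "V_pv",
    "V_total", "Q_mi", "Q_ao", "Q_tr", "Q_pu");
  return List::create(_["trace"] = tr,
                      _["final_volumes"] = NumericVector(V.begin(), V.end()));
}
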