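#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rice-style cross-bridge cycling driven by a cytosolic calcium trace.
// States: TCa (troponin-bound fraction), N, P (non/permissive regulatory
// units), XBPreR, XBPostR (bound cross-bridge duty fractions), xPre, xPost
// (mean distortions, um). N + P + XBPreR + XBPostR is conserved.
//
// myo state indices
enum { M_TCA = 0, M_N, M_P, M_B1, M_B2, M_XPRE, M_XPOST, M_NSTATE };
// myo parameter indices (order fixed; built by myofilament_parameters())
enum {
  MP_KON = 0, MP_KOFF, MP_KNP, MP_KPN, MP_PERM50, MP_NPERM_HALF, MP_PNCAP,
  MP_FAPP, MP_GAPP, MP_GSLMOD, MP_HF, MP_HFMDC, MP_HB, MP_GXB,
  MP_SIGMAP, MP_SIGMAN, MP_X0, MP_PHI, MP_SL, MP_NPAR
};

static double sovf_thick(double sl) {
  // single-overlap fraction of the thick filament (Rice geometry, um)
  const double len_thick = 1.65, len_hbare = 0.1, len_thin = 1.2;
  double sovr_ze = std::min(len_thick / 2.0, sl / 2.0);
  double sovr_cle = std::max(sl / 2.0 - (sl - len_thin), len_hbare / 2.0);
  double len_sovr = std::max(sovr_ze - sovr_cle, 0.0);
  return len_sovr * 2.0 / (len_thick - len_hbare);
}

struct MyoRates {
  double fappT, gappT, hfT, hbT, gxbT, knpT, kpnT, sovf;
};

static MyoRates myo_rates(const double *s, const double *p) {
  MyoRates r;
  r.sovf = sovf_thick(p[MP_SL]);
  r.fappT = p[MP_FAPP];
  r.gappT = p[MP_GAPP] * (1.0 + (1.0 - r.sovf) * p[MP_GSLMOD]);
  double xr = s[M_XPRE] / p[MP_X0];
  double sgn = (s[M_XPRE] >= 0.0) ? 1.0 : -1.0;
  r.hfT = p[MP_HF] * std::exp(-sgn * p[MP_HFMDC] * xr * xr);
  r.hbT = p[MP_HB];
  double dpost = (p[MP_X0] - s[M_XPOST]) / p[MP_X0];
  double sig = (s[M_XPOST] < p[MP_X0]) ? p[MP_SIGMAP] : p[MP_SIGMAN];
  r.gxbT = p[MP_GXB] * std::exp(sig * dpost * dpost);
  double tca = std::max(s[M_TCA], 1e-8);
  double ratio = tca / p[MP_PERM50];
  double pw = std::pow(ratio, p[MP_NPERM_HALF]);
  // both switching rates saturate at the cap (keeps the cooperative
  // equilibrium while bounding the stiffness of the ODE)
  r.knpT = std::min(p[MP_KNP] * pw, p[MP_PNCAP]);
  r.kpnT = std::min(p[MP_KPN] / pw, p[MP_PNCAP]);
  return r;
}

// steady-state duty fractions of the 3-state bound cycle at base rates
static void ss_duty(const double *p, double &ssB1, double &ssB2) {
  double fapp = p[MP_FAPP], gapp = p[MP_GAPP], hf = p[MP_HF],
         hb = p[MP_HB], gxb = p[MP_GXB];
  double den = fapp * hf + gxb * hf + gxb * gapp + hb * fapp +
               hb * gapp + gxb * fapp;
  ssB1 = (hb * fapp + gxb * fapp) / den;
  ssB2 = fapp * hf / den;
}

static double active_force_of(const double *s, const double *p) {
  double ssB1, ssB2;
  ss_duty(p, ssB1, ssB2);
  return sovf_thick(p[MP_SL]) *
         (s[M_B1] * s[M_XPRE] + s[M_B2] * s[M_XPOST]) /
         (p[MP_X0] * ssB2);
}

static void myo_step(double *s, const double *p, double ca, double dt) {
  MyoRates r = myo_rates(s, p);
  double dTCa = p[MP_KON] * ca * (1.0 - s[M_TCA]) - p[MP_KOFF] * s[M_TCA];
  double dN = -r.knpT * s[M_N] + r.kpnT * s[M_P];
  double dP = r.knpT * s[M_N] - r.kpnT * s[M_P] - r.fappT * s[M_P] +
              r.gappT * s[M_B1] + r.gxbT * s[M_B2];
  double dB1 = r.fappT * s[M_P] - r.gappT * s[M_B1] - r.hfT * s[M_B1] +
               r.hbT * s[M_B2];
  double dB2 = r.hfT * s[M_B1] - r.hbT * s[M_B2] - r.gxbT * s[M_B2];
  double ssB1, ssB2;
  ss_duty(p, ssB1, ssB2);
  double dxPre = (p[MP_PHI] / ssB1) *
                 (-r.fappT * s[M_XPRE] +
                  r.hbT * (s[M_XPOST] - p[MP_X0] - s[M_XPRE]));
  double dxPost = (p[MP_PHI] / ssB2) *
                  (r.hfT * (s[M_XPRE] + p[MP_X0] - s[M_XPOST]));
  s[M_TCA] += dt * dTCa;
  s[M_N] += dt * dN;
  s[M_P] += dt * dP;
  s[M_B1] += dt * dB1;
  s[M_B2] += dt * dB2;
  s[M_XPRE] += dt * dxPre;
  s[M_XPOST] += dt * dxPost;
}

// [[Rcpp::export]]
NumericVector cpp_myo_init(NumericVector params) {
  NumericVector s(M_NSTATE);
  s[M_TCA] = 0.0; s[M_N] = 1.0; s[M_P] = 0.0;
  s[M_B1] = 0.0; s[M_B2] = 0.0;
  s[M_XPRE] = 0.0; s[M_XPOST] = params[MP_X0];
  s.attr("names") = CharacterVector::create(
    "TCa_Tot", "N_xb", "P_xb", "XB_PreR", "XB_PostR", "xXB_PreR", "xXB_PostR");
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_myo_step(NumericVector state, NumericVector params,
                           double ca, double dt, long n_steps = 1) {
  std::vector<double> s(state.begin(), state.end());
  for (long i = 0; i < n_steps; ++i) myo_step(s.data(), REAL(params), ca, dt);
  NumericVector out(s.begin(), s.end());
  out.attr("names") = state.attr("names");
  return out;
}

// [[Rcpp::export]]
double cpp_active_force(NumericVector state, NumericVector params) {
  return active_force_of(REAL(state), REAL(params));
}

// [[Rcpp::export]]
double cpp_sovf_thick(double sl) { return sovf_thick(sl); }

// Drive the myofilament with a calcium time series (linear interpolation).
// Records t, F_active, instantaneous ATP flux g_xbT * XB_PostR (1/ms), and
// the state fractions at `record_dt` spacing.
// [[Rcpp::export]]
List cpp_run_myofilament(NumericVector state, NumericVector params,
                         NumericVector ca_t, NumericVector ca_v,
                         double duration, double dt, double record_dt) {
  std::vector<double> s(state.begin(), state.end());
  long n = (long)std::llround(duration / dt);
  long rec_every = std::max(1L, (long)std::llround(record_dt / dt));
  long n_rec = n / rec_every + 1;
  NumericMatrix tr(n_rec, 4 + M_NSTATE);
  long row = 0;
  int nca = ca_t.size(), ica = 0;
  for (long i = 0; i <= n; ++i) {
    double t = i * dt;
    // interpolate calcium (ca_t assumed sorted increasing)
    while (ica < nca - 2 && ca_t[ica + 1] < t) ++ica;
    double ca;
    if (t <= ca_t[0]) ca = ca_v[0];
    else if (t >= ca_t[nca - 1]) ca = ca_v[nca - 1];
    else {
      double f = (t - ca_t[ica]) / (ca_t[ica + 1] - ca_t[ica]);
      ca = ca_v[ica] + f * (ca_v[ica + 1] - ca_v[ica]);
    }
    if (i % rec_every == 0 && row < n_rec) {
      MyoRates r = myo_rates(s.data(), REAL(params));
      tr(row, 0) = t;
      tr(row, 1) = active_force_of(s.data(), REAL(params));
      tr(row, 2) = r.gxbT * s[M_B2];
      tr(row, 3) = ca;
      for (int k = 0; k < M_NSTATE; ++k) tr(row, 4 + k) = s[k];
      ++row;
    }
    if (i == n) break;
    myo_step(s.data(), REAL(params), ca, dt);
  }
  colnames(tr) = CharacterVector::create(
    "t", "F_active", "atp_flux", "Ca_i", "TCa_Tot", "N_xb", "P_xb",
    "XB_PreR", "XB_PostR", "xXB_PreR", "xXB_PostR");
  NumericVector fin(s.begin(), s.end());
  fin.attr("names") = state.attr("names");
  return List::create(_["trace"] = tr, _["state"] = fin);
}
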