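#include "model.h"
using namespace Rcpp;
using namespace cardioem;

// [[Rcpp::export]]
NumericVector cpp_default_state() {
  NumericVector out(N_STATE);
  default_state(REAL(out));
  out.attr("names") = CharacterVector::create(
    "V", "m", "h", "j", "d", "f", "f2", "fcass", "r", "s",
    "xr1", "xr2", "xs", "Rbar", "Ca_i", "Ca_SR", "Ca_ss", "Na_i", "K_i");
  return out;
}

// [[Rcpp::export]]
List cpp_currents(NumericVector state, NumericVector params,
                  int celltype, int cond) {
  Currents c = eval_currents(REAL(state), REAL(params), celltype, cond);
  return List::create(
    _["I_Na"] = c.INa, _["I_K1"] = c.IK1, _["I_to"] = c.Ito,
    _["I_Kr"] = c.IKr, _["I_Ks"] = c.IKs, _["I_CaL"] = c.ICaL,
    _["I_NaCa"] = c.INaCa, _["I_NaK"] = c.INaK, _["I_pCa"] = c.IpCa,
    _["I_pK"] = c.IpK, _["I_bCa"] = c.IbCa, _["I_bNa"] = c.IbNa,
    _["I_ion"] = c.Iion, _["I_leak"] = c.Ileak, _["I_up"] = c.Iup,
    _["I_rel"] = c.Irel, _["I_xfer"] = c.Ixfer,
    _["E_K"] = c.EK, _["E_Na"] = c.ENa, _["E_Ca"] = c.ECa, _["E_Ks"] = c.EKs);
}

// [[Rcpp::export]]
double cpp_ik1_shape(double u, int cond) { return ik1_shape(u, cond); }

static void check_state_finite(const double *s, double t) {
  static const char *nm[] = {"V", "m", "h", "j", "d", "f", "f2", "fcass",
                             "r", "s", "xr1", "xr2", "xs", "Rbar",
                             "Ca_i", "Ca_SR", "Ca_ss", "Na_i", "K_i"};
  for (int k = 0; k < N_STATE; ++k) {
    if (!std::isfinite(s[k])) {
      stop("numerical divergence in state variable '%s' at t = %.3f ms",
           nm[k], t);
    }
  }
  if (s[S_V] < -120.0 || s[S_V] > 90.0) {
    stop("numerical divergence in state variable 'V' (%.1f mV) at t = %.3f ms",
         s[S_V], t);
  }
}

// Advance a single cell for `duration` ms with square stimulus pulses starting
// at `stim_times` (ms, relative to run start). Records (t, V, Ca_i, I_K1) and
// optionally all membrane currents from `record_start` at `record_dt` spacing.
// [[Rcpp::export]]
List cpp_run_cell(NumericVector state, NumericVector params, int celltype,
                  int cond, double duration, double dt,
                  NumericVector stim_times, double stim_amp, double stim_dur,
                  double record_start, double record_dt,
                  bool record_currents = false) {
  std::vector<double> s(REAL(state), REAL(state) + N_STATE);
  Lut lut;
  build_lut(lut, dt, params[P_CAO]);

  long n_steps = (long)std::llround(duration / dt);
  long rec_every = std::max(1L, (long)std::llround(record_dt / dt));
  long first_rec = (long)std::ceil(record_start / dt - 1e-9);
  long n_rec = 0;
  for (long i = 0; i <= n_steps; ++i)
    if (i >= first_rec && (i - first_rec) % rec_every == 0) ++n_rec;

  int base_cols = 4;
  int ncol = record_currents ? base_cols + 17 : base_cols;
  NumericMatrix trace(n_rec, ncol);

  int ns = stim_times.size();
  long row = 0;
  Epots ep;
  for (long i = 0; i <= n_steps; ++i) {
    double t = i * dt;
    if (i % EPOT_REFRESH_STEPS == 0) refresh_epots(s.data(), REAL(params), ep);
    if (i >= first_rec && (i - first_rec) % rec_every == 0) {
      Currents c = eval_currents(s.data(), REAL(params), celltype, cond);
      trace(row, 0) = t;
      trace(row, 1) = s[S_V];
      trace(row, 2) = s[S_CAI];
      trace(row, 3) = c.IK1;
      if (record_currents) {
        trace(row, 4) = c.INa;  trace(row, 5) = c.Ito;  trace(row, 6) = c.IKr;
        trace(row, 7) = c.IKs;  trace(row, 8) = c.ICaL; trace(row, 9) = c.INaCa;
        trace(row, 10) = c.INaK; trace(row, 11) = c.IpCa; trace(row, 12) = c.IpK;
        trace(row, 13) = c.IbCa; trace(row, 14) = c.IbNa; trace(row, 15) = c.Iion;
        trace(row, 16) = c.Ileak; trace(row, 17) = c.Iup; trace(row, 18) = c.Irel;
        trace(row, 19) = c.EK;   trace(row, 20) = c.ENa;
      }
      ++row;
    }
    if (i == n_steps) break;

    double istim = 0.0;
    for (int k = 0; k < ns; ++k) {
      if (t >= stim_times[k] && t < stim_times[k] + stim_dur) {
        istim = stim_amp;
        break;
      }
    }
    reaction_step(s.data(), REAL(params), celltype, cond, istim, dt, lut,
                  0.0, ep);
    if ((i & 1023) == 0) check_state_finite(s.data(), t);
  }
  check_state_finite(s.data(), duration);

  NumericVector final_state(s.begin(), s.end());
  final_state.attr("names") = cpp_default_state().attr("names");

  CharacterVector cn;
  if (record_currents) {
    cn = CharacterVector::create("t", "V", "Ca_i", "I_K1", "I_Na", "I_to",
                                 "I_Kr", "I_Ks", "I_CaL", "I_NaCa", "I_NaK",
                                 "I_pCa", "I_pK", "I_bCa", "I_bNa", "I_ion",
                                 "I_leak", "I_up", "I_rel", "E_K", "E_Na");
  } else {
    cn = CharacterVector::create("t", "V", "Ca_i", "I_K1");
  }
  colnames(trace) = cn;
  return List::create(_["trace"] = trace, _["state"] = final_state);
}

// Plain fixed-step advance without recording; used by the step oracle tests.
// [[Rcpp::export]]
NumericVector cpp_step_cell(NumericVector state, NumericVector params,
                            int celltype, int cond, double istim, double dt,
                            long n_steps = 1) {
  std::vector<double> s(REAL(state), REAL(state) + N_STATE);
  Lut lut;
  build_lut(lut, dt, params[P_CAO]);
  Epots ep;
  for (long i = 0; i < n_steps; ++i) {
    if (i % EPOT_REFRESH_STEPS == 0) refresh_epots(s.data(), REAL(params), ep);
    reaction_step(s.data(), REAL(params), celltype, cond, istim, dt, lut,
                  0.0, ep);
    if ((i & 1023) == 0) check_state_finite(s.data(), i * dt);
  }
  NumericVector out(s.begin(), s.end());
  out.attr("names") = cpp_default_state().attr("names");
  return out;
}
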