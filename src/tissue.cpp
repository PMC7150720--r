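#include "model.h"
using namespace Rcpp;
using namespace cardioem;

// Monodomain reaction-diffusion on a 1D cable / ring or 2D sheet.
//
// states:    n_nodes x N_STATE matrix (row per node)
// params:    3 x N_PAR matrix, one row per cell type (endo/mid/epi)
// celltype:  per-node cell type code 0/1/2
// cond:      per-node mutation condition code 0/1/2
// ik1scale:  length-3 conductance scale per condition
// stim_*:    one entry per stimulus episode; stim_nodes is a list of
//            integer vectors (0-based node indices)
// cuts:      k x 3 matrix (node_a, node_b, t_open): conduction between the
//            two nodes is disabled while t < t_open (unidirectional-block
//            initiation on rings)
// Records: probe voltages, whole-field frames, per-node first EAT/EDT inside
// [map_t0, map_t1], activation counts, and excited-node counts per frame.
// [[Rcpp::export]]
List cpp_run_tissue(NumericMatrix states, NumericMatrix params,
                    IntegerVector celltype, IntegerVector cond,
                    NumericVector ik1scale,
                    int nx, int ny, double dx, double D, bool periodic,
                    double duration, double dt,
                    NumericVector stim_t0, NumericVector stim_dur,
                    NumericVector stim_amp, List stim_nodes,
                    IntegerVector probes, double probe_dt,
                    double frame_dt, double map_t0, double map_t1,
                    double act_threshold = -40.0) {
  const int n = nx * ny;
  if (states.nrow() != n || states.ncol() != N_STATE)
    stop("states matrix must be n_nodes x n_state");

  // per-node state (structure-of-arrays not needed; row pointer per node)
  std::vector<double> S(n * N_STATE);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < N_STATE; ++k) S[i * N_STATE + k] = states(i, k);

  // per-celltype parameter vectors with condition scale applied per node
  // (g_K1 in the params row is ignored; scale vector is authoritative)
  std::vector<std::vector<double>> P(3, std::vector<double>(N_PAR));
  for (int c = 0; c < 3; ++c)
    for (int k = 0; k < N_PAR; ++k) P[c][k] = params(c, k);

  Lut lut;
  build_lut(lut, dt, P[0][P_CAO]);

  long n_steps = (long)std::llround(duration / dt);
  long probe_every = std::max(1L, (long)std::llround(probe_dt / dt));
  long frame_every = std::max(1L, (long)std::llround(frame_dt / dt));

  int n_probe = probes.size();
  long n_probe_rec = n_steps / probe_every + 1;
  NumericMatrix probe_v(n_probe_rec, n_probe + 1);
  NumericMatrix probe_ca(n_probe_rec, n_probe + 1);
  long n_frames = n_steps / frame_every + 1;
  NumericMatrix frames(n_frames, n);
  NumericVector frame_t(n_frames);
  NumericVector excited(n_frames);

  // activation bookkeeping
  std::vector<double> eat(n, NA_REAL), edt(n, NA_REAL);
  std::vector<double> vdia(n), vpeak(n), last_act(n, NA_REAL);
  std::vector<int> phase(n, 0), n_act(n, 0);
  for (int i = 0; i < n; ++i) vdia[i] = S[i * N_STATE + S_V];

  std::vector<double> lap(n), Vbuf(n);
  std::vector<Epots> epots(n);
  int n_cuts = 0;
  // cuts passed through attribute-free extra args would clutter; reuse stim
  // machinery instead: cuts come in via the "cuts" attribute of states
  NumericMatrix cuts;
  if (states.hasAttribute("cuts")) {
    cuts = as<NumericMatrix>(states.attr("cuts"));
    n_cuts = cuts.nrow();
  }

  double ddx2 = D / (dx * dx);
  long probe_row = 0, frame_row = 0;

  for (long istep = 0; istep <= n_steps; ++istep) {
    double t = istep * dt;

    // recording
    if (istep % probe_every == 0 && probe_row < n_probe_rec) {
      probe_v(probe_row, 0) = t;
      probe_ca(probe_row, 0) = t;
      for (int k = 0; k < n_probe; ++k) {
        probe_v(probe_row, k + 1) = S[probes[k] * N_STATE + S_V];
        probe_ca(probe_row, k + 1) = S[probes[k] * N_STATE + S_CAI];
      }
      ++probe_row;
    }
    if (istep % frame_every == 0 && frame_row < n_frames) {
      int nex = 0;
      for (int i = 0; i < n; ++i) {
        double v = S[i * N_STATE + S_V];
        frames(frame_row, i) = v;
        if (v > act_threshold) ++nex;
      }
      frame_t[frame_row] = t;
      excited[frame_row] = nex;
      ++frame_row;
    }
    if (istep == n_steps) break;

    // snapshot V and laplacian
    for (int i = 0; i < n; ++i) Vbuf[i] = S[i * N_STATE + S_V];
    if (ny == 1) {
      for (int i = 0; i < n; ++i) {
        int il = (i == 0) ? (periodic ? n - 1 : 1) : i - 1;
        int ir = (i == n - 1) ? (periodic ? 0 : n - 2) : i + 1;
        lap[i] = Vbuf[il] + Vbuf[ir] - 2.0 * Vbuf[i];
      }
    } else {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          int i = y * nx + x;
          int xl = (x == 0) ? 1 : x - 1;
          int xr = (x == nx - 1) ? nx - 2 : x + 1;
          int yl = (y == 0) ? 1 : y - 1;
          int yr = (y == ny - 1) ? ny - 2 : y + 1;
          lap[i] = Vbuf[y * nx + xl] + Vbuf[y * nx + xr] +
                   Vbuf[yl * nx + x] + Vbuf[yr * nx + x] - 4.0 * Vbuf[i];
        }
      }
    }
    // temporary conduction block across cut edges: remove the pair fluxes
    for (int c = 0; c < n_cuts; ++c) {
      if (t < cuts(c, 2)) {
        int a = (int)cuts(c, 0), b = (int)cuts(c, 1);
        lap[a] -= (Vbuf[b] - Vbuf[a]);
        lap[b] -= (Vbuf[a] - Vbuf[b]);
      }
    }

    // active stimuli this step
    std::vector<double> istim(n, 0.0);
    for (int k = 0; k < stim_t0.size(); ++k) {
      if (t >= stim_t0[k] && t < stim_t0[k] + stim_dur[k]) {
        IntegerVector nodes = stim_nodes[k];
        for (int m = 0; m < nodes.size(); ++m) istim[nodes[m]] += stim_amp[k];
      }
    }

    bool refresh = (istep % EPOT_REFRESH_STEPS == 0);
    for (int i = 0; i < n; ++i) {
      double *s = &S[i * N_STATE];
      double diff_term = dt * ddx2 * lap[i];
      int ct = celltype[i];
      double gk1 = ik1scale[cond[i]];
      // swap in the per-condition conductance scale
      double saved = P[ct][P_GK1];
      P[ct][P_GK1] = gk1;
      if (refresh) refresh_epots(s, P[ct].data(), epots[i]);
      reaction_step(s, P[ct].data(), ct, cond[i], istim[i], dt, lut,
                    diff_term, epots[i]);
      P[ct][P_GK1] = saved;

      // activation state machine
      double v = s[S_V];
      if (phase[i] == 0) {
        if (v > act_threshold && Vbuf[i] <= act_threshold) {
          phase[i] = 1;
          ++n_act[i];
          last_act[i] = t;
          vpeak[i] = v;
          if (ISNA(eat[i]) && t >= map_t0 && t <= map_t1) eat[i] = t;
        } else if (v < vdia[i]) {
          vdia[i] = v;
        }
      } else {
        if (v > vpeak[i]) vpeak[i] = v;
        double vth = vdia[i] + 0.1 * (vpeak[i] - vdia[i]);
        if (v < vth) {
          phase[i] = 0;
          if (ISNA(edt[i]) && !ISNA(eat[i]) && t >= map_t0 && t <= map_t1)
            edt[i] = t;
          vdia[i] = v;
        }
      }
      if (!std::isfinite(v) || v < -150.0 || v > 120.0)
        stop("numerical divergence at node %d (V = %.1f) at t = %.2f ms",
             i + 1, v, t);
    }
  }

  IntegerVector nact(n_act.begin(), n_act.end());
  return List::create(
    _["probe_v"] = probe_v, _["probe_ca"] = probe_ca,
    _["frames"] = frames, _["frame_t"] = frame_t,
    _["excited"] = excited, _["eat"] = NumericVector(eat.begin(), eat.end()),
    _["edt"] = NumericVector(edt.begin(), edt.end()),
    _["n_activations"] = nact,
    _["last_activation"] = NumericVector(last_act.begin(), last_act.end()),
    _["final_states"] = [&]() {
      NumericMatrix out(n, N_STATE);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < N_STATE; ++k) out(i, k) = S[i * N_STATE + k];
      return out;
    }());
}
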