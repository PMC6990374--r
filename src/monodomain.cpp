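// Explicit finite-difference monodomain stepper on a regular 2D node grid.
// Diffusion uses precomputed per-node neighbour weights (1/ms) built in R
// from the element conductivity field; reaction is the TT06 endocardial
// model advanced in lock-step at the same dt. Records probe traces,
// threshold-crossing events (with sub-dt linear interpolation), optional
// full-field snapshots, and the final state for segment chaining.
#include <Rcpp.h>
#include "tt06core.h"

using namespace Rcpp;
using namespace tt06;

// [[Rcpp::export]]
List mono_run_cpp(NumericVector V0, NumericMatrix S18_0, IntegerVector active,
                  IntegerMatrix nb_idx, NumericMatrix nb_w,
                  NumericVector gna, NumericVector gkr, NumericVector gks,
                  IntegerVector stim_nodes, NumericVector stim_onsets,
                  double stim_dur, double stim_amp, double dt, double t0,
                  double t_end, IntegerVector probe_nodes, double probe_dt,
                  double up_thresh, double rep_thresh, int max_cross,
                  double snap_dt, IntegerVector stop_nodes, double stop_delay,
                  bool quiet_stop, double quiet_level, double quiet_min_t,
                  int rev_every, bool reaction_on, bool diffusion_on) {
  const int n = V0.size();
  if (S18_0.nrow() != NSTATE - 1 || S18_0.ncol() != n)
    stop("state matrix must be %d x n_nodes", NSTATE - 1);
  if (dt <= 0 || dt > 0.1) stop("dt must lie in (0, 0.1] ms");

  const int na = active.size();
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> S(S18_0.begin(), S18_0.end());  // column-major 18 x n
  std::vector<double> dvd(na, 0.0);
  std::vector<double> EK(n, 0.0), ENa(n, 0.0), EKs(n, 0.0), ECa(n, 0.0);

  std::vector<char> is_stim(n, 0), is_stop(n, 0);
  for (int q = 0; q < stim_nodes.size(); ++q) is_stim[stim_nodes[q]] = 1;
  for (int q = 0; q < stop_nodes.size(); ++q) is_stop[stop_nodes[q]] = 1;

  Tables T;
  T.build(dt);

  const long nstep = (long)llround((t_end - t0) / dt);
  const long pstride = probe_dt > 0 ? (long)llround(probe_dt / dt) : nstep + 1;
  const long sstride = snap_dt > 0 ? (long)llround(snap_dt / dt) : 0;
  const int npr = probe_nodes.size();

  std::vector<double> probe_t;
  std::vector<double> probe_v;  // row-major blocks of npr
  std::vector<int> cr_node;
  std::vector<double> cr_time;
  std::vector<int> cr_dir;
  std::vector<int> up_count(n, 0), down_count(n, 0);
  std::vector<NumericVector> snaps;
  std::vector<double> snap_t;

  const int* act = INTEGER(active);
  const int* nb = INTEGER(nb_idx);
  const double* w = REAL(nb_w);
  const double* gna_p = REAL(gna);
  const double* gkr_p = REAL(gkr);
  const double* gks_p = REAL(gks);
  const int nstim = stim_onsets.size();
  double last_stim_end = -1e30;
  for (int q = 0; q < nstim; ++q)
    last_stim_end = std::max(last_stim_end, stim_onsets[q] + stim_dur);

  // record t0 probe sample
  if (npr > 0) {
    probe_t.push_back(t0);
    for (int q = 0; q < npr; ++q) probe_v.push_back(V[probe_nodes[q]]);
  }

  std::string reason = "t_end";
  double stop_at = R_PosInf;  // early-exit deadline once a stop node fires
  double t_stop = t_end;
  int bad_node = -1;
  double bad_t = 0.0;

  // refresh reversal potentials of the active nodes
  auto refresh_rev = [&](void) {
    for (int a = 0; a < na; ++a) {
      int i = act[a];
      const double* si = &S[(size_t)i * (NSTATE - 1)];
      EK[i] = RTF * log(Ko / si[iKi - 1]);
      ENa[i] = RTF * log(Nao / si[iNai - 1]);
      EKs[i] = RTF * log((Ko + pKNa * Nao) / (si[iKi - 1] + pKNa * si[iNai - 1]));
      ECa[i] = 0.5 * RTF * log(Cao / si[iCai - 1]);
    }
  };
  refresh_rev();

  long step = 0;
  for (; step < nstep; ++step) {
    double t = t0 + step * dt;
    if (step % 2000 == 0) checkUserInterrupt();
    if (rev_every > 0 && step % rev_every == 0 && step > 0) refresh_rev();

    bool stim_on = false;
    for (int q = 0; q < nstim; ++q) {
      if (t >= stim_onsets[q] - 1e-9 && t < stim_onsets[q] + stim_dur - 1e-9) {
        stim_on = true;
        break;
      }
    }

    if (diffusion_on) {
      for (int a = 0; a < na; ++a) {
        int i = act[a];
        const int* nbi = nb + 4 * (size_t)i;
        const double* wi = w + 4 * (size_t)i;
        double vi = V[i], acc = 0.0;
        for (int q = 0; q < 4; ++q) {
          int jn = nbi[q];
          if (jn >= 0) acc += wi[q] * (V[jn] - vi);
        }
        dvd[a] = acc;
      }
    }

    double vmax = -1e30;
    double tnew = t0 + (step + 1) * dt;
    for (int a = 0; a < na; ++a) {
      int i = act[a];
      double istim = (stim_on && is_stim[i]) ? stim_amp : 0.0;
      double extra = (diffusion_on ? dvd[a] : 0.0) + istim;
      double vold = V[i];
      double vnew;
      if (reaction_on) {
        double E[4] = {EK[i], ENa[i], EKs[i], ECa[i]};
        vnew = advance_node(V[i], &S[(size_t)i * (NSTATE - 1)], T,
                            gna_p[i], gkr_p[i], gks_p[i], extra, istim, E);
      } else {
        vnew = vold + dt * extra;
        V[i] = vnew;
      }
      if (!R_finite(vnew) || fabs(vnew) > 200.0) {
        if (bad_node < 0) { bad_node = i; bad_t = tnew; }
      }
      if (vnew > vmax) vmax = vnew;
      if (vold < up_thresh && vnew >= up_thresh) {
        if (up_count[i] < max_cross) {
          double tc = t + dt * (up_thresh - vold) / (vnew - vold);
          cr_node.push_back(i);
          cr_time.push_back(tc);
          cr_dir.push_back(1);
        }
        up_count[i]++;
        if (is_stop[i] && !R_finite(stop_at)) stop_at = tnew + stop_delay;
      } else if (vold > rep_thresh && vnew <= rep_thresh) {
        if (down_count[i] < max_cross) {
          double tc = t + dt * (rep_thresh - vold) / (vnew - vold);
          cr_node.push_back(i);
          cr_time.push_back(tc);
          cr_dir.push_back(-1);
        }
        down_count[i]++;
      }
    }

    if (bad_node >= 0) {
      reason = "unstable";
      t_stop = tnew;
      break;
    }

    if (npr > 0 && (step + 1) % pstride == 0) {
      probe_t.push_back(tnew);
      for (int q = 0; q < npr; ++q) probe_v.push_back(V[probe_nodes[q]]);
    }
    if (sstride > 0 && (step + 1) % sstride == 0) {
      NumericVector sv(V.begin(), V.end());
      snaps.push_back(sv);
      snap_t.push_back(tnew);
    }

    if (tnew >= stop_at) {
      reason = "stop_node";
      t_stop = tnew;
      break;
    }
    if (quiet_stop && tnew > quiet_min_t && tnew > last_stim_end &&
        vmax < quiet_level) {
      bool pending = false;
      for (int q = 0; q < nstim; ++q)
        if (stim_onsets[q] > tnew) { pending = true; break; }
      if (!pending) {
        reason = "quiescent";
        t_stop = tnew;
        break;
      }
    }
  }
  if (step == nstep) t_stop = t_end;

  NumericVector Vf(V.begin(), V.end());
  NumericMatrix Sf(NSTATE - 1, n);
  std::copy(S.begin(), S.end(), Sf.begin());

  NumericMatrix PV(npr, (int)probe_t.size());
  for (size_t c = 0; c < probe_t.size(); ++c)
    for (int q = 0; q < npr; ++q) PV(q, (int)c) = probe_v[c * npr + q];

  IntegerVector crn(cr_node.begin(), cr_node.end());
  for (R_xlen_t q = 0; q < crn.size(); ++q) crn[q] += 1;  // 1-based for R

  List out = List::create(
      _["probe_t"] = wrap(probe_t), _["probe_v"] = PV,
      _["cross_node"] = crn, _["cross_time"] = wrap(cr_time),
      _["cross_dir"] = wrap(cr_dir),
      _["up_count"] = wrap(up_count), _["down_count"] = wrap(down_count),
      _["V"] = Vf, _["S18"] = Sf, _["t_stop"] = t_stop,
      _["reason"] = reason,
      _["snap_t"] = wrap(snap_t), _["snapshots"] = wrap(snaps));
  if (bad_node >= 0) {
    out["bad_node"] = bad_node + 1;
    out["bad_t"] = bad_t;
  }
  return out;
}
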