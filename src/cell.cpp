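// Single-cell (space-clamped) integration of the TT06 endocardial model.
#include <Rcpp.h>
#include "tt06core.h"

using namespace Rcpp;
using namespace tt06;

// [[Rcpp::export]]
NumericVector tt06_init_state_cpp() {
  NumericVector out(NSTATE);
  initial_state(REAL(out));
  CharacterVector nm(NSTATE);
  for (int k = 0; k < NSTATE; ++k) nm[k] = state_name(k);
  out.attr("names") = nm;
  return out;
}

// [[Rcpp::export]]
CharacterVector tt06_state_names_cpp() {
  CharacterVector nm(NSTATE);
  for (int k = 0; k < NSTATE; ++k) nm[k] = state_name(k);
  return nm;
}

static void check_state(const double* s, double t) {
  for (int k = 0; k < NSTATE; ++k) {
    if (!R_finite(s[k]))
      stop("integration failure at t = %.3f ms: state variable '%s' is non-finite",
           t, state_name(k));
  }
}

// Advance a single cell. Stimulus pulses of amplitude stim_amp (pA/pF,
// depolarizing positive) and duration stim_dur start at stim_onsets (ms,
// absolute). Records (t, vm) every sample_dt from t0. Returns the trace and
// the final state.
// [[Rcpp::export]]
List cell_run_cpp(NumericVector state0, double gna_m, double gkr_m,
                  double gks_m, NumericVector stim_onsets, double stim_dur,
                  double stim_amp, double dt, double t0, double t_end,
                  double sample_dt) {
  if (state0.size() != NSTATE) stop("state must have %d entries", NSTATE);
  if (dt <= 0 || dt > 0.1) stop("dt must lie in (0, 0.1] ms");
  double s[NSTATE];
  for (int k = 0; k < NSTATE; ++k) s[k] = state0[k];
  check_state(s, t0);

  Tables T;
  T.build(dt);
  long nstep = (long)llround((t_end - t0) / dt);
  int sstride = sample_dt > 0 ? (int)llround(sample_dt / dt) : 0;
  if (sstride < 1) sstride = nstep + 1;

  std::vector<double> tr_t, tr_v;
  tr_t.reserve(nstep / sstride + 2);
  tr_v.reserve(nstep / sstride + 2);
  tr_t.push_back(t0);
  tr_v.push_back(s[iV]);

  double E[4];
  reversals(s, E);
  int nstim = stim_onsets.size();

  for (long step = 0; step < nstep; ++step) {
    double t = t0 + step * dt;
    double istim = 0.0;
    for (int q = 0; q < nstim; ++q) {
      if (t >= stim_onsets[q] - 1e-9 && t < stim_onsets[q] + stim_dur - 1e-9) {
        istim = stim_amp;
        break;
      }
    }
    if (step % 10 == 0) reversals(s, E);
    advance_node(s[iV], s + 1, T, gna_m, gkr_m, gks_m, istim, istim, E);
    if (!R_finite(s[iV]) || fabs(s[iV]) > 200.0) check_state(s, t + dt);
    if ((step + 1) % sstride == 0) {
      tr_t.push_back(t0 + (step + 1) * dt);
      tr_v.push_back(s[iV]);
    }
  }
  check_state(s, t_end);

  NumericVector fin(NSTATE);
  for (int k = 0; k < NSTATE; ++k) fin[k] = s[k];
  CharacterVector nm(NSTATE);
  for (int k = 0; k < NSTATE; ++k) nm[k] = state_name(k);
  fin.attr("names") = nm;

  return List::create(_["time_ms"] = wrap(tr_t), _["vm_mV"] = wrap(tr_v),
                      _["state"] = fin);
}

// n identical explicit steps at constant stimulus; the step primitive.
// [[Rcpp::export]]
NumericVector cell_steps_cpp(NumericVector state0, double gna_m, double gkr_m,
                             double gks_m, double istim, double dt, int nsteps) {
  if (state0.size() != NSTATE) stop("state must have %d entries", NSTATE);
  if (dt <= 0 || dt > 0.1) stop("dt must lie in (0, 0.1] ms");
  double s[NSTATE];
  for (int k = 0; k < NSTATE; ++k) s[k] = state0[k];
  check_state(s, 0.0);
  Tables T;
  T.build(dt);
  double E[4];
  for (int step = 0; step < nsteps; ++step) {
    reversals(s, E);
    advance_node(s[iV], s + 1, T, gna_m, gkr_m, gks_m, istim, istim, E);
    if (!R_finite(s[iV]) || fabs(s[iV]) > 200.0) check_state(s, (step + 1) * dt);
  }
  check_state(s, nsteps * dt);
  NumericVector fin(NSTATE);
  for (int k = 0; k < NSTATE; ++k) fin[k] = s[k];
  CharacterVector nm(NSTATE);
  for (int k = 0; k < NSTATE; ++k) nm[k] = state_name(k);
  fin.attr("names") = nm;
  return fin;
}

// Instantaneous ionic current components for a given state (diagnostics and
// the identity-scaling contract).
// [[Rcpp::export]]
NumericVector tt06_currents_cpp(NumericVector state, double gna_m,
                                double gkr_m, double gks_m) {
  if (state.size() != NSTATE) stop("state must have %d entries", NSTATE);
  const double* s = REAL(state);
  double V = s[iV];
  double E[4];
  reversals(s, E);
  double EK = E[0], ENa = E[1], EKs = E[2], ECa = E[3];
  double c1, c2;
  cal_coef(V, c1, c2);
  double n1, n2;
  ncx_coef(V, n1, n2);

  double INa = GNa * gna_m * s[iM] * s[iM] * s[iM] * s[iH] * s[iJ] * (V - ENa);
  double ICaL = s[iD] * s[iF] * s[iF2] * s[iFCaSS] * (c2 * s[iCaSS] - c1 * Cao);
  double Ito = Gto * s[iR] * s[iS] * (V - EK);
  double IKr = GKr * gkr_m * s[iXr1] * s[iXr2] * (V - EK);
  double IKs = GKs * gks_m * s[iXs] * s[iXs] * (V - EKs);
  double IK1 = GK1 * xk1_inf(V - EK) * (V - EK);
  double INaCa = n1 * s[iNai] * s[iNai] * s[iNai] - n2 * s[iCai];
  double INaK = nak_coef(V) * s[iNai] / (s[iNai] + KmNa);
  double IpCa = GpCa * s[iCai] / (s[iCai] + KpCa);
  double IpK = ipk_coef(V) * (V - EK);
  double IbNa = GbNa * (V - ENa);
  double IbCa = GbCa * (V - ECa);

  NumericVector out = NumericVector::create(
      _["INa"] = INa, _["ICaL"] = ICaL, _["Ito"] = Ito, _["IKr"] = IKr,
      _["IKs"] = IKs, _["IK1"] = IK1, _["INaCa"] = INaCa, _["INaK"] = INaK,
      _["IpCa"] = IpCa, _["IpK"] = IpK, _["IbNa"] = IbNa, _["IbCa"] = IbCa);
  return out;
}
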