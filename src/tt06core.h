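// ten Tusscher-Panfilov (2006) human ventricular membrane model,
// endocardial parameter set. Voltage in mV, time in ms, currents in pA/pF,
// concentrations in mM. Gate updates use Rush-Larsen coefficients tabulated
// on a voltage grid at fixed dt; concentrations advance by forward Euler.
#ifndef TT06CORE_H
#define TT06CORE_H

#include <cmath>
#include <vector>
#include <string>

namespace tt06 {

// physical constants
const double Rgas = 8314.472;    // mJ/(mol K)
const double Temp = 310.0;       // K
const double Frdy = 96485.3415;  // C/mol
const double RTF  = Rgas * Temp / Frdy;  // mV
const double FRT  = 1.0 / RTF;

// external concentrations (mM)
const double Ko  = 5.4;
const double Nao = 140.0;
const double Cao = 2.0;

// volumes (um^3 scaled) and capacitance scaling of the concentration updates
const double Vc  = 0.016404;
const double Vsr = 0.001094;
const double Vss = 0.00005468;
const double Cap = 0.185;

// buffering
const double Bufc  = 0.2,  Kbufc  = 0.001;
const double Bufsr = 10.0, Kbufsr = 0.3;
const double Bufss = 0.4,  Kbufss = 0.00025;

// SR calcium handling
const double Vmaxup = 0.006375, Kup = 0.00025;
const double Vrel = 0.102, Vleak = 0.00036, Vxfer = 0.0038;
const double k1p = 0.15, k2p = 0.045, k3r = 0.060, k4r = 0.005;
const double ECsr = 1.5, maxsr = 2.5, minsr = 1.0;

// maximal conductances / pump rates (endocardial cell)
const double GNa = 14.838, GK1 = 5.405, Gto = 0.073;
const double GKr = 0.153, GKs = 0.392;
const double GCaL = 0.0000398, GbNa = 0.00029, GbCa = 0.000592;
const double GpCa = 0.1238, KpCa = 0.0005, GpK = 0.0146;
const double pKNa = 0.03;
const double PNaK = 2.724, KmK = 1.0, KmNa = 40.0;
const double kNaCa = 1000.0, ksat = 0.1, alpha_ncx = 2.5, gamma_ncx = 0.35;
const double KmNai = 87.5, KmCa = 1.38;

// state vector layout: V first, then the eta vector
enum StateIdx { iV = 0, iM, iH, iJ, iD, iF, iF2, iFCaSS, iR, iS,
                iXr1, iXr2, iXs, iRq, iCai, iCaSS, iCaSR, iNai, iKi,
                NSTATE };

inline const char* state_name(int k) {
  static const char* nm[NSTATE] = {
    "vm", "m", "h", "j", "d", "f", "f2", "fcass", "r", "s",
    "xr1", "xr2", "xs", "rbar", "cai", "cass", "casr", "nai", "ki" };
  return nm[k];
}

// published initial conditions (quiescent model, endocardial)
inline void initial_state(double* s) {
  s[iV] = -86.2; s[iM] = 0.0; s[iH] = 0.75; s[iJ] = 0.75;
  s[iD] = 0.0; s[iF] = 1.0; s[iF2] = 1.0; s[iFCaSS] = 1.0;
  s[iR] = 0.0; s[iS] = 1.0; s[iXr1] = 0.0; s[iXr2] = 1.0; s[iXs] = 0.0;
  s[iRq] = 1.0; s[iCai] = 0.00007; s[iCaSS] = 0.00007; s[iCaSR] = 1.3;
  s[iNai] = 7.67; s[iKi] = 138.3;
}

// steady-state activation/time constants of the 11 voltage gates,
// order: m h j d f f2 r s xr1 xr2 xs
const int NGATE = 11;
inline void gate_inf_tau(double V, double* inf, double* tau) {
  // INa gates
  double minf = 1.0 / pow(1.0 + exp((-56.86 - V) / 9.03), 2);
  double am = 1.0 / (1.0 + exp((-60.0 - V) / 5.0));
  double bm = 0.1 / (1.0 + exp((V + 35.0) / 5.0)) +
              0.1 / (1.0 + exp((V - 50.0) / 200.0));
  inf[0] = minf; tau[0] = am * bm;

  double hinf = 1.0 / pow(1.0 + exp((V + 71.55) / 7.43), 2);
  double ah, bh;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1)));
  } else {
    ah = 0.057 * exp(-(V + 80.0) / 6.8);
    bh = 2.7 * exp(0.079 * V) + 310000.0 * exp(0.3485 * V);
  }
  inf[1] = hinf; tau[1] = 1.0 / (ah + bh);

  double aj, bj;
  if (V >= -40.0) {
    aj = 0.0;
    bj = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
  } else {
    aj = (-25428.0 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
    bj = 0.02424 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
  }
  inf[2] = hinf; tau[2] = 1.0 / (aj + bj);

  // ICaL gates
  inf[3] = 1.0 / (1.0 + exp((-8.0 - V) / 7.5));
  double ad = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
  double bd = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
  double cd = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
  tau[3] = ad * bd + cd;

  inf[4] = 1.0 / (1.0 + exp((V + 20.0) / 7.0));
  double af = 1102.5 * exp(-pow(V + 27.0, 2) / 225.0);
  double bf = 200.0 / (1.0 + exp((13.0 - V) / 10.0));
  double cf = 180.0 / (1.0 + exp((V + 30.0) / 10.0)) + 20.0;
  tau[4] = af + bf + cf;

  inf[5] = 0.67 / (1.0 + exp((V + 35.0) / 7.0)) + 0.33;
  double af2 = 562.0 * exp(-pow(V + 27.0, 2) / 240.0);
  double bf2 = 31.0 / (1.0 + exp((25.0 - V) / 10.0));
  double cf2 = 80.0 / (1.0 + exp((V + 30.0) / 10.0));
  tau[5] = af2 + bf2 + cf2;

  // Ito gates (s uses the endocardial formulation)
  inf[6] = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
  tau[6] = 9.5 * exp(-pow(V + 40.0, 2) / 1800.0) + 0.8;

  inf[7] = 1.0 / (1.0 + exp((V + 28.0) / 5.0));
  tau[7] = 1000.0 * exp(-pow(V + 67.0, 2) / 1000.0) + 8.0;

  // IKr gates
  inf[8] = 1.0 / (1.0 + exp((-26.0 - V) / 7.0));
  double axr1 = 450.0 / (1.0 + exp((-45.0 - V) / 10.0));
  double bxr1 = 6.0 / (1.0 + exp((V + 30.0) / 11.5));
  tau[8] = axr1 * bxr1;

  inf[9] = 1.0 / (1.0 + exp((V + 88.0) / 24.0));
  double axr2 = 3.0 / (1.0 + exp((-60.0 - V) / 20.0));
  double bxr2 = 1.12 / (1.0 + exp((V - 60.0) / 20.0));
  tau[9] = axr2 * bxr2;

  // IKs gate
  inf[10] = 1.0 / (1.0 + exp((-5.0 - V) / 14.0));
  double axs = 1400.0 / sqrt(1.0 + exp((5.0 - V) / 6.0));
  double bxs = 1.0 / (1.0 + exp((V - 35.0) / 15.0));
  tau[10] = axs * bxs + 80.0;
}

// ICaL driving-force coefficients: ICaL = d*f*f2*fCaSS*(c2*CaSS - c1*Cao)
inline void cal_coef(double V, double& c1, double& c2) {
  double x = 2.0 * (V - 15.0) * FRT;
  double ex = exp(x);
  if (fabs(x) < 1e-5) {
    c1 = GCaL * 2.0 * Frdy / (1.0 + 0.5 * x);  // series limit at V = 15 mV
  } else {
    c1 = GCaL * 4.0 * (V - 15.0) * Frdy * FRT / (ex - 1.0);
  }
  c2 = c1 * 0.25 * ex;
}

// INaK voltage factor: INaK = nak(V) * Nai/(Nai + KmNa)
inline double nak_coef(double V) {
  return PNaK * (Ko / (Ko + KmK)) /
         (1.0 + 0.1245 * exp(-0.1 * V * FRT) + 0.0353 * exp(-V * FRT));
}

// INaCa coefficients: INaCa = c1*Nai^3 - c2*Cai
inline void ncx_coef(double V, double& c1, double& c2) {
  double e1 = exp(gamma_ncx * V * FRT);
  double e2 = exp((gamma_ncx - 1.0) * V * FRT);
  double den = (KmNai * KmNai * KmNai + Nao * Nao * Nao) *
               (KmCa + Cao) * (1.0 + ksat * e2);
  c1 = kNaCa * e1 * Cao / den;
  c2 = kNaCa * e2 * Nao * Nao * Nao * alpha_ncx / den;
}

// IK1 inward-rectification factor as a function of V - EK
inline double xk1_inf(double x) {
  double a = 0.1 / (1.0 + exp(0.06 * (x - 200.0)));
  double b = (3.0 * exp(0.0002 * (x + 100.0)) + exp(0.1 * (x - 10.0))) /
             (1.0 + exp(-0.5 * x));
  return a / (a + b);
}

inline double ipk_coef(double V) {
  return GpK / (1.0 + exp((25.0 - V) / 5.98));
}

// Tabulated coefficients at a fixed dt. Per voltage sample, contiguous:
// 22 Rush-Larsen pairs (A, B per gate), then cal1 cal2 nak ncx1 ncx2 ipk.
const int TROW = 2 * NGATE + 6;
struct Tables {
  double dt;
  int n;
  double vmin, dv, inv_dv, vtop;
  std::vector<double> g;
  int nx;
  double xmin, dx, inv_dx, xtop;
  std::vector<double> xk1;

  void build(double dt_, double vmin_ = -110.0, double vmax_ = 90.0,
             double dv_ = 0.05) {
    dt = dt_;
    vmin = vmin_; dv = dv_; inv_dv = 1.0 / dv_;
    n = (int)floor((vmax_ - vmin_) / dv_) + 1;
    vtop = vmin + (n - 2) * dv;  // clamp limit for interpolation
    g.assign((size_t)n * TROW, 0.0);
    double inf[NGATE], tau[NGATE];
    for (int i = 0; i < n; ++i) {
      double V = vmin + i * dv;
      double* row = &g[(size_t)i * TROW];
      gate_inf_tau(V, inf, tau);
      for (int q = 0; q < NGATE; ++q) {
        double A = exp(-dt / tau[q]);
        row[2 * q] = A;
        row[2 * q + 1] = inf[q] * (1.0 - A);
      }
      double c1, c2;
      cal_coef(V, c1, c2);
      row[22] = c1; row[23] = c2;
      row[24] = nak_coef(V);
      ncx_coef(V, c1, c2);
      row[25] = c1; row[26] = c2;
      row[27] = ipk_coef(V);
    }
    xmin = -60.0; dx = 0.1; inv_dx = 10.0;
    nx = (int)floor((220.0 - xmin) / dx) + 1;
    xtop = xmin + (nx - 2) * dx;
    xk1.assign(nx, 0.0);
    for (int i = 0; i < nx; ++i) xk1[i] = xk1_inf(xmin + i * dx);
  }

  inline double xk1_at(double x) const {
    double u = (x - xmin) * inv_dx;
    if (u < 0.0) u = 0.0;
    double umax = (double)(nx - 2);
    if (u > umax) u = umax;
    int i0 = (int)u;
    double w = u - i0;
    return xk1[i0] + (xk1[i0 + 1] - xk1[i0]) * w;
  }
};

// reversal potentials from intracellular concentrations
inline void reversals(const double* s, double* E) {
  E[0] = RTF * log(Ko / s[iKi]);                                   // EK
  E[1] = RTF * log(Nao / s[iNai]);                                 // ENa
  E[2] = RTF * log((Ko + pKNa * Nao) / (s[iKi] + pKNa * s[iNai])); // EKs
  E[3] = 0.5 * RTF * log(Cao / s[iCai]);                           // ECa
}

// Advance one state (V in vref, remaining 18 states in s starting at index
// iM-1 == 0) by one step. extra = diffusion + stimulus contribution to
// dV/dt (mV/ms); istim is the stimulus alone (needed for the Ki update).
// E = cached reversal potentials {EK, ENa, EKs, ECa}. Returns new V.
inline double advance_node(double& Vref, double* s, const Tables& T,
                           double gna_m, double gkr_m, double gks_m,
                           double extra, double istim, const double* E) {
  double V = Vref;
  double Vc_ = V < T.vmin ? T.vmin : (V > T.vtop ? T.vtop : V);
  double u = (Vc_ - T.vmin) * T.inv_dv;
  int i0 = (int)u;
  double w = u - i0;
  const double* a = &T.g[(size_t)i0 * TROW];
  const double* b = a + TROW;
#define TT06_LERP(q) (a[q] + (b[q] - a[q]) * w)

  // ionic currents from the current state
  double EK = E[0], ENa = E[1], EKs = E[2], ECa = E[3];
  double m = s[iM - 1], h = s[iH - 1], j = s[iJ - 1];
  double d = s[iD - 1], f = s[iF - 1], f2 = s[iF2 - 1], fca = s[iFCaSS - 1];
  double r = s[iR - 1], sg = s[iS - 1];
  double xr1 = s[iXr1 - 1], xr2 = s[iXr2 - 1], xs = s[iXs - 1];
  double Rq = s[iRq - 1];
  double Cai = s[iCai - 1], CaSS = s[iCaSS - 1], CaSR = s[iCaSR - 1];
  double Nai = s[iNai - 1], Ki = s[iKi - 1];
  (void)Ki;

  double INa = GNa * gna_m * m * m * m * h * j * (V - ENa);
  double ICaL = d * f * f2 * fca * (TT06_LERP(23) * CaSS - TT06_LERP(22) * Cao);
  double Ito = Gto * r * sg * (V - EK);
  double IKr = GKr * gkr_m * xr1 * xr2 * (V - EK);
  double IKs = GKs * gks_m * xs * xs * (V - EKs);
  double IK1 = GK1 * T.xk1_at(V - EK) * (V - EK);
  double INaCa = TT06_LERP(25) * Nai * Nai * Nai - TT06_LERP(26) * Cai;
  double INaK = TT06_LERP(24) * Nai / (Nai + KmNa);
  double IpCa = GpCa * Cai / (Cai + KpCa);
  double IpK = TT06_LERP(27) * (V - EK);
  double IbNa = GbNa * (V - ENa);
  double IbCa = GbCa * (V - ECa);

  double Iion = INa + ICaL + Ito + IKr + IKs + IK1 + INaCa + INaK +
                IpCa + IpK + IbNa + IbCa;

  // Rush-Larsen gate updates (exact exponential toward tabulated target)
  s[iM - 1]   = m * TT06_LERP(0) + TT06_LERP(1);
  s[iH - 1]   = h * TT06_LERP(2) + TT06_LERP(3);
  s[iJ - 1]   = j * TT06_LERP(4) + TT06_LERP(5);
  s[iD - 1]   = d * TT06_LERP(6) + TT06_LERP(7);
  s[iF - 1]   = f * TT06_LERP(8) + TT06_LERP(9);
  s[iF2 - 1]  = f2 * TT06_LERP(10) + TT06_LERP(11);
  s[iR - 1]   = r * TT06_LERP(12) + TT06_LERP(13);
  s[iS - 1]   = sg * TT06_LERP(14) + TT06_LERP(15);
  s[iXr1 - 1] = xr1 * TT06_LERP(16) + TT06_LERP(17);
  s[iXr2 - 1] = xr2 * TT06_LERP(18) + TT06_LERP(19);
  s[iXs - 1]  = xs * TT06_LERP(20) + TT06_LERP(21);
#undef TT06_LERP

  // CaSS-gated inactivation (non-stiff; forward Euler)
  double xca = (CaSS / 0.05) * (CaSS / 0.05);
  double fca_inf = 0.6 / (1.0 + xca) + 0.4;
  double tau_fca = 80.0 / (1.0 + xca) + 2.0;
  s[iFCaSS - 1] = fca + T.dt * (fca_inf - fca) / tau_fca;

  // SR release machinery
  double kcasr = maxsr - (maxsr - minsr) / (1.0 + (ECsr / CaSR) * (ECsr / CaSR));
  double k1 = k1p / kcasr;
  double k2 = k2p * kcasr;
  s[iRq - 1] = Rq + T.dt * (k4r * (1.0 - Rq) - k2 * CaSS * Rq);
  double O = k1 * CaSS * CaSS * Rq / (k3r + k1 * CaSS * CaSS);
  double Irel = Vrel * O * (CaSR - CaSS);
  double Ileak = Vleak * (CaSR - Cai);
  double Iup = Vmaxup / (1.0 + (Kup * Kup) / (Cai * Cai));
  double Ixfer = Vxfer * (CaSS - Cai);

  // concentrations (forward Euler on free concentrations with
  // instantaneous-buffer factors)
  double bc = 1.0 / (1.0 + Bufc * Kbufc / ((Cai + Kbufc) * (Cai + Kbufc)));
  double bsr = 1.0 / (1.0 + Bufsr * Kbufsr / ((CaSR + Kbufsr) * (CaSR + Kbufsr)));
  double bss = 1.0 / (1.0 + Bufss * Kbufss / ((CaSS + Kbufss) * (CaSS + Kbufss)));
  double i2vcf = Cap / (2.0 * Vc * Frdy);
  double ivcf = Cap / (Vc * Frdy);
  double i2vssf = Cap / (2.0 * Vss * Frdy);

  s[iCai - 1] = Cai + T.dt * bc *
      (-(IbCa + IpCa - 2.0 * INaCa) * i2vcf - (Iup - Ileak) * (Vsr / Vc) + Ixfer);
  s[iCaSR - 1] = CaSR + T.dt * bsr * (Iup - Irel - Ileak);
  s[iCaSS - 1] = CaSS + T.dt * bss *
      (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) - ICaL * i2vssf);
  s[iNai - 1] = Nai + T.dt * (-(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * ivcf);
  s[iKi - 1] = Ki + T.dt *
      (-(-istim + IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK) * ivcf);

  double Vnew = V + T.dt * (extra - Iion);
  Vref = Vnew;
  return Vnew;
}

}  // namespace tt06

#endif
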