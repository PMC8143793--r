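// Courtemanche-Ramirez-Nattel (1998) human atrial action-potential model
// with multiplicative conductance scalings on I_Na, I_K1, I_to, I_Kur, I_CaL
// (remodeling variants), Rush-Larsen integration with optional tabulated
// voltage-dependent rates, and a classical RK4 reference integrator.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace crn {

// physical constants and model parameters (units: mV, ms, pA/pF, mM, um^3)
const double Rgas = 8.3143, Temp = 310.0, Far = 96.4867;
const double RTF = Rgas * Temp / Far;            // ~26.713 mV
const double CmPF = 100.0;                       // cell capacitance, pF
const double Vi = 13668.0, Vup = 1109.52, Vrel = 96.48;
const double Ko = 5.4, Nao = 140.0, Cao = 1.8;
const double gNa = 7.8, gK1 = 0.09, gto = 0.1652;
const double gKr = 0.0294117649, gKs = 0.12941176, gCaL = 0.12375;
const double gbCa = 0.001131, gbNa = 0.0006744375;
const double INaKmax = 0.59933874, INaCamax = 1600.0, IpCamax = 0.275;
const double Iupmax = 0.005, KQ10 = 3.0, gam = 0.35;
const double KmNai = 10.0, KmKo = 1.5, KmNa = 87.5, KmCa = 1.38, ksat = 0.1;
const double krel = 30.0, kup = 0.00092, Caupmax = 15.0;
const double Cmdnmax = 0.05, Trpnmax = 0.07, Csqnmax = 10.0;
const double KmCmdn = 0.00238, KmTrpn = 0.0005, KmCsqn = 0.8;
const double tautr = 180.0, taufca = 2.0, tauu = 8.0;
const double sigNaK = (std::exp(Nao / 67.3) - 1.0) / 7.0;

// state layout
enum { iV = 0, im, ih, ij, ioa, ioi, iua, iui, ixr, ixs, id_, if_, ifca,
       iu, iv, iw, iNai, iKi, iCai, iCaup, iCarel, NSTATE };
const int NG = 12; // V-dependent gates: m h j oa oi ua ui xr xs d f w

struct Scales { double na, k1, to, kur, cal; };

inline double sigm(double x) {
  if (x > 35.0) return 1.0;
  if (x < -35.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// steady states and time constants of the 12 voltage-dependent gates
inline void gate_rates(double V, double* inf, double* tau) {
  double a, b;
  // m
  a = (std::fabs(V + 47.13) < 1e-10) ? 3.2
      : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  b = 0.08 * std::exp(-V / 11.0);
  inf[0] = a / (a + b); tau[0] = 1.0 / (a + b);
  // h, j (Luo-Rudy style piecewise)
  if (V >= -40.0) {
    a = 0.0;
    b = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    inf[1] = 0.0; tau[1] = 1.0 / b;
    a = 0.0;
    b = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    inf[2] = 0.0; tau[2] = 1.0 / b;
  } else {
    a = 0.135 * std::exp(-(V + 80.0) / 6.8);
    b = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    inf[1] = a / (a + b); tau[1] = 1.0 / (a + b);
    a = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V))
        * (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    b = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
    inf[2] = a / (a + b); tau[2] = 1.0 / (a + b);
  }
  // oa, oi (Ito)
  a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  tau[3] = 1.0 / ((a + b) * KQ10);
  inf[3] = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  double aoa = a, boa = b;
  a = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  b = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  tau[4] = 1.0 / ((a + b) * KQ10);
  inf[4] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  // ua, ui (IKur); ua shares alpha/beta with oa
  tau[5] = 1.0 / ((aoa + boa) * KQ10);
  inf[5] = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  a = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  b = std::exp((V - 158.0) / 16.0);
  tau[6] = 1.0 / ((a + b) * KQ10);
  inf[6] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  // xr
  a = (std::fabs(V + 14.1) < 1e-10) ? 0.0015
      : 0.0003 * (V + 14.1) / (1.0 - std::exp(-(V + 14.1) / 5.0));
  b = (std::fabs(V - 3.3328) < 1e-10) ? 3.7836118e-4
      : 7.3898e-5 * (V - 3.3328) / (std::exp((V - 3.3328) / 5.1237) - 1.0);
  tau[7] = 1.0 / (a + b);
  inf[7] = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
  // xs
  a = (std::fabs(V - 19.9) < 1e-10) ? 0.00068
      : 4e-5 * (V - 19.9) / (1.0 - std::exp(-(V - 19.9) / 17.0));
  b = (std::fabs(V - 19.9) < 1e-10) ? 0.000315
      : 3.5e-5 * (V - 19.9) / (std::exp((V - 19.9) / 9.0) - 1.0);
  tau[8] = 0.5 / (a + b);
  inf[8] = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
  // d
  inf[9] = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  if (std::fabs(V + 10.0) < 1e-10) {
    tau[9] = 1.0 / (0.035 * 6.24 * 2.0);
  } else {
    double e = std::exp(-(V + 10.0) / 6.24);
    tau[9] = (1.0 - e) / (0.035 * (V + 10.0) * (1.0 + e));
  }
  // f
  inf[10] = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  tau[10] = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
  // w
  inf[11] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
  if (std::fabs(V - 7.9) < 1e-10) {
    tau[11] = 6.0 * 0.2 / 1.3;
  } else {
    double e = std::exp(-(V - 7.9) / 5.0);
    tau[11] = 6.0 * (1.0 - e) / ((1.0 + 0.3 * e) * (V - 7.9));
  }
}

// voltage-dependent current factors that do not depend on gating state
struct VFactors { double ik1r, gkurv, ikrr, fnak, e1, e2; };
inline void volt_factors(double V, VFactors& f) {
  f.ik1r  = 1.0 / (1.0 + std::exp(0.07 * (V + 80.0)));
  f.gkurv = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
  f.ikrr  = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));
  f.fnak  = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF)
                       + 0.0365 * sigNaK * std::exp(-V / RTF));
  f.e1 = std::exp(gam * V / RTF);
  f.e2 = std::exp((gam - 1.0) * V / RTF);
}

// lookup tables over V for the Rush-Larsen step at a fixed dt;
// rows of NREC doubles per grid point (interleaved for cache locality):
// inf[0..11], rex[0..11], ik1r, gkurv, ikrr, fnak, e1, e2
struct VTab {
  static const int NREC = 2 * NG + 6;
  double dt = -1.0;
  double vmin = -110.0, vmax = 80.0, dv = 0.02, invdv;
  int n = 0;
  std::vector<double> data;
  double reu = 0.0, refca = 0.0;   // exp(-dt/tau) for constant-tau gates
  void build(double dt_) {
    dt = dt_;
    reu = std::exp(-dt / tauu);
    refca = std::exp(-dt / taufca);
    n = (int)std::floor((vmax - vmin) / dv) + 2;
    invdv = 1.0 / dv;
    data.assign((size_t)n * NREC, 0.0);
    double gi[NG], gt[NG]; VFactors f;
    for (int k = 0; k < n; ++k) {
      double V = vmin + k * dv;
      double* row = &data[(size_t)k * NREC];
      gate_rates(V, gi, gt);
      for (int g = 0; g < NG; ++g) {
        row[g] = gi[g];
        row[NG + g] = std::exp(-dt / gt[g]);
      }
      volt_factors(V, f);
      row[2 * NG + 0] = f.ik1r; row[2 * NG + 1] = f.gkurv;
      row[2 * NG + 2] = f.ikrr; row[2 * NG + 3] = f.fnak;
      row[2 * NG + 4] = f.e1;   row[2 * NG + 5] = f.e2;
    }
  }
};
static VTab g_tab;

// When true, the stimulus current is booked as a K+ influx in the Ki
// balance (charge-conservative pacing); this removes the slow ionic drift
// that periodic charge injection otherwise causes.
static bool g_stim_in_ki = true;

// one Rush-Larsen / forward-Euler reaction step; updates y in place,
// returns dV/dt (mV/ms) from ionic currents + stimulus (V update applied)
inline double react_step(double* y, const Scales& s, double dt, double istim,
                         bool use_tab) {
  double V = y[iV];
  double gi[NG], gre[NG];
  VFactors vf;
  if (use_tab && V >= g_tab.vmin && V <= g_tab.vmax) {
    double x = (V - g_tab.vmin) * g_tab.invdv;
    int k = (int)x;
    double w1 = x - k, w0 = 1.0 - w1;
    const int NREC = VTab::NREC;
    const double* r0 = &g_tab.data[(size_t)k * NREC];
    const double* r1 = r0 + NREC;
    for (int g = 0; g < NG; ++g) {
      gi[g]  = w0 * r0[g] + w1 * r1[g];
      gre[g] = w0 * r0[NG + g] + w1 * r1[NG + g];
    }
    vf.ik1r  = w0 * r0[2 * NG + 0] + w1 * r1[2 * NG + 0];
    vf.gkurv = w0 * r0[2 * NG + 1] + w1 * r1[2 * NG + 1];
    vf.ikrr  = w0 * r0[2 * NG + 2] + w1 * r1[2 * NG + 2];
    vf.fnak  = w0 * r0[2 * NG + 3] + w1 * r1[2 * NG + 3];
    vf.e1    = w0 * r0[2 * NG + 4] + w1 * r1[2 * NG + 4];
    vf.e2    = w0 * r0[2 * NG + 5] + w1 * r1[2 * NG + 5];
  } else {
    double gt[NG];
    gate_rates(V, gi, gt);
    for (int g = 0; g < NG; ++g) gre[g] = std::exp(-dt / gt[g]);
    volt_factors(V, vf);
  }
  // Rush-Larsen update of V-dependent gates (m..f contiguous; w separate)
  double* gate = y + im;
  for (int g = 0; g < NG - 1; ++g) gate[g] = gi[g] + (gate[g] - gi[g]) * gre[g];
  y[iw] = gi[11] + (y[iw] - gi[11]) * gre[11];

  double m = y[im], h = y[ih], j = y[ij];
  double Nai = y[iNai], Ki = y[iKi], Cai = y[iCai];
  double ENa = RTF * std::log(Nao / Nai);
  double EK  = RTF * std::log(Ko / Ki);
  double ECa = 0.5 * RTF * std::log(Cao / Cai);

  double INa  = s.na * gNa * m * m * m * h * j * (V - ENa);
  double IK1  = s.k1 * gK1 * (V - EK) * vf.ik1r;
  double Ito  = s.to * gto * y[ioa] * y[ioa] * y[ioa] * y[ioi] * (V - EK);
  double IKur = s.kur * vf.gkurv * y[iua] * y[iua] * y[iua] * y[iui] * (V - EK);
  double IKr  = gKr * y[ixr] * (V - EK) * vf.ikrr;
  double IKs  = gKs * y[ixs] * y[ixs] * (V - EK);
  double ICaL = s.cal * gCaL * y[id_] * y[if_] * y[ifca] * (V - 65.0);
  double IpCa = IpCamax * Cai / (0.0005 + Cai);
  double rNa = KmNai / Nai;
  double INaK = INaKmax * vf.fnak / (1.0 + rNa * std::sqrt(rNa))
                * Ko / (Ko + KmKo);
  double INaCa = INaCamax
      * (vf.e1 * Nai * Nai * Nai * Cao - vf.e2 * Nao * Nao * Nao * Cai)
      / ((KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao)
         * (1.0 + ksat * vf.e2));
  double IbNa = gbNa * (V - ENa);
  double IbCa = gbCa * (V - ECa);

  // SR fluxes and Ca subsystem
  double Irel = krel * y[iu] * y[iu] * y[iv] * y[iw] * (y[iCarel] - Cai);
  double Itr  = (y[iCaup] - y[iCarel]) / tautr;
  double Iup  = Iupmax / (1.0 + kup / Cai);
  double Iupleak = Iupmax * y[iCaup] / Caupmax;
  double Fn = 1e3 * (1e-15 * Vrel * Irel
                     - 1e-15 / (2.0 * Far) * (0.5 * ICaL - 0.2 * INaCa) * CmPF);
  double sFn = sigm((Fn - 3.4175e-13) / 13.67e-16);
  double uinf = sFn;
  double vinf = 1.0 - sigm((Fn - 6.835e-14) / 13.67e-16);
  double tauv = 1.91 + 2.09 * sFn;
  double fcainf = 1.0 / (1.0 + Cai / 0.00035);
  double reu = (use_tab && g_tab.dt == dt) ? g_tab.reu : std::exp(-dt / tauu);
  double refca = (use_tab && g_tab.dt == dt) ? g_tab.refca
                                             : std::exp(-dt / taufca);
  y[iu]   = uinf + (y[iu] - uinf) * reu;
  y[iv]   = vinf + (y[iv] - vinf) * std::exp(-dt / tauv);
  y[ifca] = fcainf + (y[ifca] - fcainf) * refca;

  double dNai = (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) * CmPF / (Far * Vi);
  double dKi  = (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs
                 + (g_stim_in_ki ? istim : 0.0)) * CmPF / (Far * Vi);
  double B1 = (2.0 * INaCa - IpCa - ICaL - IbCa) * CmPF / (2.0 * Far * Vi)
              + (Vup * (Iupleak - Iup) + Irel * Vrel) / Vi;
  double t1 = Cai + KmTrpn, t2 = Cai + KmCmdn;
  double B2 = 1.0 + Trpnmax * KmTrpn / (t1 * t1) + Cmdnmax * KmCmdn / (t2 * t2);
  double dCaup  = Iup - Iupleak - Itr * Vrel / Vup;
  double c1 = y[iCarel] + KmCsqn;
  double dCarel = (Itr - Irel) / (1.0 + Csqnmax * KmCsqn / (c1 * c1));

  y[iNai]   += dt * dNai;
  y[iKi]    += dt * dKi;
  y[iCai]   += dt * B1 / B2;
  y[iCaup]  += dt * dCaup;
  y[iCarel] += dt * dCarel;

  double Iion = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa + INaK
                + INaCa + IbNa + IbCa;
  double dV = -Iion + istim;
  y[iV] = V + dt * dV;
  return dV;
}

// full right-hand side (for the RK4 reference integrator)
inline void rhs(const double* y, double* dy, const Scales& s, double istim) {
  double V = y[iV];
  double gi[NG], gt[NG];
  gate_rates(V, gi, gt);
  for (int g = 0; g < NG - 1; ++g) dy[im + g] = (gi[g] - y[im + g]) / gt[g];
  dy[iw] = (gi[11] - y[iw]) / gt[11];
  VFactors vf;
  volt_factors(V, vf);
  double m = y[im], h = y[ih], j = y[ij];
  double Nai = y[iNai], Ki = y[iKi], Cai = y[iCai];
  double ENa = RTF * std::log(Nao / Nai);
  double EK  = RTF * std::log(Ko / Ki);
  double ECa = 0.5 * RTF * std::log(Cao / Cai);
  double INa  = s.na * gNa * m * m * m * h * j * (V - ENa);
  double IK1  = s.k1 * gK1 * (V - EK) * vf.ik1r;
  double Ito  = s.to * gto * y[ioa] * y[ioa] * y[ioa] * y[ioi] * (V - EK);
  double IKur = s.kur * vf.gkurv * y[iua] * y[iua] * y[iua] * y[iui] * (V - EK);
  double IKr  = gKr * y[ixr] * (V - EK) * vf.ikrr;
  double IKs  = gKs * y[ixs] * y[ixs] * (V - EK);
  double ICaL = s.cal * gCaL * y[id_] * y[if_] * y[ifca] * (V - 65.0);
  double IpCa = IpCamax * Cai / (0.0005 + Cai);
  double INaK = INaKmax * vf.fnak / (1.0 + std::pow(KmNai / Nai, 1.5))
                * Ko / (Ko + KmKo);
  double INaCa = INaCamax
      * (vf.e1 * Nai * Nai * Nai * Cao - vf.e2 * Nao * Nao * Nao * Cai)
      / ((KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao)
         * (1.0 + ksat * vf.e2));
  double IbNa = gbNa * (V - ENa);
  double IbCa = gbCa * (V - ECa);
  double Irel = krel * y[iu] * y[iu] * y[iv] * y[iw] * (y[iCarel] - Cai);
  double Itr  = (y[iCaup] - y[iCarel]) / tautr;
  double Iup  = Iupmax / (1.0 + kup / Cai);
  double Iupleak = Iupmax * y[iCaup] / Caupmax;
  double Fn = 1e3 * (1e-15 * Vrel * Irel
                     - 1e-15 / (2.0 * Far) * (0.5 * ICaL - 0.2 * INaCa) * CmPF);
  double uinf = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  double vinf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  double tauv = 1.91 + 2.09 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  double fcainf = 1.0 / (1.0 + Cai / 0.00035);
  dy[iu]   = (uinf - y[iu]) / tauu;
  dy[iv]   = (vinf - y[iv]) / tauv;
  dy[ifca] = (fcainf - y[ifca]) / taufca;
  dy[iNai] = (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) * CmPF / (Far * Vi);
  dy[iKi]  = (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs
              + (g_stim_in_ki ? istim : 0.0)) * CmPF / (Far * Vi);
  double B1 = (2.0 * INaCa - IpCa - ICaL - IbCa) * CmPF / (2.0 * Far * Vi)
              + (Vup * (Iupleak - Iup) + Irel * Vrel) / Vi;
  double t1 = Cai + KmTrpn, t2 = Cai + KmCmdn;
  double B2 = 1.0 + Trpnmax * KmTrpn / (t1 * t1) + Cmdnmax * KmCmdn / (t2 * t2);
  dy[iCai]  = B1 / B2;
  dy[iCaup] = Iup - Iupleak - Itr * Vrel / Vup;
  double c1 = y[iCarel] + KmCsqn;
  dy[iCarel] = (Itr - Irel) / (1.0 + Csqnmax * KmCsqn / (c1 * c1));
  double Iion = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa + INaK
                + INaCa + IbNa + IbCa;
  dy[iV] = -Iion + istim;
}

inline Scales as_scales(const NumericVector& s) {
  // order: I_Na, I_K1, I_to, I_Kur, I_CaL
  Scales sc;
  sc.na = s[0]; sc.k1 = s[1]; sc.to = s[2]; sc.kur = s[3]; sc.cal = s[4];
  return sc;
}

inline void ensure_tab(double dt) {
  if (g_tab.dt != dt) g_tab.build(dt);
}

} // namespace crn

// [[Rcpp::export]]
void cpp_set_stim_in_ki(bool on) { crn::g_stim_in_ki = on; }

// [[Rcpp::export]]
NumericVector cpp_crn_initial_state() {
  NumericVector y(crn::NSTATE);
  y[crn::iV] = -81.18;
  y[crn::im] = 2.908e-3;  y[crn::ih] = 9.649e-1;  y[crn::ij] = 9.775e-1;
  y[crn::ioa] = 3.043e-2; y[crn::ioi] = 9.992e-1;
  y[crn::iua] = 4.966e-3; y[crn::iui] = 9.986e-1;
  y[crn::ixr] = 3.296e-5; y[crn::ixs] = 1.869e-2;
  y[crn::id_] = 1.367e-4; y[crn::if_] = 9.996e-1; y[crn::ifca] = 7.755e-1;
  y[crn::iu] = 0.0;       y[crn::iv] = 1.0;       y[crn::iw] = 9.992e-1;
  y[crn::iNai] = 11.17;   y[crn::iKi] = 139.0;    y[crn::iCai] = 1.013e-4;
  y[crn::iCaup] = 1.488;  y[crn::iCarel] = 1.488;
  y.attr("names") = CharacterVector::create(
    "V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs", "d", "f", "fca",
    "u", "v", "w", "Nai", "Ki", "Cai", "Caup", "Carel");
  return y;
}

// Single-cell run. stim_onsets: start times of rectangular stimulus pulses.
// method: 0 = Rush-Larsen (forward Euler for concentrations),
//         1 = classical 4th-order Runge-Kutta on the full system.
// [[Rcpp::export]]
List cpp_cell_run(NumericVector y0, NumericVector scales, double dt,
                  double duration, NumericVector stim_onsets, double stim_dur,
                  double stim_amp, double record_dt, int method,
                  bool use_tables) {
  crn::Scales sc = crn::as_scales(scales);
  if (method == 0 && use_tables) crn::ensure_tab(dt);
  std::vector<double> y(y0.begin(), y0.end());
  long nstep = (long)std::llround(duration / dt);
  int stride = std::max(1, (int)std::llround(record_dt / dt));
  long nrec = nstep / stride + 1;
  NumericVector tout(nrec), vout(nrec);
  double dvdt_max = -1e30, t_dvdt_max = NA_REAL, dvdt_ion_max = -1e30;
  std::vector<double> k1(crn::NSTATE), k2(crn::NSTATE), k3(crn::NSTATE),
      k4(crn::NSTATE), yt(crn::NSTATE);
  long irec = 0;
  tout[0] = 0.0; vout[0] = y[crn::iV];
  ++irec;
  int nstim = stim_onsets.size();
  int cur = 0;
  for (long s = 0; s < nstep; ++s) {
    double t = s * dt;
    double istim = 0.0;
    while (cur < nstim && t >= stim_onsets[cur] + stim_dur) ++cur;
    if (cur < nstim && t >= stim_onsets[cur] && t < stim_onsets[cur] + stim_dur)
      istim = stim_amp;
    double dv;
    if (method == 0) {
      dv = crn::react_step(y.data(), sc, dt, istim, use_tables);
    } else {
      crn::rhs(y.data(), k1.data(), sc, istim);
      for (int i = 0; i < crn::NSTATE; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
      crn::rhs(yt.data(), k2.data(), sc, istim);
      for (int i = 0; i < crn::NSTATE; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
      crn::rhs(yt.data(), k3.data(), sc, istim);
      for (int i = 0; i < crn::NSTATE; ++i) yt[i] = y[i] + dt * k3[i];
      crn::rhs(yt.data(), k4.data(), sc, istim);
      for (int i = 0; i < crn::NSTATE; ++i)
        y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      dv = k1[crn::iV];
    }
    if (dv > dvdt_max) { dvdt_max = dv; t_dvdt_max = t; }
    if (dv - istim > dvdt_ion_max) dvdt_ion_max = dv - istim;
    if ((s + 1) % stride == 0 && irec < nrec) {
      tout[irec] = (s + 1) * dt;
      vout[irec] = y[crn::iV];
      ++irec;
    }
    if (!std::isfinite(y[crn::iV]) || y[crn::iV] < -150.0 || y[crn::iV] > 150.0)
      stop("membrane voltage diverged at t = %f ms", t);
  }
  NumericVector yf(y.begin(), y.end());
  yf.attr("names") = cpp_crn_initial_state().attr("names");
  return List::create(_["time"] = tout[Range(0, irec - 1)],
                      _["vm"] = vout[Range(0, irec - 1)],
                      _["final_state"] = yf,
                      _["dvdt_max"] = dvdt_max,
                      _["dvdt_ion_max"] = dvdt_ion_max,
                      _["t_dvdt_max"] = t_dvdt_max);
}

// direct (untabulated) gate steady states / time constants, for validation
// [[Rcpp::export]]
List cpp_crn_gate_rates(double V) {
  double inf[crn::NG], tau[crn::NG];
  crn::gate_rates(V, inf, tau);
  CharacterVector nm = CharacterVector::create(
      "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs", "d", "f", "w");
  NumericVector i_(inf, inf + crn::NG), t_(tau, tau + crn::NG);
  i_.attr("names") = nm; t_.attr("names") = nm;
  return List::create(_["inf"] = i_, _["tau"] = t_);
}

// Monodomain tissue stepper: operator splitting, reaction (Rush-Larsen)
// then explicit diffusion through a precomputed operator.
//
// states: NSTATE x N matrix (column per node). K: symmetric stiffness-type
// operator in CSC triplet arrays (p, i, x) with units mm^2/ms * mm^0 such
// that dV_i += dt * (K V)_i * invm_i. node_class: 0 healthy, 1 fibrotic,
// selecting the row of scales2 (2 x 5). Interlayer links are relaxed
// exactly (pairwise exponential exchange) for unconditional stability.
// [[Rcpp::export]]
List cpp_tissue_run(NumericMatrix states, NumericMatrix scales2,
                    IntegerVector node_class,
                    IntegerVector Kp, IntegerVector Ki_, NumericVector Kx,
                    NumericVector invm,
                    IntegerVector link_a, IntegerVector link_b,
                    NumericVector link_ka, NumericVector link_kb,
                    double dt, double duration, double t0,
                    List stim_nodes, NumericVector stim_node_amp_scale,
                    NumericMatrix stim_times, // rows: (train, pulse) onsets
                    IntegerVector stim_train_of, double stim_dur,
                    double stim_amp,
                    double record_dt, double act_threshold, double act_tref,
                    double quiet_stop_after, double quiet_monitor_from,
                    bool record_vm) {
  int N = states.ncol();
  if (states.nrow() != crn::NSTATE) stop("bad state matrix");
  crn::ensure_tab(dt);
  crn::Scales sch = crn::as_scales(scales2(0, _));
  crn::Scales scf = crn::as_scales(scales2(1, _));
  std::vector<double> Y(states.begin(), states.end()); // column-major
  long nstep = (long)std::llround(duration / dt);
  int stride = std::max(1, (int)std::llround(record_dt / dt));
  long nrec = record_vm ? (nstep / stride + 1) : 1;
  NumericMatrix vmrec(record_vm ? N : 1, nrec);
  NumericVector rectimes(nrec);
  NumericVector act(N, NA_REAL);
  std::vector<double> Vold(N), dvdiff(N);

  // flatten stimulus trains: for each train, nodes + per-node amp scale
  int ntrain = stim_nodes.size();
  std::vector<std::vector<int>> tr_nodes(ntrain);
  std::vector<std::vector<double>> tr_amp(ntrain);
  {
    int off = 0;
    for (int tr = 0; tr < ntrain; ++tr) {
      IntegerVector nd = stim_nodes[tr];
      tr_nodes[tr].assign(nd.begin(), nd.end());
      tr_amp[tr].resize(nd.size());
      for (int q = 0; q < nd.size(); ++q)
        tr_amp[tr][q] = stim_node_amp_scale[off + q];
      off += nd.size();
    }
  }
  int npulse_tot = stim_times.nrow();

  double last_up = -1e30;   // most recent activation-threshold upcrossing
  double t_end = t0 + nstep * dt;
  long irec = 0;
  if (record_vm) {
    for (int i = 0; i < N; ++i) vmrec(i, 0) = Y[(size_t)i * crn::NSTATE + crn::iV];
    rectimes[0] = t0;
    irec = 1;
  }
  bool diverged = false;
  double t_stop = t_end;

  for (long s = 0; s < nstep; ++s) {
    double t = t0 + s * dt;
    // reaction step (stimulus folded in as current)
    std::vector<double> istim_node; // lazily built only if a pulse is active
    bool any_stim = false;
    for (int p = 0; p < npulse_tot; ++p) {
      double on = stim_times(p, 0);
      if (t >= on && t < on + stim_dur) { any_stim = true; break; }
    }
    if (any_stim) {
      istim_node.assign(N, 0.0);
      for (int p = 0; p < npulse_tot; ++p) {
        double on = stim_times(p, 0);
        if (t >= on && t < on + stim_dur) {
          int tr = stim_train_of[p];
          const std::vector<int>& nd = tr_nodes[tr];
          for (size_t q = 0; q < nd.size(); ++q)
            istim_node[nd[q]] += stim_amp * tr_amp[tr][q];
        }
      }
    }
    for (int i = 0; i < N; ++i) {
      double* y = &Y[(size_t)i * crn::NSTATE];
      Vold[i] = y[crn::iV];
      const crn::Scales& sc = node_class[i] ? scf : sch;
      double is = any_stim ? istim_node[i] : 0.0;
      crn::react_step(y, sc, dt, is, true);
    }
    // diffusion step: dV = dt * (K Vhalf) * invm, using post-reaction V
    for (int i = 0; i < N; ++i) dvdiff[i] = 0.0;
    for (int col = 0; col < N; ++col) {
      double vc = Y[(size_t)col * crn::NSTATE + crn::iV];
      for (int q = Kp[col]; q < Kp[col + 1]; ++q)
        dvdiff[Ki_[q]] += Kx[q] * vc;
    }
    for (int i = 0; i < N; ++i)
      Y[(size_t)i * crn::NSTATE + crn::iV] += dt * dvdiff[i] * invm[i];
    // interlayer links: exact pairwise relaxation
    for (int l = 0; l < link_a.size(); ++l) {
      int a = link_a[l], b = link_b[l];
      double ka = link_ka[l], kb = link_kb[l];
      double& va = Y[(size_t)a * crn::NSTATE + crn::iV];
      double& vb = Y[(size_t)b * crn::NSTATE + crn::iV];
      double d0 = va - vb;
      double d1 = d0 * std::exp(-(ka + kb) * dt);
      double vbar = (kb * va + ka * vb) / (ka + kb);
      va = vbar + d1 * ka / (ka + kb);
      vb = vbar - d1 * kb / (ka + kb);
    }
    // activation bookkeeping
    double tnew = t + dt;
    for (int i = 0; i < N; ++i) {
      double vn = Y[(size_t)i * crn::NSTATE + crn::iV];
      if (Vold[i] < act_threshold && vn >= act_threshold) {
        last_up = tnew;
        if (ISNA(act[i]) && tnew >= act_tref) act[i] = tnew;
      }
      if (!std::isfinite(vn) || vn < -150.0 || vn > 150.0) diverged = true;
    }
    if (diverged) { t_stop = tnew; break; }
    if (record_vm && (s + 1) % stride == 0 && irec < nrec) {
      for (int i = 0; i < N; ++i)
        vmrec(i, irec) = Y[(size_t)i * crn::NSTATE + crn::iV];
      rectimes[irec] = tnew;
      ++irec;
    }
    // early stop once activity has extinguished
    if (quiet_stop_after > 0 && tnew >= quiet_monitor_from
        && tnew - std::max(last_up, quiet_monitor_from - quiet_stop_after)
           >= quiet_stop_after) {
      t_stop = tnew;
      break;
    }
    if ((s & 0x3fff) == 0) Rcpp::checkUserInterrupt();
    t_stop = tnew;
  }
  NumericMatrix fin(crn::NSTATE, N);
  std::copy(Y.begin(), Y.end(), fin.begin());
  List out = List::create(
      _["activation_times"] = act,
      _["final_state"] = fin,
      _["last_activation"] = (last_up <= -1e29) ? NA_REAL : last_up,
      _["t_stop"] = t_stop,
      _["diverged"] = diverged);
  if (record_vm) {
    out["vm"] = vmrec(_, Range(0, irec - 1));
    out["vm_times"] = rectimes[Range(0, irec - 1)];
  }
  return out;
}
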