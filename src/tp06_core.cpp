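// TP06 (ten Tusscher & Panfilov 2006, epicardial) ionic model and explicit
// monodomain integrator on 1D/2D regular grids.
//
// Discretisation contract:
//   V^{k+1}_{ij} = V^k_{ij} + dt * [ (J_{i+1/2,j} - J_{i-1/2,j}
//                                   + J_{i,j+1/2} - J_{i,j-1/2})/h^2 - I_ion ]
// with J_{i+1/2,j} = sigma_{i+1/2,j} (V_{i+1,j} - V_{i,j}) and J = 0 on the
// boundary (Neumann). Currents are in pA/pF so I_ion enters dV/dt directly.
// Gates advance by Rush-Larsen exponential steps by default; a forward-Euler
// gate mode is available for scheme-fidelity comparisons. Voltage-dependent
// coefficients are tabulated on a 0.05 mV grid with linear interpolation
// (exact evaluation available via use_lut = false).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------- constants
static const double Rgas = 8314.472;      // mJ/(mol K)
static const double Frd  = 96485.3415;    // C/mol
static const double Tmp  = 310.0;         // K
static const double RTONF = Rgas * Tmp / Frd;       // 26.7137... mV
static const double FORT  = 1.0 / RTONF;

static const double Nao = 140.0, Cao = 2.0;         // mM
static const double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468; // um^3 scale
static const double Bufc = 0.2,  Kbufc = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
static const double Bufss = 0.4, Kbufss = 0.00025;
static const double Vmaxup = 0.006375, Kup = 0.00025;
static const double Vrel = 0.102, Vleak = 0.00036, Vxfer = 0.0038;
static const double k1p = 0.15, k2p = 0.045, k3 = 0.060, k4 = 0.005;
static const double ECsr = 1.5, maxsr = 2.5, minsr = 1.0;
static const double GNa = 14.838, GK1 = 5.405, GKr = 0.153;
static const double GKs = 0.392, Gto = 0.294;       // epicardial
static const double GCaL = 0.00003980;
static const double GbNa = 0.00029, GbCa = 0.000592;
static const double knak = 2.724, KmK = 1.0, KmNa = 40.0;
static const double knaca = 1000.0, KmNai = 87.5, KmCa = 1.38;
static const double ksat = 0.1, ncagam = 0.35;
static const double GpCa = 0.1238, KpCa = 0.0005, GpK = 0.0146;
static const double pKNa = 0.03;

// state vector layout (19 variables)
enum { iV = 0, iM, iH, iJ, iD, iF, iF2, iFC, iR, iS, iXr1, iXr2, iXs,
       iNai, iKi, iCai, iCasr, iCass, iRR, NVAR };

// I_K1 phase-rule codes
enum { RULE_ALWAYS = 0, RULE_FRONT = 1, RULE_TAIL = 2,
       RULE_SUBFRONT = 3, RULE_SUPRAFRONT = 4 };

struct Cond {
  double gNa, gCaL, gKr, gKs, gK1, Ko, cm, ik1_factor;
  int ik1_rule;
};

static Cond as_cond(const NumericVector& p) {
  Cond c;
  c.gNa = p["g_Na"];  c.gCaL = p["g_CaL"]; c.gKr = p["g_Kr"];
  c.gKs = p["g_Ks"];  c.gK1 = p["g_K1"];   c.Ko = p["Ko"];
  c.cm  = p["Cm"];    c.ik1_factor = p["ik1_factor"];
  c.ik1_rule = (int) p["ik1_rule"];
  return c;
}

// ------------------------------------------------------------ gate kinetics
// inf and tau for the 11 voltage-gated variables, TP06 epicardial.
static inline void gate_rates(double V, double* inf, double* tau) {
  double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
  double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
              0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
  inf[0] = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2);
  tau[0] = am * bm;

  double hinf = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2);
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
    bh = 2.7 * std::exp(0.079 * V) + 310000.0 * std::exp(0.3485 * V);
    aj = (-25428.0 * std::exp(0.2444 * V) - 0.000006948 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.02424 * std::exp(-0.01052 * V) /
         (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  inf[1] = hinf; tau[1] = 1.0 / (ah + bh);
  inf[2] = hinf; tau[2] = 1.0 / (aj + bj);

  double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
  double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
  double gd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
  inf[3] = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
  tau[3] = ad * bd + gd;

  inf[4] = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  tau[4] = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
           200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
           180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;

  inf[5] = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
  tau[5] = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
           31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
           80.0 / (1.0 + std::exp((V + 30.0) / 10.0));

  inf[6] = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  tau[6] = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;

  inf[7] = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));   // s, epicardial
  tau[7] = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
           5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;

  double axr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
  double bxr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
  inf[8] = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  tau[8] = axr1 * bxr1;

  double axr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
  double bxr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
  inf[9] = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  tau[9] = axr2 * bxr2;

  double axs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
  double bxs = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
  inf[10] = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  tau[10] = axs * bxs + 80.0;
}
// order used above: m h j d f f2 r s xr1 xr2 xs
static const int GATE_IDX[11] = { iM, iH, iJ, iD, iF, iF2, iR, iS, iXr1, iXr2, iXs };

// xK1_inf as a function of V - E_K (time-independent rectification)
static inline double xk1_inf(double vmek) {
  double ak1 = 0.1 / (1.0 + std::exp(0.06 * (vmek - 200.0)));
  double bk1 = (3.0 * std::exp(0.0002 * (vmek + 100.0)) +
                std::exp(0.1 * (vmek - 10.0))) /
               (1.0 + std::exp(-0.5 * vmek));
  return ak1 / (ak1 + bk1);
}

// voltage factors for the non-gated currents
static inline void volt_factors(double V, double* f) {
  // f[0] = exp(gam*V*F/RT), f[1] = exp((gam-1)*V*F/RT)   (I_NaCa)
  // f[2] = 1/(1 + 0.1245 exp(-0.1 VF/RT) + 0.0353 exp(-VF/RT))  (I_NaK)
  // f[3] = 1/(1 + exp((25-V)/5.98))                      (I_pK)
  // f[4] = A(V)  = 4 (V-15) F^2/RT / (exp(x)-1),  x = 2(V-15)F/RT   (I_CaL)
  // f[5] = A(V) * exp(x)
  f[0] = std::exp(ncagam * V * FORT);
  f[1] = std::exp((ncagam - 1.0) * V * FORT);
  f[2] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V * FORT) +
                0.0353 * std::exp(-V * FORT));
  f[3] = 1.0 / (1.0 + std::exp((25.0 - V) / 5.98));
  double x = 2.0 * (V - 15.0) * FORT;
  if (std::fabs(x) < 1e-7) {
    f[4] = 2.0 * Frd;            // limit of 4 (V-15) F^2/RT / (e^x - 1)
    f[5] = 2.0 * Frd;
  } else {
    double ex = std::exp(x);
    f[4] = 4.0 * (V - 15.0) * Frd * FORT / (ex - 1.0);   // 4 (V-15) F^2/RT / (e^x-1)
    f[5] = f[4] * ex;
  }
}

// --------------------------------------------------------------- LUT tables
// Array-of-structs layout, 28 doubles per V bin:
//   [0..21]  per gate g: b_g = inf_g (1 - exp(-dt/tau_g)), a_g = exp(-dt/tau_g)
//            so the Rush-Larsen update is gate <- b + gate * a
//   [22..27] the 6 voltage factors of the non-gated currents
// A second table (inf, 1/tau per gate) serves the forward-Euler gate mode,
// and a 1-column table holds xk1_inf over V - E_K.
#define LUTW 28
struct Lut {
  double vmin, vmax, inv_step;
  int n;
  std::vector<double> tab;     // n * LUTW
  std::vector<double> tabfe;   // n * 22 (inf, invtau)
  double kmin, kmax, kinv_step;
  int kn;
  std::vector<double> ktab;    // kn
  double dt;
};

static void build_lut(Lut& L, double dt) {
  L.vmin = -120.0; L.vmax = 80.0; L.inv_step = 20.0;  // 0.05 mV
  L.n = (int)((L.vmax - L.vmin) * L.inv_step) + 2;
  L.tab.assign((size_t)L.n * LUTW, 0.0);
  L.tabfe.assign((size_t)L.n * 22, 0.0);
  L.dt = dt;
  double inf[11], tau[11], vf[6];
  for (int i = 0; i < L.n; ++i) {
    double V = L.vmin + i / L.inv_step;
    gate_rates(V, inf, tau);
    double* row = &L.tab[(size_t)i * LUTW];
    double* rfe = &L.tabfe[(size_t)i * 22];
    for (int g = 0; g < 11; ++g) {
      double a = std::exp(-dt / tau[g]);
      row[2 * g]     = inf[g] * (1.0 - a);
      row[2 * g + 1] = a;
      rfe[2 * g]     = inf[g];
      rfe[2 * g + 1] = 1.0 / tau[g];
    }
    volt_factors(V, vf);
    for (int k = 0; k < 6; ++k) row[22 + k] = vf[k];
  }
  L.kmin = -150.0; L.kmax = 350.0; L.kinv_step = 20.0;
  L.kn = (int)((L.kmax - L.kmin) * L.kinv_step) + 2;
  L.ktab.assign(L.kn, 0.0);
  for (int i = 0; i < L.kn; ++i)
    L.ktab[i] = xk1_inf(L.kmin + i / L.kinv_step);
}

static inline const double* lut_rows(const Lut& L, double V, double& frac,
                                     int& bin) {
  double u = (V - L.vmin) * L.inv_step;
  if (!(u >= 0.0)) u = 0.0;          // also traps NaN (aborted later)
  if (u > L.n - 2) u = L.n - 2;
  int i = (int)u;
  frac = u - i;
  bin = i;
  return &L.tab[(size_t)i * LUTW];
}

static inline double lut_xk1(const Lut& L, double vmek) {
  double u = (vmek - L.kmin) * L.kinv_step;
  if (!(u >= 0.0)) u = 0.0;
  if (u > L.kn - 2) u = L.kn - 2;
  int i = (int)u;
  double f = u - i;
  return L.ktab[i] + (L.ktab[i + 1] - L.ktab[i]) * f;
}

// ------------------------------------------------------------ current stack
// All 12 TP06 membrane currents (pA/pF). dvdt_sign drives the optional
// phase-conditional I_K1 rule; ties (0) count as repolarisation ("tail").
struct Currents {
  double INa, IK1, Ito, IKr, IKs, ICaL, INaCa, INaK, IpCa, IpK, IbCa, IbNa;
  double Iion;
};

static inline double ik1_multiplier(const Cond& c, int dvdt_sign, double V) {
  bool active;
  switch (c.ik1_rule) {
    case RULE_FRONT:      active = dvdt_sign > 0; break;
    case RULE_TAIL:       active = dvdt_sign <= 0; break;
    case RULE_SUBFRONT:   active = dvdt_sign > 0 && V < -50.0; break;
    case RULE_SUPRAFRONT: active = dvdt_sign > 0 && V > -50.0; break;
    default:              active = true; break;  // plain scaling
  }
  // rule "always" applies gK1 itself; conditional rules scale a normal gK1
  if (c.ik1_rule == RULE_ALWAYS) return c.gK1;
  return active ? c.ik1_factor : c.gK1;
}

static inline void compute_currents_full(const double* s, const Cond& c,
                                         int dvdt_sign, Currents& I) {
  double V = s[iV];
  double Ek  = RTONF * std::log(c.Ko / s[iKi]);
  double Ena = RTONF * std::log(Nao / s[iNai]);
  double Eks = RTONF * std::log((c.Ko + pKNa * Nao) / (s[iKi] + pKNa * s[iNai]));
  double Eca = 0.5 * RTONF * std::log(Cao / s[iCai]);
  double vf[6];
  volt_factors(V, vf);
  double sqrtko = std::sqrt(c.Ko / 5.4);

  I.INa = c.gNa * GNa * s[iM] * s[iM] * s[iM] * s[iH] * s[iJ] * (V - Ena);
  I.IK1 = ik1_multiplier(c, dvdt_sign, V) * GK1 * sqrtko *
          xk1_inf(V - Ek) * (V - Ek);
  I.Ito = Gto * s[iR] * s[iS] * (V - Ek);
  I.IKr = c.gKr * GKr * sqrtko * s[iXr1] * s[iXr2] * (V - Ek);
  I.IKs = c.gKs * GKs * s[iXs] * s[iXs] * (V - Eks);
  I.ICaL = c.gCaL * GCaL * s[iD] * s[iF] * s[iF2] * s[iFC] *
           (0.25 * s[iCass] * vf[5] - Cao * vf[4]);
  I.INaCa = knaca *
      (vf[0] * s[iNai] * s[iNai] * s[iNai] * Cao -
       vf[1] * Nao * Nao * Nao * s[iCai] * 2.5) /
      ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
       (1.0 + ksat * vf[1]));
  I.INaK = knak * (c.Ko / (c.Ko + KmK)) * (s[iNai] / (s[iNai] + KmNa)) * vf[2];
  I.IpCa = GpCa * s[iCai] / (KpCa + s[iCai]);
  I.IpK  = GpK * vf[3] * (V - Ek);
  I.IbNa = GbNa * (V - Ena);
  I.IbCa = GbCa * (V - Eca);
  I.Iion = I.INa + I.IK1 + I.Ito + I.IKr + I.IKs + I.ICaL + I.INaCa +
           I.INaK + I.IpCa + I.IpK + I.IbCa + I.IbNa;
}

// ------------------------------------------------------------- field struct
struct Field {
  int nx, ny, n;
  std::vector<double> s[NVAR];   // struct of arrays
  std::vector<double> Ek, Ena, Eks, Eca;
  std::vector<signed char> sgn;  // sign of last voltage change
};

static void init_field(Field& F, int nx, int ny, const NumericMatrix& init) {
  F.nx = nx; F.ny = ny; F.n = nx * ny;
  bool broadcast = (init.ncol() == 1);
  for (int v = 0; v < NVAR; ++v) {
    F.s[v].assign(F.n, 0.0);
    for (int i = 0; i < F.n; ++i)
      F.s[v][i] = broadcast ? init(v, 0) : init(v, i);
  }
  F.Ek.assign(F.n, 0.0); F.Ena.assign(F.n, 0.0);
  F.Eks.assign(F.n, 0.0); F.Eca.assign(F.n, 0.0);
  F.sgn.assign(F.n, -1);  // quiescent start counts as "tail"
}

static inline void refresh_reversals(Field& F, const Cond& c) {
  for (int i = 0; i < F.n; ++i) {
    F.Ek[i]  = RTONF * std::log(c.Ko / F.s[iKi][i]);
    F.Ena[i] = RTONF * std::log(Nao / F.s[iNai][i]);
    F.Eks[i] = RTONF * std::log((c.Ko + pKNa * Nao) /
                                (F.s[iKi][i] + pKNa * F.s[iNai][i]));
    F.Eca[i] = 0.5 * RTONF * std::log(Cao / F.s[iCai][i]);
  }
}

// one reaction step for every node; lap[] holds the diffusion term (mV/ms).
// act[] (optional) marks nodes reached by activity: nodes that start from
// the quiescent steady state are frozen (|I_ion| < 1e-5 pA/pF there) until
// the diffusive foot of a wave perturbs them, which cuts the cost of the
// tissue ahead of the front without measurable effect on the solution.
static void reaction_step(Field& F, const Cond& c, double dt,
                          const double* lap, const Lut* L, int gate_mode,
                          signed char* act = 0) {
  const int n = F.n;
  const double sqrtko = std::sqrt(c.Ko / 5.4);
  const double naca_den0 = (KmNai * KmNai * KmNai + Nao * Nao * Nao) *
                           (KmCa + Cao);
  const double inVcF  = c.cm / (Vc * Frd);
  const double inVcF2 = c.cm / (2.0 * Vc * Frd);
  const double inVssF2 = c.cm / (2.0 * Vss * Frd);
  const double nak_ko = knak * c.Ko / (c.Ko + KmK);

  for (int i = 0; i < n; ++i) {
    if (act && !act[i]) {
      if (std::fabs(lap[i]) > 1e-5) act[i] = 1;
      else continue;
    }
    double V = F.s[iV][i];
    double frac = 0.0;
    int bin = 0;
    const double* row = 0;
    double inf[11], tau[11], vf[6];
    if (L) {
      row = lut_rows(*L, V, frac, bin);
      const double* r2 = row + LUTW;
      for (int k = 0; k < 6; ++k)
        vf[k] = row[22 + k] + (r2[22 + k] - row[22 + k]) * frac;
    } else {
      gate_rates(V, inf, tau);
      volt_factors(V, vf);
    }

    double Nai = F.s[iNai][i], Ki = F.s[iKi][i];
    double Cai = F.s[iCai][i], Casr = F.s[iCasr][i], Cass = F.s[iCass][i];
    double Ek = F.Ek[i], Ena = F.Ena[i], Eks = F.Eks[i], Eca = F.Eca[i];
    int sgn = F.sgn[i];

    double gk1m = ik1_multiplier(c, sgn, V);
    double vmek = V - Ek;
    double xk1 = L ? lut_xk1(*L, vmek) : xk1_inf(vmek);
    double RRv = F.s[iRR][i];

    // All state-dependent denominators of this step share a single batched
    // reciprocal (prefix/suffix products); ratios are algebraically
    // rearranged so no other divide remains in the hot loop.
    double ca2 = Cai * Cai, cs2 = Cass * Cass, cr2 = Casr * Casr;
    double csr2 = (20.0 * Cass) * (20.0 * Cass);        // (Cass/0.05)^2
    double d_sr = cr2 + ECsr * ECsr;
    double kcasr_num = maxsr * d_sr - (maxsr - minsr) * cr2;  // kcasr*d_sr
    double bc = (Cai + Kbufc);   bc *= bc;
    double bs = (Casr + Kbufsr); bs *= bs;
    double bx = (Cass + Kbufss); bx *= bx;
    double den[9];
    den[0] = d_sr;
    den[1] = k3 * kcasr_num + k1p * cs2 * d_sr;         // RyR open fraction
    den[2] = ca2 + Kup * Kup;                           // SERCA
    den[3] = bc + Bufc * Kbufc;                         // cytosol buffer
    den[4] = bs + Bufsr * Kbufsr;                       // SR buffer
    den[5] = bx + Bufss * Kbufss;                       // subspace buffer
    den[6] = KpCa + Cai;                                // I_pCa
    den[7] = naca_den0 * (1.0 + ksat * vf[1]);          // I_NaCa
    den[8] = Nai + KmNa;                                // I_NaK
    double pre[9], suf[9], inv[9];
    pre[0] = den[0];
    for (int k = 1; k < 9; ++k) pre[k] = pre[k - 1] * den[k];
    suf[8] = den[8];
    for (int k = 7; k >= 0; --k) suf[k] = suf[k + 1] * den[k];
    double r_all = 1.0 / pre[8];
    inv[0] = r_all * suf[1];
    for (int k = 1; k < 8; ++k) inv[k] = r_all * pre[k - 1] * suf[k + 1];
    inv[8] = r_all * pre[7];

    double INa = c.gNa * GNa * F.s[iM][i] * F.s[iM][i] * F.s[iM][i] *
                 F.s[iH][i] * F.s[iJ][i] * (V - Ena);
    double IK1 = gk1m * GK1 * sqrtko * xk1 * vmek;
    double Ito = Gto * F.s[iR][i] * F.s[iS][i] * vmek;
    double IKr = c.gKr * GKr * sqrtko * F.s[iXr1][i] * F.s[iXr2][i] * vmek;
    double IKs = c.gKs * GKs * F.s[iXs][i] * F.s[iXs][i] * (V - Eks);
    double ICaL = c.gCaL * GCaL * F.s[iD][i] * F.s[iF][i] * F.s[iF2][i] *
                  F.s[iFC][i] * (0.25 * Cass * vf[5] - Cao * vf[4]);
    double INaCa = knaca *
        (vf[0] * Nai * Nai * Nai * Cao - vf[1] * Nao * Nao * Nao * Cai * 2.5) *
        inv[7];
    double INaK = nak_ko * Nai * inv[8] * vf[2];
    double IpCa = GpCa * Cai * inv[6];
    double IpK  = GpK * vf[3] * vmek;
    double IbNa = GbNa * (V - Ena);
    double IbCa = GbCa * (V - Eca);
    double Iion = INa + IK1 + Ito + IKr + IKs + ICaL + INaCa + INaK +
                  IpCa + IpK + IbCa + IbNa;

    double kcasr = kcasr_num * inv[0];
    double k2 = k2p * kcasr;
    double Orel = k1p * cs2 * RRv * d_sr * inv[1];
    double Irel = Vrel * Orel * (Casr - Cass);
    double Ileak = Vleak * (Casr - Cai);
    double Iup = Vmaxup * ca2 * inv[2];
    double Ixfer = Vxfer * (Cass - Cai);

    double bufc  = bc * inv[3];
    double bufsr = bs * inv[4];
    double bufss = bx * inv[5];

    F.s[iCai][i]  = Cai + dt * bufc *
        ((Ileak - Iup) * Vsr / Vc + Ixfer - (IbCa + IpCa - 2.0 * INaCa) * inVcF2);
    F.s[iCasr][i] = Casr + dt * bufsr * (Iup - Irel - Ileak);
    F.s[iCass][i] = Cass + dt * bufss *
        (-ICaL * inVssF2 + Irel * Vsr / Vss - Ixfer * Vc / Vss);
    F.s[iRR][i]   = RRv + dt * (-k2 * Cass * RRv + k4 * (1.0 - RRv));
    F.s[iNai][i]  = Nai + dt * (-(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * inVcF);
    F.s[iKi][i]   = Ki + dt * (-(IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK) * inVcF);

    // voltage-dependent gates
    if (L) {
      if (gate_mode == 0) {          // Rush-Larsen: gate <- b + gate a
        const double* r2 = row + LUTW;
        for (int g = 0; g < 11; ++g) {
          double gb = row[2 * g]     + (r2[2 * g]     - row[2 * g]) * frac;
          double ga = row[2 * g + 1] + (r2[2 * g + 1] - row[2 * g + 1]) * frac;
          double* gv = &F.s[GATE_IDX[g]][i];
          *gv = gb + *gv * ga;
        }
      } else {                       // forward Euler
        const double* rf = &L->tabfe[(size_t)bin * 22];
        const double* rf2 = rf + 22;
        for (int g = 0; g < 11; ++g) {
          double gi = rf[2 * g]     + (rf2[2 * g]     - rf[2 * g]) * frac;
          double it = rf[2 * g + 1] + (rf2[2 * g + 1] - rf[2 * g + 1]) * frac;
          double* gv = &F.s[GATE_IDX[g]][i];
          *gv += dt * (gi - *gv) * it;
          if (*gv < 0.0) *gv = 0.0;
          if (*gv > 1.0) *gv = 1.0;
        }
      }
    } else {
      for (int g = 0; g < 11; ++g) {
        double* gv = &F.s[GATE_IDX[g]][i];
        if (gate_mode == 0)
          *gv = inf[g] + (*gv - inf[g]) * std::exp(-dt / tau[g]);
        else {
          *gv += dt * (inf[g] - *gv) / tau[g];
          if (*gv < 0.0) *gv = 0.0;
          if (*gv > 1.0) *gv = 1.0;
        }
      }
    }
    // fCass gate (Ca-dependent). tau >= 2 ms while dt <= 0.02 ms, so the
    // forward-Euler update is indistinguishable from the exponential one
    // (dt/tau <= 1e-2). Identity used:
    //   (fc_inf - fc)/tau = [0.6 + (0.4 - fc)(1 + csr2)] / (82 + 2 csr2)
    double fc = F.s[iFC][i];
    F.s[iFC][i] = fc + dt * (0.6 + (0.4 - fc) * (1.0 + csr2)) /
                  (82.0 + 2.0 * csr2);

    double Vnew = V + dt * (lap[i] - Iion);
    F.s[iV][i] = Vnew;
    F.sgn[i] = (Vnew > V) ? 1 : -1;   // tie counts as tail
  }
}

// diffusion term: flux differences at half-nodes, zero-flux boundary
static inline void diffusion(const Field& F, const double* sigx,
                             const double* sigy, double h2inv, double* lap) {
  const int nx = F.nx, ny = F.ny;
  const double* V = F.s[iV].data();
  if (nx * ny == 1) { lap[0] = 0.0; return; }
  if (ny == 1) {
    lap[0] = sigx[0] * (V[1] - V[0]) * h2inv;
    for (int i = 1; i < nx - 1; ++i)
      lap[i] = (sigx[i] * (V[i + 1] - V[i]) - sigx[i - 1] * (V[i] - V[i - 1])) * h2inv;
    lap[nx - 1] = -sigx[nx - 2] * (V[nx - 1] - V[nx - 2]) * h2inv;
    return;
  }
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int id = j * nx + i;
      double acc = 0.0;
      if (i < nx - 1) acc += sigx[j * (nx - 1) + i] * (V[id + 1] - V[id]);
      if (i > 0)      acc -= sigx[j * (nx - 1) + i - 1] * (V[id] - V[id - 1]);
      if (j < ny - 1) acc += sigy[j * nx + i] * (V[id + nx] - V[id]);
      if (j > 0)      acc -= sigy[(j - 1) * nx + i] * (V[id] - V[id - nx]);
      lap[id] = acc * h2inv;
    }
  }
}

// --------------------------------------------------------------- exports

// [[Rcpp::export]]
NumericVector tp06_currents_cpp(NumericVector state, NumericVector cond,
                                int dvdt_sign) {
  Cond c = as_cond(cond);
  Currents I;
  compute_currents_full(REAL(state), c, dvdt_sign, I);
  NumericVector out = NumericVector::create(
    _["I_Na"] = I.INa, _["I_K1"] = I.IK1, _["I_to"] = I.Ito,
    _["I_Kr"] = I.IKr, _["I_Ks"] = I.IKs, _["I_CaL"] = I.ICaL,
    _["I_NaCa"] = I.INaCa, _["I_NaK"] = I.INaK, _["I_pCa"] = I.IpCa,
    _["I_pK"] = I.IpK, _["I_bCa"] = I.IbCa, _["I_bNa"] = I.IbNa,
    _["I_ion"] = I.Iion);
  return out;
}

// [[Rcpp::export]]
NumericMatrix tp06_gate_tables_cpp(NumericVector V) {
  // inf and tau for the 11 voltage gates at each V; for validation/plots
  NumericMatrix out(V.size(), 22);
  double inf[11], tau[11];
  for (int i = 0; i < V.size(); ++i) {
    gate_rates(V[i], inf, tau);
    for (int g = 0; g < 11; ++g) { out(i, g) = inf[g]; out(i, 11 + g) = tau[g]; }
  }
  return out;
}

struct ProbeState {
  std::vector<int> nodes;
  std::vector<std::vector<double> > acts;
  std::vector<double> lastV, lastAct;
};

// Main integrator. init: NVAR x 1 (broadcast) or NVAR x n matrix.
// stim_times (ms) all share stim_nodes unless stim_nodes2 given for times2.
// early_stop: 0 none, 1 single-pulse, 2 paced train.
// [[Rcpp::export]]
List tp06_run_cpp(NumericMatrix init, int nx, int ny,
                  NumericVector sigx, NumericVector sigy,
                  double h, double dt, double duration,
                  NumericVector cond,
                  List stimuli,
                  IntegerVector probe_nodes, double probe_threshold,
                  double probe_debounce,
                  IntegerVector record_sites, double record_stride,
                  double frame_stride,
                  int early_stop, double es_window, double es_period,
                  int es_n_ignore, int es_n_analyzed,
                  bool use_lut, int gate_mode,
                  bool monitor_convergence, double conv_tol,
                  bool lazy = false) {
  Cond c = as_cond(cond);
  Field F;
  init_field(F, nx, ny, init);
  refresh_reversals(F, c);

  Lut L;
  if (use_lut) build_lut(L, dt);
  const Lut* Lp = use_lut ? &L : 0;

  long nsteps = (long) std::llround(duration / dt);
  long rev_every = std::max(1L, (long) std::llround(1.0 / dt));
  double h2inv = 1.0 / (h * h);
  std::vector<double> lap(F.n, 0.0);
  std::vector<signed char> act(F.n, lazy ? 0 : 1);

  // stimuli: list of list(time=, nodes=) with V reset to 50 mV
  int nstim = stimuli.size();
  std::vector<long> stim_step(nstim);
  std::vector<double> stim_time(nstim);
  std::vector<IntegerVector> stim_nodes(nstim);
  for (int k = 0; k < nstim; ++k) {
    List st = stimuli[k];
    stim_time[k] = as<double>(st["time"]);
    stim_step[k] = (long) std::llround(stim_time[k] / dt);
    stim_nodes[k] = as<IntegerVector>(st["nodes"]);
  }

  // probes
  ProbeState P;
  for (int k = 0; k < probe_nodes.size(); ++k) P.nodes.push_back(probe_nodes[k]);
  P.acts.resize(P.nodes.size());
  P.lastV.assign(P.nodes.size(), 0.0);
  P.lastAct.assign(P.nodes.size(), -1e9);
  for (size_t k = 0; k < P.nodes.size(); ++k) P.lastV[k] = F.s[iV][P.nodes[k]];

  // site traces
  long rec_every = record_stride > 0 ? (long) std::llround(record_stride / dt) : 0;
  long nrec = rec_every > 0 ? nsteps / rec_every + 1 : 0;
  NumericMatrix traces(record_sites.size() > 0 ? nrec : 0, record_sites.size());
  std::vector<double> trace_t;
  long rec_count = 0;

  // frames
  long frame_every = frame_stride > 0 ? (long) std::llround(frame_stride / dt) : 0;
  long nframes = frame_every > 0 ? nsteps / frame_every + 1 : 0;
  NumericMatrix frames(frame_every > 0 ? F.n : 0, frame_every > 0 ? nframes : 0);
  std::vector<double> frame_t;
  long frame_count = 0;

  // convergence monitor (single node): state snapshot each 1 ms
  long ms_every = (long) std::llround(1.0 / dt);
  std::vector<double> snap(NVAR, 0.0);
  std::vector<double> relchg;   // per-ms max relative change
  if (monitor_convergence)
    for (int v = 0; v < NVAR; ++v) snap[v] = F.s[v][0];

  int status = 0;   // 0 completed, 1 all-conducted, 2 blocked, 3 distal-activated,
                    // 4 window-elapsed, -1 instability
  long bad_step = -1; int bad_node = -1;
  double t = 0.0;
  long step = 0;

  for (step = 0; step < nsteps; ++step) {
    t = step * dt;
    for (int k = 0; k < nstim; ++k)
      if (stim_step[k] == step)
        for (int q = 0; q < stim_nodes[k].size(); ++q) {
          F.s[iV][stim_nodes[k][q]] = 50.0;
          act[stim_nodes[k][q]] = 1;
        }

    // reversal potentials drift with the slow concentrations only; a 1 ms
    // refresh changes E_K by < 1e-3 mV per interval
    if (step % rev_every == 0) refresh_reversals(F, c);

    if (rec_every > 0 && step % rec_every == 0) {
      for (int k = 0; k < record_sites.size(); ++k)
        traces(rec_count, k) = F.s[iV][record_sites[k]];
      trace_t.push_back(t);
      ++rec_count;
    }
    if (frame_every > 0 && step % frame_every == 0) {
      for (int i = 0; i < F.n; ++i) frames(i, frame_count) = F.s[iV][i];
      frame_t.push_back(t);
      ++frame_count;
    }

    diffusion(F, sigx.begin(), sigy.begin(), h2inv, lap.data());
    reaction_step(F, c, dt, lap.data(), Lp, gate_mode,
                  lazy ? act.data() : 0);

    // probe crossings (after the update, time stamped at t + dt)
    for (size_t k = 0; k < P.nodes.size(); ++k) {
      double v = F.s[iV][P.nodes[k]];
      if (P.lastV[k] < probe_threshold && v >= probe_threshold &&
          (t + dt) - P.lastAct[k] > probe_debounce) {
        P.acts[k].push_back(t + dt);
        P.lastAct[k] = t + dt;
      }
      P.lastV[k] = v;
    }

    if (monitor_convergence && ms_every > 0 && (step + 1) % ms_every == 0) {
      double mx = 0.0;
      for (int v = 0; v < NVAR; ++v) {
        double cur = F.s[v][0];
        double rc = std::fabs(cur - snap[v]) / (std::fabs(cur) + 1e-12);
        if (rc > mx) mx = rc;
        snap[v] = cur;
      }
      relchg.push_back(mx);
    }

    if (step % 200 == 199) {
      // instability scan
      for (int i = 0; i < F.n; ++i) {
        double v = F.s[iV][i];
        if (!std::isfinite(v) || v < -150.0 || v > 200.0) {
          status = -1; bad_step = step; bad_node = i; break;
        }
      }
      if (status == -1) break;

      if (early_stop == 1 && P.nodes.size() >= 2) {
        // single pulse: the block window is measured from the proximal
        // activation so slow (e.g. hyperkalemic) conduction is not
        // misclassified; a wave that never reaches the proximal probe
        // within twice the window counts as absent.
        if (!P.acts[1].empty()) { status = 3; break; }
        if (!P.acts[0].empty()) {
          if (t + dt > P.acts[0][0] + es_window) { status = 4; break; }
        } else if (t + dt > stim_time[0] + 2.0 * es_window) {
          status = 4; break;
        }
      } else if (early_stop == 2 && P.nodes.size() >= 2 && nstim > 0) {
        int satisfied = 0; bool blocked = false; bool pending = false;
        for (int k = es_n_ignore;
             k < std::min(nstim, es_n_ignore + es_n_analyzed); ++k) {
          double sk = stim_time[k];
          double prox = -1.0;
          for (size_t q = 0; q < P.acts[0].size(); ++q)
            if (P.acts[0][q] > sk && P.acts[0][q] <= sk + es_period) {
              prox = P.acts[0][q]; break;
            }
          if (prox < 0) {
            if (t + dt > sk + es_period) blocked = true;  // no source wave
            else pending = true;
            continue;
          }
          bool hit = false;
          for (size_t q = 0; q < P.acts[1].size(); ++q)
            if (P.acts[1][q] > prox && P.acts[1][q] <= prox + es_window) {
              hit = true; break;
            }
          if (hit) ++satisfied;
          else if (t + dt > prox + es_window) blocked = true;
          else pending = true;
        }
        if (blocked) { status = 2; break; }
        if (!pending && satisfied >= std::min((long)es_n_analyzed,
                                              (long)(nstim - es_n_ignore))) {
          status = 1; break;
        }
      }
    }
  }
  double t_end = (status == 0) ? nsteps * dt : (step + 1) * dt;

  NumericMatrix final_state(NVAR, F.n);
  for (int v = 0; v < NVAR; ++v)
    for (int i = 0; i < F.n; ++i) final_state(v, i) = F.s[v][i];

  List probe_acts(P.nodes.size());
  for (size_t k = 0; k < P.nodes.size(); ++k) probe_acts[k] = wrap(P.acts[k]);

  bool converged = true;
  if (monitor_convergence) {
    size_t m = relchg.size();
    size_t from = m > 1000 ? m - 1000 : 0;
    for (size_t q = from; q < m; ++q)
      if (relchg[q] > conv_tol) { converged = false; break; }
    if (m == 0) converged = false;
  }

  return List::create(
    _["status"] = status,
    _["t_end"] = t_end,
    _["final_state"] = final_state,
    _["trace_times"] = wrap(trace_t),
    _["traces"] = (rec_count > 0 && record_sites.size() > 0) ?
        NumericMatrix(traces(Range(0, rec_count - 1),
                             Range(0, record_sites.size() - 1))) :
        NumericMatrix(0, 0),
    _["frame_times"] = wrap(frame_t),
    _["frames"] = frames,
    _["n_frames"] = frame_count,
    _["probe_activations"] = probe_acts,
    _["bad_step"] = (double) bad_step,
    _["bad_node"] = bad_node,
    _["converged"] = converged);
}

// ---------------------------------------------------------- passive medium

// [[Rcpp::export]]
NumericMatrix diffusion_term_cpp(NumericMatrix V, NumericVector sigx,
                                 NumericVector sigy, double h) {
  Field F;
  F.nx = V.nrow(); F.ny = V.ncol(); F.n = F.nx * F.ny;
  F.s[iV].assign(F.n, 0.0);
  for (int j = 0; j < F.ny; ++j)
    for (int i = 0; i < F.nx; ++i) F.s[iV][j * F.nx + i] = V(i, j);
  std::vector<double> lap(F.n, 0.0);
  diffusion(F, sigx.begin(), sigy.begin(), 1.0 / (h * h), lap.data());
  NumericMatrix out(F.nx, F.ny);
  for (int j = 0; j < F.ny; ++j)
    for (int i = 0; i < F.nx; ++i) out(i, j) = lap[j * F.nx + i];
  return out;
}

// [[Rcpp::export]]
List passive_run_cpp(NumericMatrix V0, NumericVector sigx, NumericVector sigy,
                     double h, double dt, double duration, double frame_stride) {
  Field F;
  F.nx = V0.nrow(); F.ny = V0.ncol(); F.n = F.nx * F.ny;
  F.s[iV].assign(F.n, 0.0);
  for (int j = 0; j < F.ny; ++j)
    for (int i = 0; i < F.nx; ++i) F.s[iV][j * F.nx + i] = V0(i, j);
  long nsteps = (long) std::llround(duration / dt);
  long fev = frame_stride > 0 ? (long) std::llround(frame_stride / dt) : 0;
  std::vector<double> lap(F.n, 0.0);
  std::vector<double> ftimes;
  std::vector<std::vector<double> > fr;
  for (long step = 0; step < nsteps; ++step) {
    if (fev > 0 && step % fev == 0) {
      fr.push_back(F.s[iV]); ftimes.push_back(step * dt);
    }
    diffusion(F, sigx.begin(), sigy.begin(), 1.0 / (h * h), lap.data());
    for (int i = 0; i < F.n; ++i) F.s[iV][i] += dt * lap[i];
  }
  fr.push_back(F.s[iV]); ftimes.push_back(nsteps * dt);
  NumericMatrix frames(F.n, fr.size());
  for (size_t k = 0; k < fr.size(); ++k)
    for (int i = 0; i < F.n; ++i) frames(i, k) = fr[k][i];
  return List::create(_["frames"] = frames, _["frame_times"] = wrap(ftimes),
                      _["nx"] = F.nx, _["ny"] = F.ny);
}
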