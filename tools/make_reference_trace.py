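#!/usr/bin/env python
"""Independent TP06 (epicardial) reference trajectory.

Integrates the ten Tusscher-Panfilov 2006 human ventricular cell model with
scipy's LSODA at tight tolerances, completely independently of the package's
compiled kernel (different language, different integrator, adaptive steps).
Produces:
  inst/extdata/tp06_reference_ap.csv  -- V(t) for one action potential,
      initiated from the 50 s quiescent state by resetting V to 50 mV,
      sampled every 1 ms for 500 ms.
The file is a synthetic reference computed by this script; regenerate with
`python tools/make_reference_trace.py` from the repository root.
"""
import numpy as np
from scipy.integrate import solve_ivp

R, F, T = 8314.472, 96485.3415, 310.0
RTONF = R * T / F
Ko, Nao, Cao = 5.4, 140.0, 2.0
Vc, Vsr, Vss = 0.016404, 0.001094, 0.00005468
Bufc, Kbufc = 0.2, 0.001
Bufsr, Kbufsr = 10.0, 0.3
Bufss, Kbufss = 0.4, 0.00025
Vmaxup, Kup = 0.006375, 0.00025
Vrel, Vleak, Vxfer = 0.102, 0.00036, 0.0038
k1p, k2p, k3, k4 = 0.15, 0.045, 0.060, 0.005
EC, maxsr, minsr = 1.5, 2.5, 1.0
GNa, GK1, GKr, GKs, Gto = 14.838, 5.405, 0.153, 0.392, 0.294
GCaL, GbNa, GbCa = 0.00003980, 0.00029, 0.000592
knak, KmK, KmNa = 2.724, 1.0, 40.0
knaca, KmNai, KmCa, ksat, gam = 1000.0, 87.5, 1.38, 0.1, 0.35
GpCa, KpCa, GpK = 0.1238, 0.0005, 0.0146
pKNa, Cm = 0.03, 0.185

# y = [V, m, h, j, d, f, f2, fCass, r, s, xr1, xr2, xs, Nai, Ki, Cai, CaSR, CaSS, Rbar]

def rhs(t, y):
    (V, m, h, j, d, f, f2, fC, r, s, xr1, xr2, xs,
     Nai, Ki, Cai, CaSR, CaSS, Rb) = y
    Ek = RTONF * np.log(Ko / Ki)
    Ena = RTONF * np.log(Nao / Nai)
    Eks = RTONF * np.log((Ko + pKNa * Nao) / (Ki + pKNa * Nai))
    Eca = 0.5 * RTONF * np.log(Cao / Cai)

    ak1 = 0.1 / (1 + np.exp(0.06 * (V - Ek - 200)))
    bk1 = (3 * np.exp(0.0002 * (V - Ek + 100)) + np.exp(0.1 * (V - Ek - 10))) \
        / (1 + np.exp(-0.5 * (V - Ek)))
    xk1 = ak1 / (ak1 + bk1)
    sq = np.sqrt(Ko / 5.4)

    INa = GNa * m ** 3 * h * j * (V - Ena)
    IK1 = GK1 * sq * xk1 * (V - Ek)
    Ito = Gto * r * s * (V - Ek)
    IKr = GKr * sq * xr1 * xr2 * (V - Ek)
    IKs = GKs * xs ** 2 * (V - Eks)
    x = 2 * (V - 15) * F / (R * T)
    ex = np.exp(x)
    ICaL = GCaL * d * f * f2 * fC * 4 * (V - 15) * F ** 2 / (R * T) * \
        (0.25 * CaSS * ex - Cao) / (ex - 1)
    INaCa = knaca * (np.exp(gam * V * F / (R * T)) * Nai ** 3 * Cao -
                     np.exp((gam - 1) * V * F / (R * T)) * Nao ** 3 * Cai * 2.5) / \
        ((KmNai ** 3 + Nao ** 3) * (KmCa + Cao) *
         (1 + ksat * np.exp((gam - 1) * V * F / (R * T))))
    INaK = knak * Ko / (Ko + KmK) * Nai / (Nai + KmNa) / \
        (1 + 0.1245 * np.exp(-0.1 * V * F / (R * T)) +
         0.0353 * np.exp(-V * F / (R * T)))
    IpCa = GpCa * Cai / (KpCa + Cai)
    IpK = GpK * (V - Ek) / (1 + np.exp((25 - V) / 5.98))
    IbNa = GbNa * (V - Ena)
    IbCa = GbCa * (V - Eca)
    Iion = INa + IK1 + Ito + IKr + IKs + ICaL + INaCa + INaK + IpCa + IpK + IbCa + IbNa

    minf = 1 / (1 + np.exp((-56.86 - V) / 9.03)) ** 2
    am = 1 / (1 + np.exp((-60 - V) / 5))
    bm = 0.1 / (1 + np.exp((V + 35) / 5)) + 0.1 / (1 + np.exp((V - 50) / 200))
    taum = am * bm
    hinf = 1 / (1 + np.exp((V + 71.55) / 7.43)) ** 2
    if V >= -40:
        ah, bh = 0.0, 0.77 / (0.13 * (1 + np.exp(-(V + 10.66) / 11.1)))
        aj, bj = 0.0, 0.6 * np.exp(0.057 * V) / (1 + np.exp(-0.1 * (V + 32)))
    else:
        ah = 0.057 * np.exp(-(V + 80) / 6.8)
        bh = 2.7 * np.exp(0.079 * V) + 3.1e5 * np.exp(0.3485 * V)
        aj = (-25428 * np.exp(0.2444 * V) - 6.948e-6 * np.exp(-0.04391 * V)) * \
            (V + 37.78) / (1 + np.exp(0.311 * (V + 79.23)))
        bj = 0.02424 * np.exp(-0.01052 * V) / (1 + np.exp(-0.1378 * (V + 40.14)))
    tauh, tauj = 1 / (ah + bh), 1 / (aj + bj)
    dinf = 1 / (1 + np.exp((-8 - V) / 7.5))
    taud = (1.4 / (1 + np.exp((-35 - V) / 13)) + 0.25) * \
        (1.4 / (1 + np.exp((V + 5) / 5))) + 1 / (1 + np.exp((50 - V) / 20))
    finf = 1 / (1 + np.exp((V + 20) / 7))
    tauf = 1102.5 * np.exp(-(V + 27) ** 2 / 225) + \
        200 / (1 + np.exp((13 - V) / 10)) + 180 / (1 + np.exp((V + 30) / 10)) + 20
    f2inf = 0.67 / (1 + np.exp((V + 35) / 7)) + 0.33
    tauf2 = 562 * np.exp(-(V + 27) ** 2 / 240) + \
        31 / (1 + np.exp((25 - V) / 10)) + 80 / (1 + np.exp((V + 30) / 10))
    fCinf = 0.6 / (1 + (CaSS / 0.05) ** 2) + 0.4
    taufC = 80 / (1 + (CaSS / 0.05) ** 2) + 2
    rinf = 1 / (1 + np.exp((20 - V) / 6))
    taur = 9.5 * np.exp(-(V + 40) ** 2 / 1800) + 0.8
    sinf = 1 / (1 + np.exp((V + 20) / 5))
    taus = 85 * np.exp(-(V + 45) ** 2 / 320) + 5 / (1 + np.exp((V - 20) / 5)) + 3
    xr1inf = 1 / (1 + np.exp((-26 - V) / 7))
    tauxr1 = 450 / (1 + np.exp((-45 - V) / 10)) * 6 / (1 + np.exp((V + 30) / 11.5))
    xr2inf = 1 / (1 + np.exp((V + 88) / 24))
    tauxr2 = 3 / (1 + np.exp((-60 - V) / 20)) * 1.12 / (1 + np.exp((V - 60) / 20))
    xsinf = 1 / (1 + np.exp((-5 - V) / 14))
    tauxs = 1400 / np.sqrt(1 + np.exp((5 - V) / 6)) / (1 + np.exp((V - 35) / 15)) + 80

    kcasr = maxsr - (maxsr - minsr) / (1 + (EC / CaSR) ** 2)
    k1 = k1p / kcasr
    k2 = k2p * kcasr
    O = k1 * CaSS ** 2 * Rb / (k3 + k1 * CaSS ** 2)
    Irel = Vrel * O * (CaSR - CaSS)
    Ileak = Vleak * (CaSR - Cai)
    Iup = Vmaxup / (1 + Kup ** 2 / Cai ** 2)
    Ixfer = Vxfer * (CaSS - Cai)
    bufc = 1 / (1 + Bufc * Kbufc / (Cai + Kbufc) ** 2)
    bufsr = 1 / (1 + Bufsr * Kbufsr / (CaSR + Kbufsr) ** 2)
    bufss = 1 / (1 + Bufss * Kbufss / (CaSS + Kbufss) ** 2)

    return [
        -Iion,
        (minf - m) / taum, (hinf - h) / tauh, (jinf_val(hinf) - j) / tauj,
        (dinf - d) / taud, (finf - f) / tauf, (f2inf - f2) / tauf2,
        (fCinf - fC) / taufC, (rinf - r) / taur, (sinf - s) / taus,
        (xr1inf - xr1) / tauxr1, (xr2inf - xr2) / tauxr2, (xsinf - xs) / tauxs,
        -(INa + IbNa + 3 * INaK + 3 * INaCa) * Cm / (Vc * F),
        -(IK1 + Ito + IKr + IKs - 2 * INaK + IpK) * Cm / (Vc * F),
        bufc * ((Ileak - Iup) * Vsr / Vc + Ixfer -
                (IbCa + IpCa - 2 * INaCa) * Cm / (2 * Vc * F)),
        bufsr * (Iup - Irel - Ileak),
        bufss * (-ICaL * Cm / (2 * Vss * F) + Irel * Vsr / Vss - Ixfer * Vc / Vss),
        -k2 * CaSS * Rb + k4 * (1 - Rb),
    ]


def jinf_val(hinf):
    return hinf   # j_inf == h_inf in TP06


def main():
    y0 = [-86.2, 0, 0.75, 0.75, 0, 1, 1, 1, 0, 1, 0, 1, 0,
          7.67, 138.3, 0.00007, 1.3, 0.00007, 1]
    eq = solve_ivp(rhs, (0, 50000), y0, method="LSODA",
                   rtol=1e-8, atol=1e-10, max_step=5.0)
    yq = eq.y[:, -1]
    print("rest V:", yq[0], "Ki:", yq[14], "Nai:", yq[13])
    y1 = yq.copy()
    y1[0] = 50.0
    ts = np.arange(0, 501.0, 1.0)
    ap = solve_ivp(rhs, (0, 500), y1, method="LSODA", t_eval=ts,
                   rtol=1e-8, atol=1e-10, max_step=0.5)
    with open("inst/extdata/tp06_reference_ap.csv", "w") as fh:
        fh.write("# synthetic reference: TP06 epicardial AP from the 50 s\n")
        fh.write("# quiescent state, V reset to 50 mV at t=0; scipy LSODA\n")
        fh.write("# rtol=1e-8; generated by tools/make_reference_trace.py\n")
        fh.write("time_ms,V_mV\n")
        for t, v in zip(ap.t, ap.y[0]):
            fh.write("%.1f,%.6f\n" % (t, v))
    rest = ",".join("%.8g" % v for v in yq)
    with open("inst/extdata/tp06_reference_rest.csv", "w") as fh:
        fh.write("# synthetic reference: TP06 quiescent state after 50 s,\n")
        fh.write("# scipy LSODA rtol=1e-8; tools/make_reference_trace.py\n")
        fh.write("V,m,h,j,d,f,f2,fCass,r,s,xr1,xr2,xs,Na_i,K_i,Ca_i,Ca_sr,Ca_ss,R_bar\n")
        fh.write(rest + "\n")
    print("wrote inst/extdata fixtures")


if __name__ == "__main__":
    main()
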