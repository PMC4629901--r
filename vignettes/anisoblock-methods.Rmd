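---
title: "Methods: conduction block at an abrupt fiber-orientation border"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conduction block at an abrupt fiber-orientation border}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical problem

Cardiac muscle is an anisotropic excitable medium: excitation travels
several times faster along myocyte fibers than across them. Where the fiber
direction changes abruptly — as it does at scars, trabeculae, or engineered
culture boundaries — a wave travelling across fibers suddenly faces
well-coupled tissue ahead. The depolarising current supplied by the slow,
tightly packed wavefront is diluted into the larger electrotonic load of
the fast region ("current-to-load mismatch"), and above a critical
anisotropy ratio the wave fails to cross. Because the mismatch reverses in
the opposite direction, the block is unidirectional — the classic substrate
for reentrant arrhythmia.

`anisoblock` reproduces this system end to end: a human ventricular
monodomain sheet/cable with the ten Tusscher–Panfilov 2006 (TP06)
epicardial ionic model, a straight border between a region with fibers
parallel to the border (so propagation towards the border is
cross-fiber, "transverse") and a region with fibers orthogonal to it
("longitudinal"), and the measurement machinery that maps out when block
occurs.

## Model and discretisation

The monodomain equation

$$\partial_t V = \nabla\!\cdot\!(\sigma(\mathbf{x})\nabla V) - I_{ion}/C_m$$

is discretised on a regular grid with fluxes at half-integer nodes,

$$V^{k+1}_{ij} = V^k_{ij} + \frac{\tau}{h^2}\Big(J_{i+\frac12,j}-J_{i-\frac12,j}
+J_{i,j+\frac12}-J_{i,j-\frac12}\Big) - \tau\, I_{ion}(V^k_{ij},\dots),$$

with $J_{i+\frac12,j} = \sigma_{i+\frac12,j}(V_{i+1,j}-V_{i,j})$ and zero
boundary fluxes (Neumann). One unsplit explicit step advances diffusion and
reaction together. The production grids are $(\tau, h)$ =
(0.005 ms, 125 µm) in 1D, (0.02 ms, 250 µm) in 2D, and
(0.0008 ms, 50 µm) for refinement checks; a guard rejects any pair
violating $\tau \le 0.9\,h^2/(4\sigma_{max})$.

The conductivity tensor is diagonal. Along-fiber coupling is fixed at
$\sigma_\parallel = 0.154$ mm²/ms and the cross-fiber value follows from
the anisotropy ratio, $\sigma_\perp = \sigma_\parallel / AR^2$, so that
$AR = v_\parallel/v_\perp$. Each internodal link takes the conductivity of
the region containing its midpoint; the border lies on a half-node plane,
and a node exactly on the border belongs to the left (transverse) region.

The TP06 epicardial parameter set is compiled into the package verbatim
(`src/tp06_core.cpp`, constants block). Gating variables advance by
Rush–Larsen exponential steps by default — unconditionally stable for the
gate subsystem and standard practice for this model — while V and the
intracellular concentrations use forward Euler, matching the explicit
scheme above; a pure forward-Euler gate mode (`gates = "euler"`) exists for
scheme-fidelity comparison and differs by well under 0.01 mV RMS at
$\tau = 0.005$ ms. Voltage-dependent coefficients are tabulated on a
0.05 mV grid with linear interpolation (`use_lut = FALSE` evaluates them
exactly; the two paths agree to ~10⁻⁴ mV). Reversal potentials are
refreshed from the slowly moving concentrations once per millisecond.
Nodes that start at the quiescent steady state are frozen until the
diffusive foot of a wave reaches them (`lazy = TRUE` in the search
protocols); the frozen residual is below 10⁻⁵ pA/pF, and bisection results
with and without freezing agree within the bisection tolerance.

An independent cross-check ships with the package: a separate Python/scipy
(LSODA, rtol 10⁻⁸) integration of the same model
(`tools/make_reference_trace.py`) whose quiescent state and 1 Hz action
potential are frozen as text fixtures; the compiled kernel reproduces the
resting state to ~10⁻³ mV and the AP to well under 1 mV RMS. Published
TP06 anchors (resting potential, APD90 ≈ 301 ms at 1 Hz, cable conduction
velocity ≈ 0.68 mm/ms at h = 0.25 mm) are asserted in the test suite.

## Protocols

**Equilibration.** Every simulation starts from a single cell integrated
50 s without stimulation, broadcast across the grid. The strict
convergence flag (per-ms relative change < 10⁻⁶ for every variable over
the final second) is typically still `FALSE` at 50 s because the quiescent
SR calcium pool drains on a timescale of minutes; this is a property of the
model, not an integration failure, so a separate `oscillating` flag
identifies the genuinely pathological regime (spontaneous activity when the
inward-rectifier conductance falls below ~10%, which this model enters
after roughly a minute of quiescent integration at 5% conductance).

**Stimulation.** A stimulus sets V to 50 mV for one step in a region: a
6-node-wide strip on the left edge for plane waves, a disc for 2D point
stimulation. This is the literal protocol of the study; no current
injection is modelled.

**Block classification.** Probes sit 10 mm proximal and distal of the
border. A paced wave is conducted iff the distal probe activates (upward
−20 mV crossing, 50 ms debounce) within one pacing period of the proximal
activation. For a single pulse the window is 500 ms *after the proximal
activation*; an earlier draft measured the window from the stimulus, which
silently misclassifies severe hyperkalemia, where cross-fiber conduction
slows to ~0.07 mm/ms and the wave legitimately needs more than 500 ms just
to reach the border. Reported border delays subtract the transit time of
an unbroken transverse cable of the same AR, isolating the border effect.

**Pacing trains.** Critical-AR and critical-frequency measurements use 7
stimuli: the first 3 are ignored as transients and the remaining 4
analyzed, so a 1:2 pattern is observed at least twice. For target periods
below the 2.7 Hz period the schedule ramps down by 5 ms per cycle before
holding (restitution protocol); ramp beats are always ignored.

**Searches.** The critical AR is bisected on [1.5, 8] with verified
endpoints to a tolerance of 0.01 (production) or 0.05 (routine test runs);
the critical period is bracketed to 5 ms as (T_pass, T_block); the lowest
blocking frequency is found on a 0.1 Hz grid. Because block is monotone in
frequency, the default frequency search bisects on the grid and verifies
that the next-lower grid point conducts — identical to the literal upward
scan (`search = "scan"`, available and tested) at a fraction of the cost.

**The critical-period curve.** Measured brackets are summarised by
$T(AR) = a + b\,AR^c/(AR_1-AR)^d$, with $AR_1$ the single-pulse critical
ratio and $a$ the short-period refractory asymptote. `fit_T_curve()` holds
$AR_1$ and $a$ fixed and least-squares fits $(b, c, d)$ on the log-period
scale of the bracket midpoints, starting from the exactly linearised
regression of $\log(T-a)$; the study does not state its loss function, and
the log scale weights the steep near-asymptote points sensibly.

## 2D reentry

The reentry experiment delivers two point stimuli at one site 6 mm into
the transverse region (S1S2, 500 ms apart; the study's captions admit
either one or two sites — one site is the default and both are
configurable) at AR 2.0 and 10 mM extracellular potassium. The S1 wave
crosses the border; the S2 wave, travelling into partially recovered
tissue, is blocked frontally but penetrates obliquely ~1 cm away, and the
free end curls into a reentrant pattern that drifts along the border
(faster border-parallel propagation on the transverse side shifts the core
upward for the induced chirality). An isotropic strip (8 mm by default)
centred on the border pins the drifting core.

The stimulus is placed at three quarters of the domain height. This
choice makes the induced wavebreak single-signed — the upper oblique
penetration point falls outside the tissue, so exactly one free end
survives — and the surviving rotor's chirality drives it upward, into the
larger free part of the domain (the mirror placement yields a
downward-drifting rotor that annihilates on the nearby edge within one
rotation). The
stimulus disc radius defaults to 2 mm: at 10 mM potassium a 1 mm disc
fails as a source against the surrounding load even though an isolated
cell recovers well before 500 ms — S2 then excites nothing. The radius is
a configuration parameter (the study does not state one), chosen once so
that S2 captures under the reference conditions.

Tip tracking locates, per recorded frame, grid cells where both the
V = −40 mV isoline and the dV/dt = 0 isoline pass (sign changes of both
fields inside a 2×2 cell), i.e. where wavefront meets waveback — a cheap
phase-singularity proxy adequate for drift-sign and confinement claims.
Among candidates the tracker keeps the one nearest the previous tip;
trajectories are smoothed with a 10 ms running mean. "Sustained" requires
at least two re-activations of a reference node after the last stimulus.

## Problem sizes used in the routine test run

The full acceptance computation (bisections to 0.01 on the [1.5, 8]
bracket, frequency searches over [0.5, 3.3] Hz, the 64 mm production
cable) lives in `scripts/acceptance.R`. The package's own test suite runs
the same physics at routine sizes chosen once: bisection tolerance 0.05 on
brackets that comfortably contain both the reported and the reproduced
thresholds, frequency searches on sub-ranges containing both candidate
answers, and reentry records truncated shortly after the rotor's last
re-activation (the full-size 64 × 32 mm sheet with 1 s post-S2 for the
drift experiment; a 48 × 24 mm sheet with 1.3 s post-S2 for the
isotropic-strip variant). The methods are identical; only the resolution
of the final answer differs.

## Known limitations and observed discrepancies

* The critical AR at the production grid agrees with the study's normal
  value within ~1.5% (3.77 vs 3.72), and most channel-block and
  hyperkalemia shifts reproduce within the stated ±0.1. Two cases sit
  outside: strong inward-rectifier suppression (25%: 5.66 here vs the
  study's fitted asymptote 6.20) and severe hyperkalemia (12 mM: 2.09 vs
  2.44). The study's AR₁ values are fitted vertical asymptotes of paced
  curves with the exponent d pinned at 0.333 in the inward-rectifier rows,
  which can overshoot a directly bisected single-pulse threshold; the
  study's own text quotes ≈6.0 at 1 Hz for the 25% case. The phase
  dissection equivalences (front-only ≈ full reduction, tail-only ≈
  normal) and every monotone ordering reproduce cleanly, so the mechanism
  — inward rectifier opposing the subthreshold foot of the wavefront — is
  intact; the absolute asymptote under strong suppression is sensitive to
  the exact subthreshold I_K1/I_Na balance.
* The critical AR is intrinsically grid-sensitive: at 50 µm resolution the
  normal threshold rises above 4.2 (the cross-fiber wavefront spans only
  one or two nodes at 125 µm). Block-versus-pass classification therefore
  is *not* invariant at AR = 4.0 across the two resolutions in this
  implementation; the coarse grid is the production condition and all
  reported numbers refer to it.
* The model's I_K1 outward peak at normokalemic concentrations lies near
  −66 mV (20 mV above the potassium reversal, as the TT04/TP06
  rectification function dictates; confirmed by the independent scipy
  evaluation of the same equations). The −50.86 mV quoted in the source
  literature originates from an experimental I–V curve and corresponds to
  a reversal potential near −71 mV (about 10 mM external potassium), not
  to this model at 5.4 mM.
* The velocity-ratio identity AR = v_par/v_perp holds only as the grid
  resolves the cross-fiber wavefront: at h = 125 um the measured ratio
  exceeds the nominal AR by ~7% (AR 2) to ~16% (AR 3), shrinking to
  1.4%/3.7% at the 50 um preset. AR values quoted by the package are the
  nominal sqrt(sigma ratio), exactly as the conductivities are
  constructed.
* Bidomain effects, 3D propagation, curved borders, other cell types and
  ischemic components beyond hyperkalemia are out of scope.
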