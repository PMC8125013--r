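---
title: "Zhu–Nakamura surface hopping on a calibrated photoswitch surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zhu–Nakamura surface hopping on a calibrated photoswitch surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zntraj)
```

## The model

`zntraj` simulates ultrafast internal conversion with trajectory surface
hopping: classical nuclei move on one adiabatic potential-energy surface
(velocity Verlet), and near quasi-degenerate regions the active
electronic state can switch stochastically. The switch probability is
the Zhu–Nakamura single-passage formula, a semiclassical generalization
of Landau–Zener theory that needs only quantities available from
adiabatic electronic-structure data — energies and gradients around the
crossing — and never non-adiabatic coupling vectors:

$$p = \exp\!\left[-\frac{\pi}{4a}\sqrt{\frac{2}{b^2+\sqrt{b^4\pm 1}}}\right],
\qquad
a^2 = \frac{\hbar^2\sqrt{F_1F_2}\,\lvert F_2-F_1\rvert}{2\mu\,(2V_{12})^3},
\qquad
b^2 = \frac{(E_t-E_x)\,\lvert F_2-F_1\rvert}{2V_{12}\sqrt{F_1F_2}} .$$

$F_1,F_2$ are the diabatic forces on the two curves that cross, reduced
from their multi-dimensional Cartesian forms by the mass-scaled sums
implemented in `mass_scaled_product()` and `mass_scaled_difference_sq()`
(these absorb the reduced mass $\mu$). $V_{12}$ is the diabatic
coupling, $E_x$ the crossing energy, and $E_t$ the potential energy plus
the kinetic-energy component along the hopping direction. The $+$
branch applies to the classically allowed case $E_t \ge E_x$.

Because the printed forms of such formulas are easily mangled by
typesetting, the convention adopted here is pinned *operationally* by
two independent checks that the test suite runs:

* in the weak-coupling, high-energy regime the single-passage
  probability must agree with the classic Landau–Zener closed form
  $p_{\mathrm{LZ}} = \exp(-2\pi V_{12}^2/\hbar v\lvert\Delta F\rvert)$
  to within a few percent, and
* across a scan of collision energies at moderate coupling it must track
  a numerically exact split-operator wavepacket calculation
  (`exact_transition_probability()`) to within ±0.05 absolute.

Dimensional analysis of the adopted forms confirms both parameters are
unitless; doubling $V_{12}$ scales $a^2$ by $1/8$ and $\lvert b^2\rvert$
by $1/2$, which the unit tests assert directly.

### Branch rule and degenerate inputs

The sign under the inner root is $+1$ for $E_t \ge E_x$ and $-1$
otherwise. On the forbidden branch the expression
$\sqrt{b^4-1}$ is clamped to zero when $b^4<1$, and the probability is
defined as zero whenever the bracket is non-positive. With the signed
$b^2$ convention used here the bracket is non-positive for *every*
$E_t < E_x$, so the forbidden branch contributes no hops: $p$ rises
continuously and monotonically with $E_t$ above the crossing and
vanishes below it, with a step at $E_t = E_x$. A smooth interpolation
across the branch point cannot be reconciled with the clamped $\pm$
form, and since hop attempts from the upper surface always satisfy
$E_t > E_x$ (the potential energy already exceeds the crossing mean),
the step is invisible to the dynamics; frustrated upward hops are
instead handled by the momentum-rescaling contract. Degenerate inputs
are defined explicitly: parallel equal forces ($D^2=0$) give
$a^2 = b^2 = 0$ and no hop; a non-positive force product $F_1F_2$
signals a non-Landau–Zener crossing topology — the magnitude is used
and the event is flagged `non_lz` in the hop log (this is the normal
situation at the surrogate's avoided crossing, where the two diabats
slope in opposite directions).

### Recovering the diabatic picture from adiabatic data

At a strict local minimum of the adiabatic gap along the trajectory
(three-point detection $g_{k-1}>g_k<g_{k+1}$, one attempt per minimum,
with a two-step refractory period afterwards), `diabatize_crossing()`
sets $V_{12}$ to half the minimum gap, $E_x$ to the mean adiabatic
energy there, and builds the diabatic forces by swapping the adiabatic
gradient assignment across the seam: diabat 1 follows the lower state
before and the upper state after the minimum, diabat 2 conversely, each
averaged over its two one-sided estimates.

Two numerical refinements matter in practice and are applied before
diabatization (`refine_crossing()`):

1. the seam position is located by parabolic interpolation of the gap
   through the three bracketing steps, and
2. the evaluation points for the gradients are pushed outward,
   symmetrically, until the gap has grown to three times its minimum.
   Inside the avoided-crossing mixing region the adiabatic gradients
   are rotated mixtures of the diabatic slopes and systematically
   underestimate $\lvert F_2-F_1\rvert$ and $\sqrt{F_1F_2}$; at
   $g \ge 3g_{\min}$ the local rotation angle satisfies
   $\cos 2\theta \ge \sqrt{1-(1/3)^2} \approx 0.94$, so the gradients
   are ≥94 % diabatic. Without this widening the recovered $a^2$
   fluctuates by an order of magnitude with the accidental placement of
   the trajectory steps around the seam.

The hopping direction is the unit vector along the mass-weighted
diabatic force difference $F_2-F_1$. Accepted hops solve the exact
energy-conservation quadratic for the momentum shift along that
direction (smaller root, i.e. least perturbation); if the discriminant
is negative the hop is frustrated and the velocities are untouched,
without velocity reversal — the simplest defensible contract.

## The surrogate surface

The dynamics application is the photoinduced ring closing of a
deoxyuridine-based diarylethene photoswitch. The reaction coordinate is
the distance between the two bond-forming carbons (C1–C6): open form at
3.302 Å, thermal transition state at 1.945 Å, S1/S0 conical
intersection at 2.103 Å, closed form at 1.517 Å. All electronic
structure is replaced by a one-dimensional two-state surrogate built
from the published relative energies at those geometries
(`psiv_anchors()`, kcal/mol relative to the open-form S0 minimum):

* **scan variant** — the excited-state relaxed-scan profile: S1 falls
  monotonically 73.0 → 45.6 kcal/mol from the open geometry to the
  crossing region and rises to 52.0 at the closed geometry, S0 runs
  34.4 → 44.0 → 18.9.
* **reactive variant** — the same S1 curve over the ground-state
  reaction path: S0 at 0.0 (open), 40.8 (thermal barrier), −5.6
  (closed). A single 1-D profile cannot honor both the S1-relaxed-scan
  S0 energies and the ground-state path, so both variants are shipped;
  the reactive variant supports both wells and is the default for full
  open↔closed dynamics, while the scan variant keeps the calibration
  checks faithful to the published scan.

Each state's curve is a monotone shape-preserving cubic through its
anchors (Fritsch–Carlson tangents; with only 3–4 anchors per state any
non-monotone interpolant would invent spurious wells), with zero
prescribed endpoint slopes so that harmonic walls attach with continuous
gradients and the open and closed wells sit exactly at 3.302 and
1.517 Å. A smooth floor keeps the adiabatic gap at or above
`gap_floor` near the crossing: identity where the raw gap exceeds
`gap_floor` + 10 % band, constant at the floor below it, with a C¹
quadratic blend between. Raw interpolants that actually cross are
rejected — a crossed adiabatic ordering cannot be regularized by a
floor. Anchors are reproduced exactly (to 10⁻⁹ kcal/mol and better)
whenever their own gap clears the floor band, which holds for both
variants at the default floor.

### Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `gap_floor` | 1.0 | kcal/mol | hop-point gaps of the reference simulations lie in 0–4 kcal/mol; ~1 keeps the adiabatic representation non-degenerate while preserving strong hopping |
| `mass_amu` | 6 | amu | effective reduced mass of two carbon-like fragments along an interfragment distance; the reference works in full dimensionality and states none |
| `open_wall_cm` | 300 | cm⁻¹ | loose interfragment mode of the open well (100–500 cm⁻¹ plausible range) |
| `closed_wall_cm` | 1200 | cm⁻¹ | compressing a freshly formed C–C σ bond is stiff, of the order of a C–C stretch |
| `dt_fs`, `t_max_fs`, `n_traj` | 1.0, 500, 40 | fs, fs, – | the reference protocol |
| `gap_threshold_kcal` | 30 | kcal/mol | gap gate below which hop attempts are made |
| `r_threshold_angstrom` | 1.70 | Å | strict product-classification threshold; a final frame at exactly 1.70 Å counts as open |

The anchor spacing of the published scan is not stated; the surrogate
assigns the printed endpoint energies to the optimized open/closed
distances (3.302 and 1.517 Å), which is the only placement consistent
with the printed geometries.

### What the surrogate emulates, and what it does not

It reproduces the printed energetics exactly at the anchors, the
barrierless S1 descent from the Franck–Condon region, an avoided
crossing at the right geometry (the minimum-gap point of the scan
variant falls at the 2.103 Å anchor), and a ground state supporting
both wells. It does **not** emulate vibrational energy redistribution:
the full molecule shares the ~73 kcal/mol of excitation energy among
3N−6 modes, whereas the 1-D surrogate keeps all of it in the reaction
coordinate. Three visible consequences, all computed by the test suite
on the default ensemble:

* after hopping down, trajectories retain enough energy to re-cross the
  crossing region and hop *upward* again (microscopic reversibility),
  so the S1 population partially recovers instead of decaying to zero
  and the fitted single-exponential lifetime is longer than a
  full-dimensional treatment would give;
* trajectories transiently visit C1–C6 distances below 1.70 Å while
  still on S1, so the first sub-threshold crossing can precede the
  first hop and the mean ring-closing time is not bounded below by the
  mean hop time on this surrogate;
* the hot trajectory rams the steep inner flank of the closed well
  (~100 kcal/mol/Å, as the printed anchor energies dictate), where the
  1 fs protocol step resolves the force only coarsely: total energy
  shows a bounded oscillatory error of a few kcal/mol there. The error
  scales as O(dt²) — halving the step brings the worst inter-hop
  deviation under 1 kcal/mol — and hop instants conserve energy to
  10⁻¹⁰ Hartree exactly, so the drift does not bias the hop statistics.
  The tests assert the protocol-step bound (< 5 kcal/mol), the
  half-step bound (< 1 kcal/mol) and the scaling.

Passing tests therefore demonstrate the *machinery* — calibration,
probabilities against exact quantum dynamics, conservation laws,
statistics — and qualitative features of the photoreaction (ultrafast
sub-500 fs decay onset, hops concentrated near 2.0–2.1 Å with gaps of a
few kcal/mol, both product channels populated); they do not certify the
full-dimensional rate constants or the quantum yield of the real
molecule.

## Initial conditions

Sampling is 0 K ground-vibrational-state Wigner only: position and
momentum Gaussians with $\sigma_x=\sqrt{\hbar/2\mu\omega}$,
$\sigma_p=\sqrt{\hbar\mu\omega/2}$ centred at the open-well minimum
with zero mean momentum. The frequency comes from the local curvature
of the lower surface at the minimum (`mode_from_curvature()`: gradient
root-bracketing to $\lvert\nabla E\rvert<10^{-8}$ Hartree/Bohr, central
finite difference with step 10⁻³ Bohr). The electronic state is then
set to S1 without touching the nuclei (vertical excitation). Thermal
Wigner sampling and excited vibrational states are out of scope.

Randomness is reproducible end to end: one master seed; the sampler
draws with it; trajectory $i$ uses the documented derived seed
$(\text{seed}\cdot 1009 + i) \bmod (2^{31}-1)$, so any single
trajectory can be re-run in isolation.

## The exact quantum oracle

`exact_transition_probability()` propagates a two-component wavepacket
on a 1-D diabatic linear-crossing model with Strang splitting: analytic
2×2 matrix exponential of the potential at every grid point
(half-steps), FFT kinetic full step. The propagation is unitary to
roundoff (the tests assert norm conservation to 10⁻⁸ over 10⁴ steps)
and aborts with an "enlarge grid" diagnostic if any amplitude reaches
the edges.

The scattering setup uses slopes of the same sign so both channels
leave the crossing; the incoming diabat is nearly flat so the collision
energy is well defined far from the seam. The packet starts on the
local *lower adiabat* (pointwise rotation of the diabatic amplitudes,
exact at any coupling strength) with width chosen so the energy spread
is ≤4 % of the collision energy, and the read-off — also by pointwise
adiabatic rotation — happens once every populated channel's mean
position has cleared the seam by max(25 Bohr, 3σ). The grid is sized
from the kinematics of the *fastest* outgoing front (the accelerated
channel) over that horizon. Default 2048 points; doubling the grid
changes the probability by less than 10⁻³ (asserted).

## Problem sizes

The shipped checks use: 40 trajectories × 500 steps for the protocol
ensemble (seconds on one CPU); a 10-point collision-energy scan against
the wavepacket oracle (about half a minute); 10⁵ Wigner draws for the
sampler moments; 100 Monte-Carlo replicates of the noisy decay-fit
recovery on 500-point grids. These sizes make the statistical
assertions sharp (3 standard errors for sampler moments, ±0.05 absolute
for the oracle comparison) while keeping the whole suite around a
minute.

## Known limitations

* One nuclear dimension; no vibrational energy redistribution, no
  thermostat, hence upward re-crossings (see above).
* Two electronic states only; no fewest-switches amplitude propagation,
  no decoherence correction — the Zhu–Nakamura probability is local by
  construction.
* The surrogate's gap at its avoided crossing (~1.6 kcal/mol for the
  scan variant at the 2.103 Å anchor, ~5.5 kcal/mol along the reactive
  path) is dictated by the printed anchor energies, not by the true
  conical-intersection topology, which is strictly degenerate at the
  apex.
* The exact oracle runs on analytic diabatic models only; the surrogate
  is validated through its construction invariants and the dynamics
  through conservation laws, not against exact dynamics on the
  surrogate itself.
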