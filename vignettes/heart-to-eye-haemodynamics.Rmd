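---
title: "Heart-to-eye arterial haemodynamics under gravity and simulated microgravity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-to-eye arterial haemodynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gravinet)
```

## What the package models, and what it does not

`gravinet` is a zero-dimensional (lumped, quasi-static) model of the
arterial path from the aortic root to the retinal circulation. Its
purpose is to study how blood flow *redistributes* between an upright
posture in Earth gravity and simulated microgravity, when three things
change at once: the gravitational body force disappears, stroke volume
rises (increased venous return), and lower-limb vascular resistance
rises. These are exactly the quantities a resistive network captures
well, because they act through resistances and source terms.

What a resistive network cannot capture: wall compliance and pulse-wave
propagation, flow inertia, secondary and recirculating 3D flows, and
therefore any realistic oscillatory shear. Flows in this model follow
the inflow waveform instantaneously. One consequence is embraced rather
than hidden: with an (almost) unidirectional inflow, the oscillatory
shear index is (near-)identically zero throughout the network, so the
`osi()` operator is provided and tested but no oscillatory-shear claims
are made.

## Rheology

Blood viscosity is evaluated per conduit from a three-regime blend,
continuous in diameter:

* **d < 0.6 mm — Fåhraeus–Lindqvist regime.** Apparent viscosity falls
  with tube diameter in the microcirculation. We use
  `mu_plasma * mu_rel(d, Hct)` with the Pries et al. in-vitro
  relative-viscosity fit (the standard basis of the retinal-tree
  literature this package follows), haematocrit 0.45 and plasma
  viscosity 1.2 mPa·s. The law is a pluggable function
  (`relative_viscosity_fn`) so an alternative fit can be swapped in
  without touching callers.
* **d > 1.2 mm — Carreau–Yasuda shear thinning.**
  η(γ̇) = η∞ + (η0 − η∞)[1 + (λγ̇)^a]^((n−1)/a) with η∞ = 3.5 mPa·s,
  η0 = 0.16 Pa·s, λ = 8.2 s, a = 0.64, n = 0.2128.
* **0.6–1.2 mm** — linear interpolation in diameter between the two
  values, weight w = (d − 0.6 mm)/0.6 mm.

In a 0D model there is no wall-distance field, so the diameter driving
the law is the conduit's nominal diameter, and the shear rate driving
the Carreau–Yasuda branch is the Poiseuille wall shear rate
γ̇ = 4|Q|/(πr³) of the conduit's own flow.

```{r rheology}
p <- rheology_params()
c(cy_zero_shear = carreau_yasuda_viscosity(0, p),
  cy_at_inv_lambda = carreau_yasuda_viscosity(1 / p$lambda_cy, p),
  fl_100um = fl_effective_viscosity(100e-6, p))
```

### Numerical handling of zero flow

At instants of (near-)zero flow the wall shear rate vanishes and the
Carreau–Yasuda law heads to its zero-shear plateau. That is physical,
but a literal γ̇ = 0 makes the viscosity update non-smooth, so shear
rates are floored at 1e-6 s⁻¹ (configurable `shear_floor`). At that
floor the law is within machine noise of η0, so the floor changes
nothing physically.

## Fractal-tree retinal outlets

Each central-retinal-artery outlet is closed by a deterministic
("structured") asymmetric bifurcating tree standing in for the retinal
arteriolar bed:

* radii: r_p^k = r_d1^k + r_d2^k with r_d2 = α · r_d1;
* lengths: L = lrr(d) · r with a piecewise-constant length-to-radius
  map;
* termination: a branch becomes a leaf when a daughter *diameter* would
  fall below the 4 μm capillary calibre; leaves drain to the 0 mmHg
  capillary datum;
* resistance: every segment is Hagen–Poiseuille 8μL/(πr⁴) with μ from
  the FL law (all tree vessels are below 0.6 mm — asserted at run time,
  not assumed), children combine in parallel, and the whole tree
  collapses to one equivalent resistance.

Defaults k = 2.76, α = 0.8, lrr = 50/40/30 for d < 60 μm / 60–150 μm /
> 150 μm. These are standard structured-tree (Olufsen-type) choices;
the retinal-tree literature spans a range of fitted values, so the
defaults are exactly that — defaults, exposed in `branching_params()` —
and the test suite pins behaviour (oracle equivalence, monotonicity,
viscosity linearity) rather than particular resistance values.

```{r tree}
bp <- branching_params()
tr <- build_structured_tree(163e-6 / 2, bp)   # CRA-calibre root
c(unlist(tree_summary(tr)),
  R_eq = tree_resistance(tr, p))
```

The ~1e13 Pa·s·m⁻³ equivalent resistance puts CRA flow in the tens of
μl/min at arterial pressures — the physiological range.

## Murray's-law outlets and the extruded-outlet encoding

All non-retinal outlets are designed from a cardiac-output split table:
each region (celiac 14%, cerebral 12.78%, coronary 5%, external carotid
9.45%, internal iliac 4%, external iliac 9%, ophthalmic 0.68%,
mesenteric 16%, renal 23%) receives its share of systolic flow, the
subclavian share is *computed* as the residual (a regression test — it
must come out at 6.09% — not an input), and within a region flow is
weighted by r³ (Murray's law). At the systolic design point (P_sys,
Q_sys) with a zero distal datum this fixes each outlet resistance in
closed form.

P_sys and Q_sys are not part of any printed table; they are required
configuration with documented physiologic defaults: 120 mmHg and the
synthetic waveform's systolic peak (2.1e-4 m³/s at the default 70 ml /
60 bpm / peak-to-mean 3). Whether the design flow should be the
systolic instantaneous peak or a cycle value is genuinely open; we use
the systolic peak, consistently with reading "systolic pressure and
flow" as a single instant.

Every outlet resistance — fractal or Murray — is then encoded as an
*extruded outlet*: a virtual stub of length exactly twice the outlet
diameter whose fictitious viscosity μ = Rπr⁴/(8L) reproduces R, with
a zero-pressure distal face at the outlet's own elevation. Note the
algebra: μ is *inversely* proportional to the extrusion length at fixed
R (a longer stub needs thinner fluid to present the same resistance).

## The quasi-static solve and gravity

At each waveform sample the solver assembles nodal flow balance with
segment flows Q = (P_from − P_to − ρgΔz)/R_seg(μ) and outlet drains
Q = P_node/R_out (distal pressure 0 at the outlet's own elevation,
mirroring a zero-pressure extrusion face), injects the instantaneous
inlet flow, and solves the dense linear system (networks here are ~100
nodes; no sparse machinery is warranted). Gravity therefore enters
purely as hydrostatic heads: in the upright case the eye (+0.35 m) pays
≈3.6 kPa of head, the iliac outlets (−0.55 m) gain ≈5.7 kPa.

The shear-thinning nonlinearity is resolved by under-relaxed Picard
iteration (factor 0.5) on segment viscosities to a relative tolerance of
1e-6, warm-started from the previous instant. The cap is 200
iterations: at instants where a near-zero-flow bridge vessel (e.g. a
communicating segment) sits in the steep part of the Carreau–Yasuda
curve the contraction rate approaches ~0.75, and a 50-iteration cap —
fine for typical instants — lands just short of tolerance; 200 gives
comfortable margin without masking true non-convergence. The converged
solution is checked (in tests) to be independent of the initial
viscosity guess.

Because the network carries no state, successive cardiac cycles are
identical. `run_case()` exploits this: one cycle is solved and reused,
and the cycle-convergence report (cycle-averaged outlet flows changing
by < 3% between the final two cycles, the usual CFD criterion) is
trivially satisfied at machine precision. `recompute_cycles = TRUE`
forces a genuine multi-cycle march; the test suite uses it to verify
cycle-to-cycle identity rather than assume it. The default time step
0.001 s is retained from common practice for waveform resolution even
though a quasi-static solve has no stability constraint.

## The microgravity transform

`apply_microgravity()` derives the second case from the first:

* inflow waveform scaled vertically so stroke volume rises by exactly
  20% (cardiac output increase with near-constant heart rate);
* every **external-iliac** outlet resistance multiplied by exactly 1.93
  (elevated lower-limb vascular resistance), with the extruded-outlet
  effective viscosity recomputed so the encoding stays consistent;
  "external iliac" is taken literally — internal-iliac outlets are
  untouched, as are all other regions;
* g set to 0.

## The synthetic geometry: what it emulates, what it does not

No reference geometry is bundled with the package, so
`generate_network()` builds a synthetic stand-in with the *structure*
the analysis needs: a connected tree from the aortic root through arch,
carotid/vertebral and circle-of-Willis junctions to 32 cerebral
outlets and two CRA outlets at eye level (+0.35 m), coronary outlets
at heart level, visceral outlets along the descending aorta, and
internal/external iliac outlets below (−0.55 m at the external-iliac
terminals) — 72 outlets in the region census of the split table, CRA
diameter 163 μm. Elevation anchors (eye +0.35, cerebral +0.40, iliac
−0.55 m) are typical adult upright anatomy; heart rate 60 min⁻¹ and
stroke volume 70 ml are physiologic conventions. All are configurable
and flagged as assumptions.

The inflow is a raised-cosine systolic pulse over 35% of the cycle on a
diastolic plateau, peak-to-mean ratio 3, normalised so the sampled
stroke volume is analytically exact. It stands in for a measured aortic
waveform; it has the right gross features (single systolic peak,
non-negative, correct stroke volume) and none of the fine ones (no
dicrotic notch, no early-diastolic reversal).

Consequently, a green directional test establishes that *this class of
model*, under the stated transform, shifts flow head-ward and away from
the legs — robustly across ±10% seeded geometry jitter. It does **not**
establish absolute flows or shear stresses, nor specific percent
changes: those belong to a particular 3D geometry and waveform.
Two known distortions deserve naming:

* the Murray design point makes mean arterial pressure ≈ P_sys/3
  (~40 mmHg) at mean inflow, because outlets are sized at the systolic
  peak; upright cerebral/ocular perfusion is therefore unrealistically
  sensitive to the ~3.6 kPa eye-level head, inflating relative
  head-ward changes in microgravity;
* left/right asymmetries in the source data arise from subject anatomy;
  the synthetic network is bilaterally symmetric by default (jitter 0),
  so no such asymmetry is modelled.

## Metrics

Per-segment wall shear is the Poiseuille surrogate τ_w = 4μQ/(πr³)
(cross-checked in tests against the momentum balance τ_w = rΔP/2L on a
solved pipe). TAWSS is the cycle mean of |τ_w|; OSI is
0.5(1 − |∫τ|/∫|τ|) with the all-zero series defined as 0. Velocity
metrics are reported as mean velocity Q/(πr²) (and optionally the
parabolic centreline value 2Q/(πr²)), explicitly labelled — a 3D
maximal-velocity probe is not claimed. Comparison tables round percent
changes to integers (publication format) while retaining full precision
in a companion column; published-table regression tests use only rows
whose 2-significant-figure inputs round consistently.

## Determinism and seeds

The structured tree is deterministic by construction (no sampled
radii). The geometry generator is deterministic at jitter 0 and seeded
otherwise; `perturb_geometry()` is the explicit robustness harness.
Reports regenerate byte-identically from identical inputs.

## Known limitations

No compliance, inertia, autoregulation, venous return or intraocular /
cerebrospinal pressure coupling; rigid vessels; laminar Poiseuille
resistance in every conduit regardless of Reynolds number; OSI
degenerate by construction; synthetic geometry not subject-specific.
All are deliberate: the package isolates the boundary-condition and
rheology machinery and the gravity transform, which is where its test
surface lies.
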