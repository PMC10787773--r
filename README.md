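# gravinet

Reduced-order (0D) haemodynamics of a continuous heart-to-eye arterial
network, built to compare an upright Earth-gravity posture against
simulated microgravity — the fluid-shift regime implicated in
spaceflight-associated neuro-ocular syndrome (SANS).

The package is aimed at cardiovascular modellers who want the *boundary
condition and rheology machinery* of large-artery CFD — diameter- and
shear-dependent blood viscosity, structured fractal-tree outlet
resistances for the retinal microcirculation, Murray's-law outlet design
from cardiac-output splits, effective-viscosity "extruded outlet"
encoding — in a form that runs in seconds on a laptop, at the price of a
quasi-static resistive reduction (no compliance, no inertia, no 3D
fields).

## The model

**Rheology.** Apparent blood viscosity is evaluated per vessel from a
blended law:

- diameter d < 0.6 mm — Fåhraeus–Lindqvist regime: μ = μ_plasma ·
  μ_rel(d, Hct), with μ_rel the Pries et al. in-vitro relative-viscosity
  fit (Hct = 0.45, μ_plasma = 1.2 mPa·s);
- d > 1.2 mm — Carreau–Yasuda shear thinning:
  η(γ̇) = η_∞ + (η_0 − η_∞)[1 + (λγ̇)^a]^((n−1)/a), with η_∞ = 0.0035 Pa·s,
  η_0 = 0.16 Pa·s, λ = 8.2 s, a = 0.64, n = 0.2128, evaluated at the
  Poiseuille wall shear rate γ̇ = 4Q/(πr³);
- 0.6–1.2 mm — linear interpolation in diameter between the two.

**Outlet boundary conditions.** Each retinal (central retinal artery,
CRA) outlet is closed by a structured asymmetric fractal tree: parents
of radius r_p spawn daughters via r_p^k = r_d1^k + r_d2^k with
r_d2 = α·r_d1, lengths follow a diameter-dependent length-to-radius
map, branching stops at the 4 μm capillary calibre, and the tree is
collapsed to one Hagen–Poiseuille equivalent resistance (FL viscosity
throughout). Every other outlet gets a resistance from its region's
cardiac-output share and cube-of-radius (Murray) weighting:

    R_i = P_sys / (Q_sys · CO_split · r_i³ / Σ_j r_j³)

Any outlet resistance is then re-expressed as an *extruded outlet*: a
stub of length twice the outlet diameter whose fictitious effective
viscosity μ_i = R_i π r_i⁴ / (8 L_i) reproduces the resistance, with a
zero-pressure distal face.

**Network solve.** A quasi-static nodal solve of the resistive vessel
graph at every waveform sample: segment flow obeys
Q = (ΔP − ρgΔz)/R(μ), gravity enters as hydrostatic heads (ρ = 1050
kg·m⁻³, g = 9.81 m·s⁻² upright, 0 in microgravity), and the
shear-thinning viscosity is iterated to a fixed point. The microgravity
case scales stroke volume by exactly 1.2, multiplies external-iliac
outlet resistance by 1.93, and sets g = 0.

## Worked example

```r
library(gravinet)

inp <- build_study_inputs(dt = 0.001)       # synthetic network + inflow
res_g <- run_case(inp$net, inp$wave, gravity_case(), inp$params)

mg <- apply_microgravity(inp$wave, inp$net$outlets, gravity_case())
net_mg <- inp$net; net_mg$outlets <- mg$outlets
res_u <- run_case(net_mg, mg$wave, mg$cc, inp$params)

build_comparison_report(res_g, res_u)
```

Output (abridged; full table has ICA/VA mass flows and per-region
TAWSS):

```
Gravity vs simulated-microgravity comparison

         quantity                units   gravity microgravity pct_change
   ICA_L MFR_peak                 kg/s 7.540e-03    1.338e-02         78
     CRA_L Q_peak               ul/min 5.213e+01    8.823e+01         69
      CRA_L Q_ave               ul/min 5.398e+00    2.934e+01        443

Combined (left+right) retinal flow:
  retinal Q_peak (combined): 88.2 +- 0.0 vs 52.1 +- 0.0 ul/min (+69%)

Region TAWSS (Pa):
           region gravity_Pa microgravity_Pa pct_change
         cerebral     1.2690          2.8380        124
   external_iliac     0.5069          0.2083        -59
```

Reading this: per-side CRA flow and cerebral-region shear rise under
simulated microgravity while external-iliac flow and shear fall — the
directional signature of the head-ward fluid shift. Magnitudes are those
of the synthetic stand-in geometry under a quasi-static reduction and
are deliberately *not* calibrated to any individual; the upright case's
low cerebral perfusion (hence the large relative changes) is an honest
consequence of the Murray design point, discussed in the methods
vignette. Only the directions are asserted by the test suite.

A command-line interface wraps the same pipeline:

```sh
Rscript inst/cli/gravinet.R synth --seed 1 --out model/
Rscript inst/cli/gravinet.R compare-cases --network model/ \
    --waveform model/waveform.csv --out results/
```

## Layout

- `R/rheology.R` — blended FL / Carreau–Yasuda viscosity
- `R/fractal_tree.R` — structured-tree outlet resistances
- `R/boundary_conditions.R` — split table, Murray's law, extruded outlets
- `R/network.R`, `R/solver.R` — vessel graph, quasi-static pulsatile solver,
  microgravity transform
- `R/synthetic_geometry.R` — synthetic heart-to-eye network and inflow
- `R/metrics.R` — peak/average flows, Poiseuille WSS, TAWSS, OSI, report
- `vignettes/heart-to-eye-haemodynamics.Rmd` — methods and modelling choices
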