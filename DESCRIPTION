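Package: gravinet
Title: Heart-to-Eye Arterial Network Haemodynamics Under Gravity and
    Microgravity
Version: 0.1.0
Authors@R:
    person("Vascular", "Modelling", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reduced-order (0D) modelling of a continuous heart-to-eye
    arterial network.  Provides a blended blood rheology model combining
    the diameter-dependent Fahraeus-Lindqvist effect in small vessels
    with Carreau-Yasuda shear thinning in large vessels, structured
    asymmetric fractal-tree boundary conditions for retinal arteriole
    outlets, Murray's-law outlet resistances driven by cardiac-output
    splits, conversion of any outlet resistance to an effective-viscosity
    extruded outlet, a quasi-static pulsatile resistive network solver
    with hydrostatic gravity heads, a synthetic heart-to-eye geometry and
    inflow-waveform generator, and haemodynamic metric extraction
    (peak/average flows, Poiseuille wall shear stress, TAWSS, OSI) for
    comparing an upright Earth-gravity case against simulated
    microgravity (increased stroke volume, raised lower-limb resistance,
    zero gravitational acceleration).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
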