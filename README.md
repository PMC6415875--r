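# chamberflux

Quantifying CO2 deprivation in sealed Petri-dish plant cultures.

Sealed in vitro cultures of *Arabidopsis thaliana* (agar plates wrapped in
Parafilm or Micropore tape) are a workhorse of plant biology, yet the seal
itself throttles gas exchange: photosynthesis and respiration drive the
in-dish CO2 concentration far from ambient, and the culture can be severely
CO2-deprived. chamberflux is for experimenters who log in-dish CO2 with
cheap NDIR sensors and want defensible whole-culture exchange rates out of
those traces.

The core computation treats the dish as a one-compartment chamber and
inverts its mass balance for the net plant CO2 exchange rate
J_plant (umol m^-2 s^-1, uptake negative):

    V dC_in/dt = J_plant(t) A_plant(t) + (D_eff/Dx) A_seal (C_out - C_in)

where the second term is Fick's-law permeation through the seal membrane
(effective diffusivity D_eff, thickness Dx, seal area A_seal) and A_plant
is the leaf area from a power-law growth fit of daily photographs. Around
the inversion the package provides: NDIR calibration against standard
gases, 60-s trace averaging with duty-cycle gap handling, seal-permeability
estimation from box-decay experiments, exponential fitting of light/dark
transition kinetics (peak flux J_max, steady state J_ss, time constant
tau), MRPP pathway-level testing of expression count matrices
(upper-quartile logCPM normalization, permutation p-values, BH-FDR),
hue-angle kernel-density and starch-stain phenotyping, and forward
simulators for every input so the whole chain is testable end-to-end.

## Worked example

Simulate one day-10 Parafilm-sealed dark period (8 h) with realistic sensor
noise, then run the full measurement chain — calibration fitted from
standard-gas readings, 60-s averaging, mass-balance inversion with a
refitted leaf-area law, and the transition-kinetics fit:

```r
library(chamberflux)

r <- recover_scenario("parafilm_day10_dark", seed = 42)
r$kinetics
#> <exponential_kinetics> J_max 8.466, J_ss 0.8641 umol m-2 s-1, tau 43.7 min (R^2 0.842)

ss <- steady_state_flux(r$flux, 0, 8 * 3600)
sprintf("tail steady state: %.3f +/- %.3f umol m-2 s-1", ss$mean, ss$se)
#> "tail steady state: 0.871 +/- 0.056 umol m-2 s-1"
```

The simulated culture releases CO2 after lights-off with a peak near
8.2 umol m^-2 s^-1 and relaxes exponentially (tau = 44 min) to a steady
respiration of 0.86; the recovered values (J_max 8.47 from a noisy
extremum search, tau 43.7 min, J_ss 0.864) agree within the sensor-noise
scatter, and the model-free tail mean corroborates the fitted asymptote.

Seal permeability from a simulated box-decay experiment (dish equilibrated
at 400 ppm placed in a well-mixed 3000 ppm box):

```r
seal <- seal_properties("micropore")
bd <- simulate_box_decay(seal$permeability_m_s, box_ppm = 3000, C0_ppm = 400,
                         duration_s = 1800, noise_sd_ppm = 3, seed = 42)
estimate_permeability(bd$inside, bd$box, thickness_m = seal$thickness_m,
                      seal = "micropore")
#> <seal_properties> micropore: Dx = 6.79e-05 m, D_eff = 7.97e-08 m^2/s, D/Dx = 0.00117 m/s
```

recovering the ground-truth D_eff = 8e-8 m^2/s within 0.4%.

A YAML-driven pipeline (`run_pipeline()`, stages
`simulate | calibrate | diffusivity | leafarea | flux | kinetics |
pathways | hue | starch`) chains the same functions over artifact files
with provenance headers; `inst/cli/chamberflux.R` is a thin shell wrapper
over it.

## Documentation

The methods vignette (`vignettes/chamberflux-methods.Rmd`) describes the
chamber model and its assumptions, the kinetics and permeability
estimators, the synthetic-data generators and what they deliberately omit,
the pathway-testing procedure, and the package's numerical choices and
limitations.
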