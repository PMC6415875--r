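---
title: "Inferring CO2 exchange in sealed Petri-dish cultures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring CO2 exchange in sealed Petri-dish cultures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chamberflux)
```

## The measurement problem

In vitro plant cultures — typically *Arabidopsis thaliana* seedlings on agar
in 10 cm square Petri dishes — are routinely sealed with paraffin film
(Parafilm) or porous surgical tape (Micropore). The seal restricts gas
exchange, so photosynthesis and respiration of the plants themselves drive
the in-dish CO2 concentration far from the room level, and the culture can
become severely CO2-deprived. chamberflux treats the sealed dish as a
single-compartment gas-exchange chamber and recovers the whole-culture
exchange rate from an in-dish NDIR CO2 trace.

The mass balance of the dish headspace is

$$V \frac{dC_{in}}{dt} \;=\; J_{plant}(t)\,A_{plant}(t)
  \;+\; \frac{D_{eff}}{\Delta x}\,A_{seal}\,\bigl(C_{out} - C_{in}\bigr),$$

where $V$ is the headspace volume (1.1e-4 m^3 for the default dish), $C$ are
molar concentrations (mol m^-3, from ppm via the ideal-gas law),
$J_{plant}$ is the net exchange rate per unit leaf area (umol m^-2 s^-1;
uptake negative, release positive — conceptually the sum of photosynthetic
uptake and respiratory release), $A_{plant}$ the total leaf area, and the
second term is Fick's-law permeation through the seal, with effective
diffusivity $D_{eff}$, thickness $\Delta x$ and seal area $A_{seal}$
(dish perimeter times the 1 mm plate gap). `invert_flux()` solves this for
$J_{plant}(t)$ pointwise.

The processing chain mirrors how the raw data are actually produced:

1. **Calibration** (`fit_calibration()`, `apply_calibration()`): NDIR
   sensors are linear over 0-1000 ppm, so readings against standard gases
   (0, 100, 500, 1000 ppm) define a least-squares line mapping raw readings
   to true ppm. We fit `true ~ raw` directly; for a line this is equivalent
   to inverting a `reading ~ input` fit and gives a simpler contract.
2. **Averaging** (`average_window()`): 1 Hz readings are averaged over
   non-overlapping 60 s windows (timestamp = window midpoint). Because the
   calibration is affine and averaging is linear, the two operations
   commute; the suite asserts this, so the unspecified order is immaterial.
3. **Inversion** (`invert_flux()`): $dC_{in}/dt$ by central differences on
   the 60-s grid, one-sided at segment boundaries. Sensors are duty-cycled
   (powered off roughly daily), so traces carry explicit gap/segment
   structure and differences are never taken across a gap — differencing
   across a multi-hour hole would manufacture spurious flux spikes.
4. **Kinetics** (`fit_transition_kinetics()`, `steady_state_flux()`): see
   below.

## Transition kinetics

After a light/dark transition, $J_{plant}$ of a Parafilm-sealed culture
shoots to an extremum within minutes and then relaxes roughly exponentially
toward a small steady value. The package models this within a phase as a
linear ramp to the peak followed by

$$J(t) = J_{ss} + (J_{peak} - J_{ss})\,e^{-(t - t_{peak})/\tau}.$$

The ramp shape before the peak is an explicit modelling assumption: only
the time-to-peak (minutes) is observable at 60-s resolution, and a linear
rise is the simplest continuous choice.

The fit locates $t_{peak}$ as the argmax of $|J|$ within a 15-min
post-transition search window (the observed peaks sit at 3-9 min;
earliest time wins ties) and fits $J_{ss}$, $\tau$ and the peak amplitude
$J_{peak}$ by least squares from $t_{peak}$ to the end of the phase,
excluding the final 5 min before the next transition. Two numerical
choices matter:

* **The peak amplitude is a free parameter**, initialized at the observed
  extremum (which is separately reported as `J_max`). Anchoring the curve
  exactly at the single observed peak sample couples the whole fit to one
  noisy measurement; at the default sensor noise this biased recovered
  $\tau$ by several minutes in replicate experiments, while freeing the
  amplitude removes the bias (the exponential is self-similar, so $\tau$
  and $J_{ss}$ do not depend on which post-peak sample anchors the curve).
* **Robust initialization**: $\tau$ is profiled on a log grid — for fixed
  $\tau$ the model is linear in $(J_{ss}, J_{peak})$, so each grid point is
  a plain regression — and the best profile point seeds a Levenberg-
  Marquardt refinement. If the refinement fails (e.g. near-zero overshoot
  in fast-equilibrating Micropore dishes), the profile solution is used.

An extremum at the search-window edge is accepted as a (possibly
noise-displaced) peak when the flux declines beyond the window, and flagged
`undefined` when it is still rising — a monotone flux has no relaxation to
fit, and only a steady-state summary is returned. Steady states are also
estimated model-free as the mean over the final quarter of a phase
(`steady_state_flux()`), which reports both the standard error and the tail
standard deviation since either convention appears in practice.

## Seal permeability from box decay

$D_{eff}$ of a seal is estimated from a separate experiment: a sealed dish
equilibrated at ambient CO2 sits in a large, well-mixed box at a high CO2
level (a sublimated dry-ice source), and the in-dish trace relaxes toward
the box level through the seal alone, with time constant
$\tau_{box} = V\,\Delta x / (D_{eff} A_{seal})$. Each averaged time point
yields a Fick's-law estimate

$$D_t = \frac{V\,(dC_{in}/dt)\,\Delta x}{A_{seal}\,(C_{out} - C_{in})},$$

and the reported $D_{eff}$ is the mean over points with its standard error
(the error construction is a package choice; the per-point table is
attached for other conventions). Because $D_t$ is a ratio of a rate to a
difference of the same quantity, the ppm-to-molar conversion cancels, and
the estimate is invariant to affine calibration — the same property that
motivates the dimensionless form $(C - C_{avg})/(C_{max} - C_{avg})$
(`dedimensionalize()`) used to overlay replicate decays. Points where the
gradient has decayed below 10% of its initial value are excluded: using
literally every point along the curve makes the estimator divide by
near-zero gradients at equilibrium and blow up under noise. The mean over
the trace (default conditions) is computed over the analysis window only;
pre-placement samples should be trimmed before estimation. Reference
values: Parafilm $\Delta x$ = 46.9 um, $D_{eff}$ = 1.0e-9 m^2 s^-1
(permeability 2.13e-5 m s^-1, dish time constant ~3.6 h); Micropore
$\Delta x$ = 67.9 um, $D_{eff}$ = 8e-8 m^2 s^-1 (~4 min).

## Leaf area

$A_{plant}(t)$ comes from daily plate photographs: pixels inside an HSV
window (default hue 60-180 deg, S, V >= 0.15 — thresholds are a package
default, configurable) are counted and scaled (`segment_leaf_area()`), and
the daily areas are fitted with a power law $A = a\,t^b$ on the log-log
scale ($t$ in days since sowing; day-0 and zero-area points are excluded
from the log fit) and evaluated on the 60-s grid of the trace
(`interpolate_area()`; extrapolation outside the photographed range
requires an explicit flag).

## The forward simulators

Every pipeline input has a generator, so the whole chain is testable
end-to-end without the (undeposited) raw recordings.

`simulate_chamber()` integrates the mass balance with an explicit Euler
scheme at 1 s steps (a stability guard refuses steps above a tenth of the
membrane time constant; chamber time constants are minutes to hours, so
stiffness is not an issue), then produces raw sensor readings through a
linear sensor response with i.i.d. Gaussian noise, default sd 3 ppm per
1-s sample — consistent with +-30 ppm-class NDIR hardware once 60-s
averaging (which reduces it to ~0.4 ppm) is taken into account. The room
trace defaults to a constant 400 ppm; square "experimenter breathing"
excursions can be injected via a time-varying room function but are off by
default. The noiseless ground truth is returned alongside the noisy
readings. `simulate_box_decay()` uses the exact exponential update of its
constant-coefficient ODE, so noiseless decays match the closed form to
machine precision.

The reference scenarios (`chamber_preset()`, `flux_presets()`) encode the
measured day-10 and day-6 kinetics of 15-plant cultures: Parafilm dark
(peak release 8.19 umol m^-2 s^-1 at ~3 min, tau 44 min, steady 0.86),
Parafilm light (peak uptake -11.33 at ~9 min, tau 28 min, steady -1.080),
day-6 Parafilm light (peak -27.7, steady -4.40), and Micropore steady
states (10 dark, -19.3 light, reached within ~20 min). Two quantities are
not separately characterized and are package choices: the Micropore
transient (tau = 5 min with a ~10% overshoot — immaterial, since Micropore
summaries use the tail mean) and the day-6 relaxation time (taken equal to
the day-10 light value of 28 min). The leaf-area law default
($a$ = 1.14e-7 m^2 day^-b, $b$ = 2.5, i.e. ~0.10 cm^2 at day 6 and
~0.36 cm^2 at day 10) was chosen so that the simulated traces reproduce the
observed extreme concentration slopes (about -6 and +4 ppm/min at day 10)
given the peak fluxes above; it represents small, stressed in vitro
rosettes, not soil-grown plants.

What the simulator deliberately omits: the CO2-depleted boundary layer at
the leaf surface (the biological cause of the day-6 uptake suppression; no
quantitative model is available), multi-layer seal wrapping effects,
sensor drift, and room-level diel cycles. Passing recovery tests therefore
demonstrate correctness of the *inference chain*, not realism of every
physiological detail.

`simulate_counts()` generates negative-binomial count matrices (lognormal
per-gene baselines, lognormal library-size factors, configurable
dispersion) in which genes of designated pathways receive a log2
fold-change in group 2, with the affected set recorded as ground truth.
`simulate_rosette_image()` renders disc-blob rosettes with controlled hue,
saturation and stain darkness for the imaging operators.

## Pathway-level expression testing

The transcriptomic arm asks whether predefined gene sets (pathways) differ
between two culture treatments, without parametric assumptions. Counts are
normalized by the upper-quartile method — per-sample 75th percentile of
nonzero counts (linear-interpolation quantile; the convention is recorded
since several are in circulation), rescaled to geometric mean 1 — and
converted to $\log_2$ counts-per-million with a half-count offset,
$\log_2\!\bigl((n + 0.5)/(f \cdot N + 1) \cdot 10^6\bigr)$. Genes are then
scaled to unit variance so each contributes comparably to multivariate
distances.

For each pathway, the multiresponse permutation procedure (MRPP) statistic

$$\delta = \sum_g \frac{n_g}{N}\,\xi_g,$$

with $\xi_g$ the mean pairwise Euclidean distance among group $g$'s samples
in the pathway's gene subspace (classical MRPP group weights $n_g/N$; the
weighting variant and distance are explicit configuration, not a claim
about any particular historical run), measures within-group cohesion:
small $\delta$ means the groups separate. Significance comes from the
permutation null — labels are permuted across samples and
$p = (1 + \#\{\delta_{perm} \le \delta_{obs}\})/(1 + n_{perm})$, or the
exact proportion when all distinct assignments (at most 20,000) are
enumerated. Pathways with a single present gene are still tested but
flagged; groups below two samples cannot be tested. Benjamini-Hochberg
selection across pathways controls the FDR at 5% by default. The suite
verifies exactness on an enumerable example, uniformity of null p-values,
a ~5% type-I rate over hundreds of null pathway tests, power monotone in
effect size, and agreement of $\delta$ with an independent implementation.

## Imaging phenotypes

Discoloration is quantified as the distribution of hue angles: photographs
are first histogram-matched per channel to a reference image from the same
experiment (monotone 8-bit CDF mapping, so pixel ranks are preserved),
leaf pixels are converted RGB -> HSV, and the hue angles (degrees; green =
120) enter a Gaussian kernel density with bandwidth 0.8 on the hue-angle
axis. The bandwidth unit is ambiguous in common usage; here it is degrees
on the axis as plotted, and it is configurable. The kernel is evaluated
with circular wrap-around — green hues sit far from the 0/360 seam, so
this matches the usual non-circular plots in practice while remaining
correct in general. Achromatic pixels carry no hue and are excluded with
their count reported.

Starch staining (Lugol iodine) is scored as mean 8-bit darkness,
$255 - \mathrm{gray}$, per leaf mask, using luminance weights
(0.299, 0.587, 0.114) for the grayscale conversion; darker stain = more
dye = more starch. The mean background darkness is reported so that images
shot under the same lighting can be checked for comparability.

## Problem sizes, determinism, limitations

The recovery experiments in the test suite and acceptance script use
single-phase simulations (8 h dark / 16 h light at 1 s steps, averaged to
60 s), 25-50 noise replicates per experiment, and permutation tests with
199-10,000 permutations — sizes chosen so the full suite runs in minutes
on a laptop while keeping Monte-Carlo error well inside the tolerances
being asserted. All stochastic steps take explicit seeds; identical
configuration and seed reproduce outputs byte-identically
(`write_results()` records the config hash and seed in every artifact
header).

Known limitations: the inversion reports only the *net* exchange
$J_{plant}$ — photosynthesis and respiration cannot be separated within a
phase; the two averaged samples adjacent to each transition (and the
ramp/exponential kink) carry a differencing artifact and are excluded from
round-trip error bounds; leaf areas from backside photographs carry an
unmodelled projection bias; and the pathway test's distance/weight choices
follow the classical MRPP, which is one of several variants in use.
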