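---
title: "Correcting and fitting rapid A-Ci curves from large chambers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting and fitting rapid A-Ci curves from large chambers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racirkit)
```

## The problem

Rapid CO2-response measurement (RACiR) replaces the classic stepped
A-Ci protocol with a continuous CO2 ramp, cutting a 30-60 min
measurement to a few minutes. The price is that the instrument's
steady-state gas-exchange equations are applied to a system that is not
at steady state: the chamber's mixing volume and transport lines delay
and smear the sample-cell signal relative to the reference cell, and
analyzer match offsets add a slowly varying bias. For conifers the
problem is acute because needle geometry demands a large cuvette
(193.7 cm3 here, versus ~87 cm3 for a typical broadleaf fluorometer
chamber): at 600 umol s-1 flow the mixing time constant is
`chamber_moles()/600` ~ 13.2 s, and the observed reference-to-sample
signal lag grows to roughly 48-92 s.

The remedy is empirical: measure the same ramp with the chamber
*empty* (an empty-chamber response curve, ECRC), fit a low-order
polynomial to the apparent assimilation artifact as a function of
reference CO2, and subtract it from leaf measurements taken the same
day with the same chamber settings. This package implements that
pipeline — raw-channel bookkeeping, steady-state selection,
polynomial correction with BIC model selection, FvCB fitting — plus a
physics-based simulator so the whole chain can be tested without an
instrument.

## Gas-exchange bookkeeping

All derived quantities are recomputed from the raw analyzer channels
(open-system equations with transpiration dilution):

* `A = flow (c_r - c_s (1000 - w_r)/(1000 - w_s)) / (100 S)`
* `E = flow (w_s - w_r) / (100 S (1000 - w_s))`
* `gtw = E (1000 - (W_leaf + w_s)/2) / (W_leaf - w_s)`, `gtc = gtw / 1.6`
* `Ci = ((gtc - E/2) c_s - A) / (gtc + E/2)`

with CO2 in umol mol-1, H2O in mmol mol-1, flow in umol s-1 and leaf
area `S` in cm2. `W_leaf` is the saturation mole fraction at leaf
temperature via a Buck-type formula,
`e_s(T) = 0.61365 exp(17.502 T / (240.97 + T))` kPa. Recomputing
everything in the package (rather than trusting instrument columns) is
what makes post-measurement leaf-area correction possible: conifer
shoots are not flat, their true needle area is usually measured after
the fact, and `rescale_leaf_area()` rebuilds A, E, conductances and Ci
from the unchanged raw channels. Boundary-layer and stomatal
conductance are lumped into a single total conductance; the 1.6
water:CO2 diffusivity ratio is configurable. Leaf area is treated as an
opaque positive scalar — whether it is projected or total needle area
is the user's convention.

Degenerate records are flagged, never silently dropped or NaN'd: zero
water flux or a non-physical gradient (`W_leaf <= w_s`, condensation)
yields `NA` conductances and a `gx_flag`; negative Ci — which arises in
practice under noisy humidity control — is kept but flagged suspect.

## Steady-state selection

The quasi-linear portion of a ramp is isolated with a delta-threshold
rule on consecutive-point changes in A (`select_quasi_linear()`):

1. the *lag block* is everything before the first run of
   `min_run_length` consecutive deltas within `+/- delta_threshold`;
2. later points are *outliers* when they deviate from the last kept
   point (default) or their raw predecessor (`compare = "raw"`) by more
   than the threshold.

Defaults are 0.05 umol m-2 s-1 and a run of 10 (20 s at 2 s logging,
comfortably shorter than the shortest observed lag). Two refinements
matter in practice:

* **Settling margin.** The run rule localises steady state only to
  threshold precision: a first-order transient still carries up to
  `delta_threshold / (1 - exp(-dt/tau))` ~ 0.35 umol m-2 s-1 when it
  first slips inside the band, an order of magnitude above analyzer
  noise, and it decays with the chamber time constant. BIC is sharp
  enough to buy an extra polynomial degree to chase that remnant, so
  the pipeline assigns a further `settle_points = 20` points (~3 time
  constants at 2 s logging) to the lag block. The margin comes from the
  chamber physics, not from data fitting.
* **Leaf curves need a larger threshold.** An empty chamber's
  steady-state signal is flat, but a leaf's A changes genuinely along
  the ramp: at 100 ppm min-1 and 2 s logging the A-Ci signal itself
  moves by up to ~0.1-0.15 umol m-2 s-1 per step on the steep Rubisco
  branch (Vcmax ~60, conductance ~0.12 mol m-2 s-1). A 0.05 threshold
  would reject the entire region that determines Vcmax. The pipeline
  therefore filters leaf ramps at `racir_delta = 0.25` — above the
  maximum expected signal change plus noise, below mixing-transient
  swings — while keeping 0.05 for ECRCs.

Only up-ramp data are used by default; `split_ramps()` discards the
down ramp at the global minimum of a smoothed reference-CO2 trace.

## Empty-chamber correction

`fit_ecrc()` regresses the filtered ECRC's apparent A (computed at the
nominal 36 cm2 aperture area) on reference CO2 for polynomial degrees
1-3 and `select_best_bic()` picks the best candidate by
`BIC = n log(RSS/n) + (d + 1) log(n)` (the Gaussian constant cancels in
comparisons; an exact fit, RSS < 1e-12 n, counts as `-Inf` and
parsimony breaks ties towards the lowest degree). `correct_racir()`
then subtracts the polynomial, evaluated at each leaf record's
reference CO2, after rescaling by `nominal_area / leaf_area` — the
mass-balance artifact in flux units is inversely proportional to the
area used. Records outside the polynomial's fitted domain are dropped,
never extrapolated; if under 20% of a curve falls inside the domain the
correction refuses and asks for a matching ECRC. Ci is recomputed from
the corrected flux rather than shifted, because Ci is nonlinear in A.

A useful side effect of the domain trim: the ECRC's own lag block sets
the lower edge of its fitted domain, and the leaf curve's lag records
sit below that same edge, so non-steady leaf data are excluded even
before the leaf-side filter acts.

## FvCB fitting

Net assimilation is the hard minimum of the Rubisco-limited and
RuBP-regeneration-limited branches minus day respiration:

* `Ac = Vcmax (Ci - G*) / (Ci + Km)`, `Km = Kc (1 + O2/Ko)`
* `Aj = J (Ci - G*) / (4 Ci + 8 G*)`, with `J` the smaller root of
  `theta J^2 - (alpha Q + Jmax) J + alpha Q Jmax = 0`
* `A = min(Ac, Aj) - Rd`

Kinetic constants default to the widely used 25 degC values
(`G* = 42.75`, `Kc = 404.9` umol mol-1, `Ko = 278.4` mmol mol-1,
`O2 = 210` mmol mol-1, `theta = 0.85`, `alpha = 0.24`), matching the
defaults of the common A-Ci fitting tools; all are arguments. No
temperature response is implemented — the intended use is data measured
at a controlled 25 degC, and the constants refer to that temperature.
TPU limitation and branch blending are deliberately omitted.

`fit_aci()` minimises the residual sum of squares over
`(Vcmax, Jmax)` — and `Rd` when no measured value is supplied — by
Levenberg-Marquardt from three starting points
(`Vcmax in {25, 50, 100}`, `Jmax = 1.9 Vcmax`, `Rd = 1`), keeping the
best optimum; the multi-start guards against branch-assignment local
minima of the hard-min model. RMSE is reported on A over the fitted Ci
range only. The transition Ci solves `Ac = Aj` numerically (the
`(Ci - G*)` factor is divided out first so the root finder cannot grab
the trivial crossing at `G*`). The CO2 compensation point has a closed
form on the Rubisco branch, `(G* Vcmax + Rd Km) / (Vcmax - Rd)`,
reducing to `G*` when `Rd = 0`.

Partial-range fitting (`ci_range = c(200, 800)`) reproduces the
practice of fitting only the 200-800 ppm Ci window; at a default-light
electron transport of ~110 umol m-2 s-1 the branch transition sits
near Ci ~ 480, so both branches stay identified inside the window.

## The simulator

`simulate_ramp()` integrates a one-compartment mixing model with a pure
transport delay,

`n dc_s/dt = f c_in(t - D) - f_out c_s - 100 A S`,

by explicit Euler at 0.1 s (reduced automatically if the time constant
demands it; `tau >= 13 s` at the default chamber makes this stable and
cheap), logging every 2 s. `f_out = f (1000 - w_r)/(1000 - w_s)`
balances dry air, so the instrument's dilution-corrected A formula is
exact at steady state. The reference analyzer reads the incoming ramp
directly; the sample signal trails it by the transport delay plus the
mixing constant. The default program mirrors the field protocol: a down
ramp 420 to 20 ppm at 200 ppm min-1, a 12 s hold, an up ramp 20 to
1520 ppm at 100 ppm min-1.

Choices worth stating:

* **Transport delay 50 s.** Volume and flow fix the mixing constant at
  13.2 s; the residual system delay is not separately reported for this
  chamber, so it is set to place the total reference-to-sample lag
  (cross-correlation peak, `measure_lag()`) at ~63 s, the centre of the
  48-92 s range observed with this chamber class. The lag metric itself
  is a choice; a settling-time definition gives similar values.
* **Leaf coupling.** The leaf responds instantaneously to chamber CO2
  through a fixed total conductance (default 0.12 mol m-2 s-1;
  stomata move slowly relative to a ramp). At each step the implicit
  pair `A = FvCB(Ci)`, `Ci = ((gtc - E/2) c_s - A)/(gtc + E/2)` is
  solved by Newton on a monotone scalar equation (a plain fixed-point
  iteration diverges at low Ci, where the Rubisco branch is steeper
  than the supply line). Sample-cell humidity is the steady solution of
  the transpiration balance at the 22 mmol mol-1 reference target,
  plus jitter.
* **Match offsets.** `offset_poly` injects an apparent-A offset
  polynomial in reference CO2 by shifting the logged sample channel —
  the physical location of a match offset — so the injected artifact is
  recoverable by the ECRC workflow.
* **Noise.** Gaussian, per channel, seeded; defaults 0.05 umol mol-1
  (CO2) and 0.05 mmol mol-1 (H2O). The CO2 value is chosen so the
  classic +/-0.05 delta filter behaves as it does on real data,
  retaining the bulk of steady-state ECRC points: the implied delta-A
  noise (~0.017 umol m-2 s-1 at 600 umol s-1 flow and 36 cm2) puts
  the band at ~3 sd.
* Same seed, bit-identical log (`withr::with_seed` around all draws).

What the simulator does *not* emulate: humidity control-loop dynamics
(the periodic H2O noise that plagues VPD-controlled measurements
appears only as optional extra jitter), temperature transients,
multi-compartment analyzer plumbing, and the matching procedure beyond
a static offset. Passing tests on simulated logs therefore demonstrate
the pipeline's correctness under first-order mixing physics, not
robustness to every instrument pathology.

## Known limitations

* The ECRC correction is *static*. With a leaf present the measured
  flux carries an extra dynamic term ~ `tau dA/dt` that no polynomial
  in reference CO2 can remove; at 100 ppm min-1 in the 193.7 cm3
  chamber this biases the steep Rubisco region low by ~0.5 umol m-2
  s-1, which shows up as a Vcmax underestimate of roughly 4% in the
  end-to-end recovery tests (Jmax, set by the flat branch, is nearly
  unaffected, and when Rd is estimated rather than fixed it absorbs
  part of the same bias). Slower ramps shrink the effect; time-domain
  deconvolution would remove it but is out of scope.
* One ECRC per day per chamber setting is assumed; there is no
  cross-day ECRC library, and the correction refuses ramps that do not
  overlap the ECRC domain.
* Kinetic constants are fixed at their 25 degC values; fitting data
  measured at other temperatures requires supplying adjusted constants.

## Problem sizes used in the test suite

Simulated logs are full-length protocol runs (517 records each,
~1030 s). The end-to-end recovery check uses 20 seeded
ECRC + leaf-curve pairs; the grid-search oracle compares the NLS
optimum against a 241 x 481 grid (0.1 umol m-2 s-1 resolution) on 5
noisy 30-point curves; polynomial round trips use 3 seeds per injected
degree. The whole suite runs in well under a minute on one CPU.
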