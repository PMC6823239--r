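# racirkit

Rapid CO2-response (RACiR) curves replace the classic stepped A–Ci
protocol with a continuous CO2 ramp, cutting the 30–60 minutes needed
per photosynthetic-capacity estimate to a few minutes — which is what
makes traits like V<sub>cmax</sub> and J<sub>max</sub> usable for
large-scale phenotyping. In the big cuvettes that conifer shoots
require (~194 cm³), however, the chamber mixing volume delays the
sample analyzer signal by 48–92 s relative to the reference analyzer,
so the instrument's steady-state equations produce a large apparent
assimilation artifact that must be removed before fitting.

`racirkit` is an R package for people who make such measurements. It

* recomputes A, E, conductances and C<sub>i</sub> from the raw infrared
  gas analyzer channels — so leaf area can be corrected *after* the
  measurement, as non-flat needles demand (`compute_gas_exchange()`,
  `rescale_leaf_area()`);
* isolates the quasi-linear, steady-state portion of a ramp with the
  delta-threshold rule (|ΔA| ≤ 0.05 µmol m⁻² s⁻¹ between consecutive
  points), separating the initial mixing lag from isolated outliers
  (`select_quasi_linear()`);
* fits 1st–3rd degree polynomials to an empty-chamber response curve
  (ECRC), selects by BIC, and subtracts the selected polynomial from
  leaf curves measured the same day (`fit_ecrc()`, `select_best_bic()`,
  `correct_racir()`);
* fits the Farquhar–von Caemmerer–Berry model

  A = min( V<sub>cmax</sub>(C<sub>i</sub> − Γ\*)/(C<sub>i</sub> + K<sub>m</sub>),
  J(C<sub>i</sub> − Γ\*)/(4C<sub>i</sub> + 8Γ\*) ) − R<sub>d</sub>

  by multi-start nonlinear least squares, full-range or restricted to
  C<sub>i</sub> ∈ [200, 800] ppm, with R<sub>d</sub> either fixed at a
  measured value or estimated (`fit_aci()`,
  `co2_compensation_point()`);
* simulates complete instrument logs — first-order chamber mixing,
  transport delay, FvCB leaf, match offsets, seeded noise — so the
  whole pipeline is testable without an instrument (`simulate_ramp()`,
  `simulate_ecrc()`).

Everything takes and returns plain tibbles; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate one measuring session (an empty-chamber curve and a leaf curve
with known truth V<sub>cmax</sub> = 60, J<sub>max</sub> = 120,
R<sub>d</sub> = 2) and run the full pipeline:

```r
library(racirkit)

chamber <- chamber_spec(offset_poly = c(0.5, 8e-4, -3e-7))  # match offset
ecrc  <- simulate_ecrc(chamber, seed = 1)
racir <- simulate_ramp(chamber, leaf = leaf_spec(), seed = 2)

result <- process_racir(racir, ecrc, rd_measured = 2, ci_range = c(200, 800))
result
#> Rapid A-Ci pipeline result
#> ECRC polynomial, degree 2 (n = 374, RSS = 0.09129, BIC = -3093.15)
#>   coefficients (c0..c2): 18.0413, 0.000800971, -3.00639e-07
#>   valid co2_ref domain: [236.6, 1520.0] umol mol-1
#> FvCB fit to A-Ci data
#>   Vcmax = 57.39, Jmax = 119.39, Rd = 2.00 (fixed) umol m-2 s-1
#>   RMSE = 0.299 on 385 points, Ci range [100, 967], transition Ci = 483
#> Partial-range fit:
#> FvCB fit to A-Ci data
#>   Vcmax = 57.77, Jmax = 119.27, Rd = 2.00 (fixed) umol m-2 s-1
#>   RMSE = 0.199 on 264 points, Ci range [201, 795], transition Ci = 475
#> Discarded records:  ecrc_lag=67, ecrc_outliers=12, down_ramp=64,
#>   racir_lag=56, racir_outliers=0, domain_trim=12, ci_window=0
```

Reading the output: the selected degree-2 ECRC polynomial carries an
~18 µmol m⁻² s⁻¹ intercept — the steady mixing artifact of a
100 ppm min⁻¹ ramp lagging ~63 s through the chamber — plus the
injected match-offset curvature. After subtracting it and recomputing
C<sub>i</sub>, the FvCB fit recovers J<sub>max</sub> within 0.5% and
V<sub>cmax</sub> within ~4% of truth; the remaining V<sub>cmax</sub>
deficit is the method's known dynamic bias (a static ECRC correction
cannot remove the τ·dA/dt term on the steep Rubisco branch — see the
vignette). The partial-range fit (C<sub>i</sub> 200–800) agrees with
the full-range fit to well under 1%, and every discarded record is
accounted for by stage.

`glance()` gives the same fit as one row:

```r
glance(result$fit)
#>   vcmax  jmax rd rd_fixed   rmse ci_transition ci_lo ci_hi n_points converged
#> 1 57.39 119.4  2     TRUE 0.2991         482.8 100.4   967      385      TRUE
```

Batch processing of many files, with per-entry error isolation and a
summary CSV, goes through `run_batch()`; a thin command-line front end
(`simulate`, `correct`, `fit`, `batch` subcommands) lives at
`inst/cli/racirkit.R`.

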