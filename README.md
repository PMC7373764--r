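# haldane

Batch-culture kinetics of microbial phenol biodegradation: rate
extraction, Haldane substrate-inhibition model fitting, and a seeded
simulator for validating the whole chain by parameter recovery.

Phenol feeds the culture and poisons it at the same time, so the specific
growth rate μ and specific degradation rate q both rise with substrate,
peak, and fall again. The package implements the standard analysis of such
data for microbiologists and environmental engineers characterising
degrader strains:

* **Calibration** — linear standard curves (4-aminoantipyrine phenol assay,
  OD600 → dry biomass) with exact forward/inverse round trips, blank
  clamping and extrapolation warnings.
* **Rate extraction** — μ as the least-squares slope of ln X vs t, q as the
  slope of −ln(S/S₀) vs t, with optional automatic exponential-phase
  windowing and a substrate detection floor.
* **Haldane fit** — nonlinear least squares of

  μ(S) = μ\*·S / (Ks + S + S²/Ki)

  over (S₀, rate) points, multistart Levenberg–Marquardt in log-parameter
  space, plus the closed-form derived quantities: the critical substrate
  concentration Sm = √(Ks·Ki) and the true maximum rate
  μmax = μ\*/(1 + 2√(Ks/Ki)), which is always below the fitting parameter
  μ\*. Setting `ki = Inf` gives the Monod (uninhibited) limit.
* **Simulator** — seeded batch time-courses from dX/dt = μ(S)·X,
  dS/dt = −q(S)·S with lag at high substrate and multiplicative log-normal
  noise, so every downstream stage is testable without any dataset.
* **Pipeline** — `run_pipeline()` chains the stages and writes traceable,
  byte-reproducible CSV/JSON reports; a thin CLI wrapper lives in
  `inst/scripts/run_kinetics.R`.

## Worked example

Published Haldane growth parameters for a phenol degrader
(μ\* = 0.574 h⁻¹, Ks = 20.29 mg/L, Ki = 268.1 mg/L):

```r
library(haldane)

p <- haldane_params(0.574, 20.29, 268.1)
critical_substrate(p)      # 73.75465
true_max_rate(p)           # 0.3702742
overestimation_percent(p)  # 55.02026
```

Growth is fastest at ~74 mg/L phenol; above that, inhibition wins. The
observable maximum rate is 0.37 h⁻¹ — the fitting parameter μ\* = 0.574
overstates it by 55%, which is why reporting μ\* as "μmax" for inhibitory
substrates is misleading.

Round trip through the simulator: generate noisy rate points at the
default substrate grid (41–1117 mg/L, triplicate) and fit them back:

```r
scn <- simulation_scenario(
  growth_params = p,
  degradation_params = haldane_params(1.244, 9.152, 517.5,
                                      branch = "degradation"),
  seed = 7)
fit <- fit_haldane(generate_rate_points(scn, noise_sd = 0.05))
fit
#> Haldane growth fit (24 points, 10 starts):
#>   mu* = 0.5548 1/h, Ks = 16.92 mg/L, Ki = 292.8 mg/L
#>   Sm = 70.39 mg/L, mu_max = 0.3747 1/h, R2 = 0.9766
```

With 5% measurement noise the maximum-rate parameter comes back within a
few percent; Ki is the weakly identified direction (see the methods
vignette, `vignettes/phenol-kinetics.Rmd`).

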