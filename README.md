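# riceNNI

In-season rice nitrogen diagnosis and precision topdressing from canopy
reflectance.

Fertilizing rice well means knowing, mid-season, whether the crop has
enough nitrogen and how much more it will need to reach its yield
potential. This package implements a complete diagnosis-to-recommendation
chain for agronomists and remote-sensing researchers working on
multi-rate nitrogen trials:

* **Critical N dilution curve** — the minimum shoot N concentration for
  unrestricted growth declines with biomass as `Nc = a · DM^−b` (Nc in %,
  DM in t/ha). The curve is built by the Justes procedure: per-date
  ANOVA/LSD grouping of treatments into N-limited and non-limited sets,
  an oblique regression through the limited plots, a vertical line at the
  non-limited biomass, and an allometric fit through the per-date
  intersection points.
* **Nitrogen nutrition index** — `NNI = Na / Nc`; 1 is optimal, below 1
  deficient, above 1 surplus.
* **Spectral estimation of NNI** — nine vegetation indices from 5-band
  (blue/green/red/red-edge/NIR) reflectance, screened by gray relational
  analysis (Deng coefficients, resolution ρ = 0.5, per-stage degree
  threshold 0.7), then inverted to NNI with a random-forest model
  (100 trees, depth 2, leaf size 2; 70/30 stage-stratified split).
* **Yield response and nitrogen balance** — a linear-plateau model
  `RY = a·NNI − b` below the breakpoint and `RY = c` above it, feeding
  the balance `Nr = (APGN · Ymax · RY / 100 − Ns) / NUE − Nuse` with
  NUE = 0.426, split into basal and stage-wise topdressing doses
  (default 2:1).
* **Synthetic trial generator** — a 2-cultivar-style, five-rate
  (0–200 kg N/ha), four-stage trial simulator with a known dilution
  curve, yield plateau and NNI-linked reflectance, so the whole pipeline
  is testable end-to-end without field data.

## Worked example

Fit a dilution curve from critical points, diagnose a plot, and turn a
saturated nitrogen status into a topdressing plan:

```r
library(riceNNI)

dm <- c(1, 2, 4, 8)
curve <- fit_dilution_curve(dm, 2.24 * dm^(-0.35))
curve
#> Critical N dilution curve (shoot dry matter)
#>   Nc = 2.24 * DM^-0.35   (Nc in %, DM in t/ha)
#>   validity: 1.00 - 8.00 t/ha;  R2 = 1.000;  n = 4 points

compute_nni(1.5, critical_concentration(4, curve))
#>    na       nc      nni  status
#> 1 1.5 1.378882 1.087838 surplus
```

A plot measuring 1.5% N at 4 t/ha sits 9% above its critical
concentration (1.379%): nitrogen surplus. For a treatment whose NNI has
reached the yield plateau (historical maximum 10,573.3 kg/ha, 1.97 kg N
per 100 kg grain, control uptake 128.90 kg/ha, basal dose 80 kg/ha):

```r
yj <- list(slope = 1.088, intercept = 0.08, breakpoint = 1.01,
           plateau = 1.01)
recommend_topdressing(1.2, yj, y_max = 10573.3, apgn = 1.97,
                      ns = 128.90, basal = 80)
#> Topdressing plan (kg N/ha)
#>  basal     JT     HD  total
#>  80.00  74.17  37.09 191.26
```

191.26 kg N/ha in total: 80 basal, then 74.17 at jointing and 37.09 at
heading (the 2:1 split). The full pipeline — simulate (or read) a trial,
build the curve, compute NNI, screen indices, invert NNI from
reflectance, fit the plateau, and recommend per treatment — runs from a
single seed:

```r
res <- run_nni_pipeline(seed = 7)
res$curve
#> Critical N dilution curve (shoot dry matter)
#>   Nc = 2.42 * DM^-0.4101   (Nc in %, DM in t/ha)
#>   validity: 1.04 - 8.10 t/ha;  R2 = 0.991;  n = 4 points
res$eval_test$rmse
#> [1] 0.0457
```

Under the generator's default noise (5% dry matter, 3% N, 2%
reflectance) the recovered curve sits close to the generating truth
(a = 2.24, b = 0.35) and the spectral inversion predicts held-out NNI
with an RMSE of about 0.05. See `vignette("nitrogen-topdressing")` for
the model details, parameter choices and limitations.

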