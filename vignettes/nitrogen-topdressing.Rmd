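---
title: "In-season rice nitrogen diagnosis and precision topdressing"
author: "riceNNI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-season rice nitrogen diagnosis and precision topdressing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riceNNI)
```

## The problem

Rice takes up nitrogen over the season, and the concentration it *needs*
falls as the crop grows: a large canopy dilutes its nitrogen over more
structural biomass. The **critical nitrogen dilution curve** formalises
this as a power law,

$$N_c = a \cdot DM^{-b},$$

with $N_c$ the minimum shoot N concentration (%) that still permits
maximum growth at shoot dry matter $DM$ (t/ha), $a$ the critical
concentration at 1 t/ha, and $b$ the dilution exponent. The **nitrogen
nutrition index**

$$NNI = N_a / N_c$$

compares the measured concentration $N_a$ to that requirement: $NNI < 1$
means deficiency, $NNI > 1$ surplus. Because NNI can be estimated from
canopy reflectance, it supports *non-destructive, in-season* fertilizer
decisions. This package implements the full chain: curve construction,
NNI, multispectral index screening, random-forest NNI inversion, the
NNI–relative-yield response, and a nitrogen-balance topdressing
calculator — together with a synthetic trial generator so that every
stage is testable without field data.

## Curve construction (Justes procedure)

For each sampling date of a multi-rate N trial:

1. treatments are compared by one-way ANOVA on shoot dry matter,
   followed by least-significant-difference comparisons between
   *adjacent* N rates at the 5% level (`classify_n_status()`);
2. a treatment is **N-limited** when moving to the next-higher rate
   still increases DM significantly; the top treatments whose DM no
   longer responds (while N% does) form the **non-limited** group;
3. the N-limited plots are fitted by a simple linear regression of N%
   on DM (the *oblique* line); the non-limited plots estimate the date's
   maximum DM as their mean (the *vertical* line);
4. the intersection ordinate is the date's **critical point**
   (`critical_point()`); and
5. the per-date critical points are fitted by `fit_dilution_curve()` in
   log–log space — exact on power-law data, with an optional nonlinear
   refinement (`refine = TRUE`) for noisy points.

Two procedural details are under-determined by common usage and were
fixed as follows. The oblique regression uses N *concentration* on DM
(the intersection ordinate is a concentration), and the vertical line is
the *mean* DM of the non-limited group. Dates with no usable grouping
(no significant DM step anywhere, or fewer than two limited treatments)
are skipped with a warning; at least three usable dates are required.

With replicated noise-free data the within-group variance is exactly
zero and the F statistic degenerates; the grouping then treats any
relative mean difference above $10^{-8}$ as significant.

## The synthetic trial generator

`trial_config()` + `simulate_trial()` emulate a one-cultivar,
five-rate (0/60/120/160/200 kg N/ha) trial with `plots_per_rate = 3`
replicates sampled at four stages (tillering, jointing, heading,
filling). Its moving parts:

* **N-rate → NNI link.** Logistic,
  $NNI(r) = M/(1 + e^{-(r - r_0)/s})$ with defaults $M = 1.07$,
  $r_0 = -78$, $s = 82.5$, calibrated once so that the unfertilised
  control sits near $NNI \approx 0.77$ (relative yield $\approx 0.76$,
  typical of paddy controls with substantial soil N supply) and the two
  highest rates sit on the yield plateau. `nni_values` can override the
  logistic with explicit per-rate targets.
* **Dry matter.** A stage ladder (1, 3, 6, 8 t/ha potential shoot DM)
  times the N response. The response is $RY(NNI)^{p}$ with
  `dm_power` $p = 2$ by default: vegetative biomass responds more
  steeply to N shortage than grain yield, and an exponent above 1 is
  needed for the grouping ANOVA to have realistic power at 3 replicates
  and 5% DM noise.
* **N concentration.** Non-limited plots sit exactly at
  $NNI \cdot a\,DM^{-b}$. N-limited plots are placed on the per-stage
  *oblique line through the true critical point*, anchored at the
  control's logistic NNI; their NNI truth is then derived from that
  line. This makes the generator's geometry exactly self-consistent
  with the Justes construction, so the full noise-free pipeline
  recovers $(a, b)$ to machine precision — a strong end-to-end
  correctness check. Intermediate limited rates consequently deviate
  slightly from the logistic; the generator reports the actual
  `nni_true` per plot.
* **Yield.** $Y_{max} \cdot RY(NNI)$ using the NNI reached at the
  yield-driving stage (`yield_stage`, default jointing).
* **Noise.** Multiplicative lognormal for DM, N% and yield (positivity);
  additive Gaussian truncated to $[0,1]$ for reflectance. Defaults: 5%
  DM, 3% N, 2% reflectance, 5% yield.
* **Reflectance.** `simulate_reflectance()` maps NNI to the five bands
  by a linear monotone surrogate (NIR rises, red falls), *not* a
  radiative-transfer model. Passing tests on these data shows the
  pipeline machinery is correct, not that any particular field accuracy
  is attainable: real canopies add stage-dependent structure, soil and
  water background, and index saturation that the surrogate does not
  emulate.

## Vegetation indices and screening

`compute_all_indices()` evaluates NDVI, NNVI, RVI, NRI, RVI−1, SR,
NDRE, PSNDc and SAVI from the five bands. The source table prints NDRE
with the same formula as NDVI — almost certainly a red-edge typo — so
both dialects are available; `as_printed` is the default for fidelity,
`red_edge` computes $(\rho_{NIR}-\rho_{RE})/(\rho_{NIR}+\rho_{RE})$.
Zero denominators yield `NA` markers rather than errors, and
`mask_soil()` removes records below an NDVI threshold (default 0.3, a
common canopy/soil cut; the published workflow masks soil without
stating its threshold).

Index screening uses Deng's **gray relational analysis** (`gra()`):
series are non-dimensionalised (mean-normalisation by default;
initial-value normalisation available, and the choice matters because
$\Delta_{min}/\Delta_{max}$ depend on it), coefficients follow

$$\gamma_{0i}(k) = \frac{\Delta_{min} + \rho\,\Delta_{max}}
                        {\Delta_{0i}(k) + \rho\,\Delta_{max}},
  \qquad \rho = 0.5,$$

with the extrema taken globally over all comparison series (the
standard Deng formulation; the alternative per-series scope is not
offered), and the relational degree is the coefficient mean.
`rank_and_select()` keeps indices whose degree exceeds 0.7 at *every*
stage, ranked by mean degree with ties broken by canonical table order.

## NNI inversion

`fit_nni_rf()` wraps a random-forest regression with the published
settings: 100 trees, maximum depth 2, minimum samples per split and per
leaf of 2. Depth is enforced through the terminal-node cap
(`maxnodes` $= 2^{depth}$) and the leaf minimum through `nodesize`;
a minimum split size of 2 constrains nothing and is kept only as
documentation. Depth 2 is unusually shallow; it is implemented as
printed, with `max_depth = NULL` as the documented unrestricted
override. Note one consequence: a depth-2 forest has an approximation
bias floor (about 0.006 NNI on the synthetic link), so convergence
experiments that shrink only the reflectance noise use the unrestricted
override to isolate the noise effect.

The 70/30 `split_dataset()` is stratified by growth stage (the source
does not say whether its split was pooled; stratification keeps every
stage represented in both sets) and `evaluate_inversion()` reports
RMSE, $R^2 = 1 - SSE/SST$, an *accuracy* defined as one minus the mean
relative error (the term is used but never defined in the source; this
labelled definition is the package's choice), and the through-origin
slope $k$ of predicted on measured.

## Yield response and the nitrogen balance

`fit_linear_plateau()` fits

$$RY = a \cdot NNI - b \;\; (NNI < NNI_{max}), \qquad
  RY = c \;\; (NNI \ge NNI_{max})$$

by grid search over candidate breakpoints at the observed NNI values:
below-points by OLS, plateau as the mean of the at-or-above points,
total SSE minimised, ties to the smallest breakpoint, candidates
without a rising (positive-slope) segment excluded. The plateau is
*unconstrained* by default because the published parameter sets are
slightly discontinuous at the breakpoint
($1.088 \times 1.01 - 0.08 = 1.0189 \ne 1.01$); `continuous = TRUE`
ties $c = a \cdot NNI_{max} - b$. Breakpoint resolution equals the gap
between adjacent observed NNI values — exact recovery therefore needs a
design whose grid contains the true breakpoint, which the package's
reference checks use.

The balance chain (`recommend_topdressing()`) is

$$GY = Y_{max} \cdot RY, \qquad GNA = \frac{APGN \cdot GY}{100}, \qquad
  N_r = \frac{GNA - N_s}{NUE} - N_{use},$$

with $Y_{max}$ the historical maximum yield (kg/ha), $APGN$ the N
uptake per 100 kg grain, $N_s$ the control's N uptake (kg/ha), and
$NUE = 0.426$. Negative requirements are clamped to zero (surplus
soils; the source is silent). The requirement above the basal dose is
split across topdressing stages in fixed ratios (default 2:1, i.e. the
40%/20% jointing/heading shares of a plan whose basal dose is 40%).
Published recommendation tables use two conventions for the saturated
case — relative yield equal to the plateau $c$, or exactly 1 — so the
`saturated_ry` policy (`"plateau_c"` default, `"unity"`) supports both.
For the indica cultivar the published table's topdressing columns are
labelled jointing/heading while its scheme assigns tillering/jointing;
stage labels here are free-form `split_ratios` names, so either
labelling can be produced.

## The pipeline

`run_nni_pipeline()` chains the stages for one cultivar and derives all
randomness from one master seed (generator = seed, reflectance = seed+1,
split = seed+2, forest = seed+3), so a fixed seed reproduces every
output file byte-for-byte. Stage failures abort with the stage's name.
With `out_dir` set it writes the plot table, index table, relational
degrees, recommendations, and a JSON manifest (package version, seed,
fitted parameters).

```{r pipeline, eval = FALSE}
res <- run_nni_pipeline(seed = 7)
res$curve          # fitted dilution curve
coef(res$plateau)  # NNI-relative yield platform
res$recommendations$N4
```

Default problem sizes — 60 plot-stage records per trial, 200-replicate
simulation studies for bias checks — were chosen so the whole test
suite and the reference script run in well under a minute while keeping
Monte-Carlo error far below the tolerances being checked.

## Known limitations

* The reflectance link is an empirical monotone surrogate; inversion
  accuracies obtained on synthetic data say nothing about field $R^2$.
* The generator's control N uptake is tied to the dilution curve, so it
  is lower than the uptake typically measured at maturity in the field
  (maturity N includes grain N that sits above the vegetative dilution
  envelope); synthetic recommendation totals are accordingly higher
  than published field totals, while the balance arithmetic itself
  reproduces the published rows exactly when fed the published inputs.
* No radiometric calibration, orthomosaic handling, or per-pixel raster
  I/O: inputs are plot-level tables.
* Curve comparison statistics between cultivars, hierarchical curve
  fits, and economic-optimum N rates are out of scope.
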