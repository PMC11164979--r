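---
title: "Ecological and economic multifunctionality: models, assumptions, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecological and economic multifunctionality: models, assumptions, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecomult)
```

# The setting

`ecomult` analyses two-factor split-plot agro-experiments of the kind run at
large climate-manipulation field facilities: climate (ambient vs. a future
scenario) is applied to whole *mainplots*, and five land-use types — extensive
meadow (EM), extensive pasture (EP), intensive meadow (IM), organic farming
(OF) and conventional farming (CF) — are randomized as subplots within each
mainplot. EM, EP and OF are *sustainable* (no mineral nitrogen fertiliser, no
pesticides), IM and CF *intensive*; EM, EP and IM are grassland, OF and CF
cropland. With 10 mainplots this gives 50 plots and 5 replicates per
climate × land-use cell.

Fourteen ecosystem variables, measured per plot and year, approximate six
ecosystem services: yield (food production), the soil organic carbon flux
(climate regulation), nitrogen surplus (water quality, a dis-service),
microbial biomass, three enzyme activities and three decomposition rates
(soil health), three soil-faunal Shannon diversities (biodiversity
conservation) and flower abundance (landscape aesthetics).

# Ecological multifunctionality

Each function is averaged over its measurement years and min–max normalized
across all plots pooled over treatments, so the worst plot scores 0 and the
best 1; nitrogen surplus is normalized with direction reversed. Ecological
multifunctionality is the weighted average

$$ egEMF = \sum_i \alpha_i\, EF_i, \qquad \sum_i \alpha_i = 1 ,$$

where the weights come from one of three scheme kinds: equal weighting of
the 14 functions; equal weighting of the 6 services, distributed within each
service by the function's share (the three biodiversity functions get 1/18
each; soil health is hierarchical — microbial biomass 1/18, each enzyme and
each decomposition measure 1/54); or stakeholder service preferences
distributed the same way. The hierarchical soil-health distribution mirrors
the soil-health composite itself; a flat 1/7-per-function alternative is
available via `service_map(soil_health = "flat")`.

Stakeholder preferences are survey-derived service percentages. The
published transfer procedure (averaging crop and livestock provisioning,
splitting the supporting-class and regulating-class weights 50/50 onto the
two supporting and two regulating services, then renormalizing) is
implemented verbatim in `transfer_preferences()`. Applied to the published
farmer source vector (44/29/16/11) it yields 44/14.5/14.5/16/5.5/5.5 — *not*
the published final vector 38/18/18/14/7/7, which also sums to 102%. We do
not guess the missing rescaling step: the default farmer scheme uses the
published final vector renormalized to 1, the procedure is available and its
output is auditable through the `intermediate` attribute, and an alternative
"farmers put only 5% on regulating and supporting services" reading ships as
the `farmers_low_regulating` fixture. The vectors for the other three
stakeholder groups are **synthetic illustrative defaults** (marked as such in
`stakeholder_preferences()`), since only the farmer vector is published.

Degenerate normalization ranges raise errors instead of returning a
mid-scale constant: a fabricated 0.5 would silently distort every weighted
average downstream.

# Economic multifunctionality

Monetary service values (€/ha/yr) are summed per plot:

$$ enEMF = \sum_i p_i\, ES_i $$

* **Food production**: harvested mass (dt/ha) times producer prices, times a
  crop-price multiplier in sensitivity runs. The default prices
  (grain 18, organic grain 25, straw 5, grassland biomass 9 €/dt) are
  documented placeholders; the organic price was set so that organic
  monetary yields end up a few percent above conventional ones despite lower
  mass yields, matching the qualitative pattern the index is meant to
  exhibit. Override them for any real valuation.
* **Climate regulation**: mean net soil carbon flux (t C/ha/yr, from
  `carbon_stock_and_flux()`: TOC% × 4050 t soil/ha at 30 cm depth and
  1350 kg/m³) × 3.66 (CO2/C mass ratio) × the CO2 accounting price
  (default 195 €/t; scenarios 280 and 90 €/t).
* **Water quality**: −(nitrogen surplus) × the nitrogen accounting price
  (default 7.30 €/kg for surface-water leaching; scenario 1.9 €/kg for
  groundwater). A nitrogen *deficit* earns no credit. The surplus itself is
  bookkeeping: soil mineral N at time x + fertiliser input − harvest
  removal, combined with the soil mineral N one year later. The printed
  formulation *adds* the later stock, which is physically surprising; both
  the literal (default) and the mass-balance (subtracting) variant are
  implemented and flagged in the result, and they differ by exactly
  2·nmin(x+1).
* **Natural insurance of biodiversity and soil health**: a risk-averse
  farmer values yield stability. For lognormal yields with mean
  $\bar Y$ and coefficient of variation $CV$, and constant relative risk
  aversion $r$ (default 0.28), the certainty equivalent is
  $\bar Y (1+CV^2)^{-r/2}$, so the risk premium is
  $RP = \bar Y\left(1 - (1+CV^2)^{-r/2}\right)$. The package verifies this
  closed form against numeric integration of the CRRA expected utility.
  Plot-level premia are regressed on soil multidiversity $b$ and soil
  health $h$ (both on their normalized scales, which is what the composites
  deliver) with the quadratic surface
  $RP(b,h) = x_1 + x_2 b + x_3 b^2 + x_4 h + x_5 h^2 + x_6 bh$, and the
  insurance values are surface differences:
  $I_B = RP(0,h) - RP(b,h)$, $I_H = RP(b,0) - RP(b,h)$,
  $I_{HB} = RP(0,0) - RP(b,h)$, which satisfy
  $I_{HB} = I_B(b,0) + I_H(b,h) = I_H(0,h) + I_B(b,h)$ exactly. Both
  $I_B + I_H$ (used in the total) and $I_{HB}$ (reported alongside) are
  returned, since they differ for a non-additive surface. Evaluating the
  surface at level 0 extrapolates whenever the data do not reach 0; the
  package warns outside the fitted range.

`enEMF` sums food production, climate regulation, water quality and the two
insurance values; the farmer's value is food production plus the two
insurance values. Landscape aesthetics is not monetized. Risk premia are
computed on *monetary* yields so all components share the €/ha/yr unit.

# Inference

Because the design is balanced and complete, the split-plot ANOVA is
computed from stratified sums of squares: climate against the
mainplot-within-climate mean square with df (1, m−2); land-use and the
interaction against the subplot residual with df (4, 4(m−2)) — i.e. (4, 32)
at 10 mainplots. In the balanced case these F tests are exactly the
REML-plus-Satterthwaite tests of the corresponding mixed model, which the
test suite confirms against `aov()` error strata; unbalanced data are
rejected loudly rather than approximated. Tukey post-hoc comparisons use the
subplot residual and its df, on land-use means, or on cell means when the
interaction is significant at 0.05 (the "drop the interaction if
non-significant" flow). Monte-Carlo calibration (2000 null replicates with a
mainplot random effect) keeps each test's type-I error inside the binomial
95% band around 0.05.

The biodiversity–multifunctionality regression uses an 11-function
equal-weight index (the three biodiversity functions removed, so predictor
and response share no components) against soil multidiversity, pooled, per
climate, and with a multidiversity × climate interaction.

# The synthetic world

The generator is first-class, tested code; it emulates the *statistical
structure* the analysis assumes, not agronomy:

* every non-yield function is `baseline × climate_effect^(future) ×
  management_effect^(intensive) × plot quality × truncated-Gaussian noise`;
  effects are multiplicative because responses are naturally fractional;
* annual yields are lognormal, mean-parameterized by the same product, with
  a plot-level CV that decreases linearly in soil multidiversity `b` and
  soil health `h` (default `CV = 0.32 − 0.15 b − 0.10 h`, i.e. 0.32 on
  lifeless soil down to 0.07 on the best soils — agronomically plausible
  yield volatilities);
* `b` and `h` are computed from the simulated soil variables exactly the way
  the downstream analysis computes them, so the planted CV structure is
  recoverable end to end;
* two persistent, correlated (ρ = 0.5) lognormal plot-quality factors
  (sd 0.25 on the log scale) scale the biodiversity and soil-health
  functions. This represents spatial soil heterogeneity and is what makes
  the quadratic risk-premium surface identifiable: without it the synthetic
  plots collapse onto four treatment-group points with `b` and `h` nearly
  collinear, and the surface's behaviour at level 0 is pure noise. Real
  field data have exactly this within-treatment spread.

Default effect sizes (yield 0.8 under future climate and 1.3 under intensive
management; diversity suppressed to 0.6–0.7 under intensive management;
nitrogen surplus ×8 under intensive management; flower abundance 0.6 under
future climate and 0.15 under intensive management) are *illustrative*: no
per-function effect sizes are published in reusable form. They are chosen
once, directionally faithful to the reported responses, and the tests treat
them as the planted truth rather than as tuning knobs.

What a green test establishes: the estimators recover what was planted, at
the configured replication. What it does not establish: anything about real
fields — the generator has no weather, no phenology, no spatial
autocorrelation beyond the plot-quality factor, and its independence
assumptions (years i.i.d. given the plot) are optimistic.

Two replication choices deserve emphasis. The classical 10 × 5 design is the
default everywhere. The end-to-end insurance-recovery check, however, runs
at 20 mainplots × 20 years: a 5-year sample CV has a sampling error of
roughly CV/√8 ≈ 0.07, larger than the planted CV differences, so at the
field design's own replication the fitted surface's sign is seed-dependent —
an honest smallness-of-data statement, not an implementation defect. The
acceptance suite documents the replication at which recovery is reliable.

# Numerical choices and degenerate inputs

* Min–max normalization refuses constant vectors (no silent 0.5).
* Shannon's index drops zero-count taxa; an all-zero community errors.
* The lognormal yield draw is mean-parameterized
  (`mu = log(mean) − sigma²/2`, `sigma² = log(1+CV²)`), so Monte-Carlo means
  are unbiased for the planted means.
* The CV uses the sample (n−1) standard deviation by default; population
  variant behind a switch.
* The surface fit requires ≥ 6 observations and a full-rank design; rank
  deficiency (e.g. constant `b`) is a hard error.
* The classifier uses strict inequalities and first-match precedence in the
  published rule order; boundary values match nothing. The violet rule is
  implemented exactly as published although it is unsatisfiable (r < 100 and
  b > 150 force |r − b| ≥ 52 > 50) — the test suite proves this exhaustively
  over the admissible sub-grid. Masked (blacked-out) pixels can never match
  but stay in the denominator. The ~1.37% white-pixel background-noise
  subtraction is available but off by default, since min–max normalization
  absorbs constant offsets.
* ANOVA with 2 mainplots has zero-df error strata; F values are reported as
  `NA` with a `degenerate` flag rather than fabricated.

# Known limitations

* Stakeholder vectors other than the farmers' are synthetic placeholders.
* Producer prices are placeholders; absolute € results are only meaningful
  relative to each other under the shipped configuration.
* The insurance valuation inherits the extrapolation-to-zero problem of the
  published method; with narrow (b, h) spread the values are unstable, and
  the package only warns.
* No general unbalanced mixed-model engine; the ANOVA is exact for the
  balanced design and refuses anything else.
* Yield moisture correction (residual grain moisture) is not applied, as the
  published workflow leaves it unstated.
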