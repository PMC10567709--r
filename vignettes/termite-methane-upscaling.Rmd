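---
title: "Methods: gridded upscaling of termite methane emissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gridded upscaling of termite methane emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termiteCH4)
```

## The estimation model

Termite CH₄ emission at a grid cell is the product of termite biomass
density and an emission factor (EF), annualised over 24 × 365 hours:

$$F = \big[(1-f)\,\rho_{\mathrm{nat}}\,E_{\mathrm{nat}} +
      f\,\rho_{\mathrm{crop}}\,E_{\mathrm{crop}}\big]
      \times 8760 \times 10^{-6}
      \quad [\mathrm{g\,CH_4\,m^{-2}\,yr^{-1}}],$$

where $f$ is the cropland areal fraction, $\rho$ densities in g dry weight
m⁻² and $E$ emission factors in µg CH₄ g⁻¹ termite h⁻¹. The flux is zero
outside the climate envelope. Global and regional totals are
area-weighted sums over a spherical Earth (R = 6371 km), reported in
Tg CH₄ yr⁻¹. The model's key assumptions:

* **Temperature-only habitat.** Potential habitat is the set of cells whose
  climatological minimum monthly mean temperature exceeds −8 °C. The
  inequality is strict: a cell at exactly −8.0 °C is excluded (covered by a
  boundary test). Rainfall is not a constraint; arid-class cells are instead
  limited by their low densities.
* **Land-cover–determined density.** Each of the 15 natural vegetation
  classes carries a fixed density (0–11 g m⁻²; see
  `landcover_table()`); in the two tropical forest classes density responds
  to productivity as $\rho = a\,e^{b\,\mathrm{GPP}}$ with defaults
  $a = 1.21$ g m⁻², $b = 8\times10^{-4}$ (g C m⁻² yr⁻¹)⁻¹. The relationship
  is applied *uncapped*: at GPP = 3000 it gives ≈ 13.3 g m⁻², close to the
  table's tropical-evergreen 11, and no saturation is assumed. The output
  unit (g m⁻²) is asserted by dimensional consistency with the density
  table rather than by an independent derivation. Whether savanna or
  shrubland should also respond to GPP is genuinely open; the responsive
  set is a config field (`density_config(gpp_responsive_classes = ...)`)
  defaulting to the two tropical forest classes only, because the land-use-
  only variant is described by exactly those two fixed values (8 and 11).
* **Cropland bookkeeping.** Cropland is counted *out* of habitat area
  (actual = potential × (1 − f)) yet still emits with its own density
  (3.815 g m⁻²) and EF (3.45), constant in all variants. Habitat-area
  accounting and emission accounting are therefore deliberately different
  sums, and both are reported.
* **EF uncertainty by resampling.** The observed EF sample is heavily
  right-skewed (cv > 1), so the global total is reported as the mean ± s.d.
  of a Monte-Carlo ensemble (default 1000 members) in which each member
  draws one EF per land-cover class, uniformly with replacement from the
  sample.

## Draw granularity: one EF per class per member

The sampling granularity determines the ensemble spread and is the one
structural choice the uncertainty estimate hinges on. Drawing an
independent EF for *every cell* would average the EF distribution over
~10³–10⁵ habitat cells and collapse the global-total spread toward zero;
drawing one EF *per class per member* keeps the effective number of draws
per member small (≲ 16), so the ensemble's relative spread stays comparable
to the EF sample's own relative spread — consistent with a reported
uncertainty of roughly half the mean for a sample with cv ≈ 1.08. The
choice is isolated behind the `scheme` argument of `run_ensemble()`
(empirical sampling vs prescribed per-class values), so sensitivity runs
need no code change. Within a member, the natural classes and cropland are
drawn independently.

Because the total is *linear* in the per-class EFs, each member's total is
a dot product of its EF draw with per-class area-weighted density sums
computed once per year. The test suite cross-checks this fast path against
the full per-cell engine and against a naive scalar loop (agreement to
10⁻⁹ relative on the 36 × 72 grid).

## Estimator variants

`run_scenario()` supports four variants crossing the two method choices:

| variant | density | emission factors |
|---|---|---|
| `control` | GPP-responsive tropical forests | sampled per class per member |
| `sanderson_ef` | GPP-responsive | prescribed per-class table values |
| `landuse_density` | table values only | sampled |
| `sanderson_ef_and_landuse_density` | table values only | prescribed |

With prescribed EFs and deterministic density the member spread is exactly
zero — a structural property the tests assert — which distinguishes
EF-sampling uncertainty from interannual variability. `decadal_stats()`
reports the latter (the s.d. of annual ensemble means within a window);
the two statistics answer different questions and are labelled separately
throughout.

## The habitat climatology window

The envelope is meant to capture whether colonies survive a *typical*
winter, so it is evaluated on a trailing 20-year mean of the monthly
temperatures, not on single-year weather (`climatology_window`, default
20 years; truncated to the available years at the start of a series). A
single-year evaluation would make the habitat boundary flicker with
interannual noise; twenty years is the conventional climatological
averaging period for this kind of envelope.

## What the synthetic world emulates — and what it does not

The generators (`gen_monthly_temperature()`, `gen_landcover()`,
`gen_cropland_fraction()`, `gen_gpp()`, `gen_soil_sink()`,
`gen_ef_sample()`) reproduce the *statistical structure the method
consumes*:

* zonal-mean temperature 27 cos φ − 3 °C with a seasonal cycle of amplitude
  25 sin²φ and opposite hemispheric phase, a configurable warming trend
  (°C decade⁻¹) and seeded noise (s.d. 0.5 °C, truncated at ±4 s.d. so the
  generator's range guarantees hold deterministically). At baseline the
  habitat boundary sits near |φ| ≈ 60°, leaving both habitat and
  non-habitat bands on every grid;
* a static zonal biome mosaic containing all 15 natural classes, with
  longitude splits so every temperate/boreal class is present;
* a cropland belt centred at |φ| = 30° (Gaussian width 12°), baseline
  amplitude 0.25, growing by `cropland_trend` per decade — cropland
  expansion erodes subtropical habitat as in historical land-use
  reconstructions;
* GPP as a land-cover baseline (2500 g C m⁻² yr⁻¹ in tropical evergreen
  forest, tapering to 0 in polar desert) times a warming modifier and a
  CO₂-fertilization multiplier (default +2.2 % decade⁻¹ compounding, ≈ +30 %
  over twelve decades), with multiplicative noise that is independent of
  the fertilization path so paired runs differ by an exact ratio;
* a soil CH₄ oxidation sink with a smooth upland-latitude shape, scalable
  to any prescribed global total (default 31.6 Tg yr⁻¹) for net-flux
  bookkeeping;
* an EF sample from a zero-inflated lognormal truncated at 25.26, with 5 %
  exact zeros and (µ, σ) moment-matched so the mixture attains mean 3.81
  and s.d. 4.10. The lognormal family is the simplest positive-skew choice
  consistent with s.d. > mean and a hard upper range; the published source
  distribution is summarised only by its moments and range, so only those
  are reproduced, not an exact histogram shape.

The synthetic world is **all land**: there is no ocean mask, because the
pipeline treats missing cells generically (`NA` in any `grid_field`) and a
land/ocean geography would add nothing to what the tests can falsify.
Consequently synthetic absolute totals are roughly the all-land/real-land
area ratio above realistic values, and passing tests demonstrate the
*machinery* — unit chain, masking, weighting, linearity, convergence,
reproducibility, variant contrasts — not agreement with observed global
totals. Reproducing published gridded estimates requires the real driver
datasets (observational climate, harmonised land use, process-model GPP
and an observed EF compilation), which are consumed through `read_field()`
/ `read_ef_csv()` but not shipped. Likewise there is no spatial
autocorrelation beyond zonal structure, no interannual climate modes, and
cropland never exceeds the belt shape.

## Numerical choices

* **Moment matching** uses Nelder–Mead on (µ, log σ) against relative
  moment residuals, accepted only below 10⁻⁶ on both targets; infeasible
  targets (e.g. an s.d. the truncation bound cannot support) are an error,
  not a silent approximation.
* **Truncated sampling** is by inverse CDF on the restricted quantile
  range, so draws respect the upper bound exactly rather than by
  rejection.
* **Seeds.** Every stochastic stream (each year × month temperature field,
  each year's GPP noise, the EF sample, each year's ensemble) derives its
  seed deterministically from the base seed and context tags via a 31-bit
  mix, so adding years to a run never perturbs existing ones, and all
  generators save/restore the caller's RNG state.
* **Degenerate inputs** are defined, not accidental: a single-value EF
  dataset gives a zero-spread ensemble; a single-value summary reports
  s.d. 0 with a warning; `zero_fraction = 1` yields the all-zero sample; a
  missing month makes a cell's minimum temperature missing; missing GPP in
  a responsive cell falls back to the table density with a warning.
* **Constants.** 365-day years (8760 h); spherical Earth, no ellipsoid
  (sub-0.3 % effect, far below the method's uncertainty); GWP values
  (79.7 at 20 years, 27.0 at 100) are arguments with those defaults, not
  hard-coded.

## Problem sizes

The default test and example grid is 5° (36 × 72) — coarse enough that a
full 1000-member ensemble, including habitat climatology and density
mapping, runs in well under a minute, while exercising every band of the
biome mosaic. Moving to the 0.5° grid (360 × 720) is a `grid_spec()`
argument, not a code change; all geometry tests run on both. Convergence
tests use EF samples of 10⁵ (moment recovery within 3 standard errors) and
ensembles of 10³ (analytic-expectation recovery on a single-class world).

## Known limitations

* No termite migration lag: habitat gained by warming is assumed occupied
  immediately.
* Soil-feeding and wood-feeding termites are not separated, and EFs are not
  stratified by region or taxon — the calibrated sample is a single pooled
  distribution.
* Mound-internal CH₄ oxidation (which can consume a large share of gross
  production before it reaches the atmosphere) is not modelled; EFs are
  used as provided.
* The soil sink is an input field, not a process model; `net_flux_field()`
  is bookkeeping only.
* The per-class-per-member EF draw granularity is an inference from the
  magnitude of reported uncertainties in this literature, not an observed
  protocol; the `scheme`/granularity boundary exists precisely so it can be
  revisited.
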