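---
title: "DEM-based inundation scoring and the phosphorus field-trial analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DEM-based inundation scoring and the phosphorus field-trial analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inundr)
```

## The problem

Rainfed lowland rice on the Central Plateau of Burkina Faso depends on
runoff flooding, and the efficacy of phosphorus fertilization — in
particular whether cheap, low-solubility phosphate rock (PR) can replace
imported triple superphosphate (TSP) — varies with the water regime and
the soil type of each field. Hydrometric data are absent in the region,
so flooding tendency must be inferred from terrain alone. `inundr`
implements an *inundation score* computed purely from a projected DEM,
packages the site, trial and soil-profile tables of a seven-field survey
around the Saria station, and provides the statistical layer that relates
the score to soil texture, observed submergence and grain yield.

## The score

For a DEM on a projected, meter-unit grid the pipeline runs:

1. **5×5 focal mean** on the raw elevations (integer-valued source DEMs
   become smooth floats).
2. **Depression filling**, so every cell drains to the grid edge.
3. **D8 flow directions**: each cell drains to the neighbor with the
   largest positive drop per unit distance (diagonals weighted by
   $\sqrt 2$); ties resolve to the first maximum in the fixed scan order
   N, NE, E, SE, S, SW, W, NW, which makes the routing fully
   deterministic.
4. **Flow accumulation**: the number of upstream cells draining through
   each cell.
5. **$\log_{10}(x+1)$ transform** of the counts (zero accumulation maps
   to zero; the heavy tail is compressed).
6. **25×25 focal mean, twice**, suppressing microtopography.
7. **Min–max normalization** to a *water accumulation score* $W \in
   [0,1]$.
8. **Convexity**: the negated second directional derivative of elevation
   along the gradient (*longitudinal*, $C_L$) and perpendicular to it
   (*cross-sectional*), from the 3×3 Zevenbergen–Thorne quadratic on the
   smoothed DEM. Negative convexity = concave, water-stagnating terrain.
9. **Composite**:
   $$ S = \begin{cases} 0 & C_L \ge 0 \\ 100 \, W \, |C_L| & C_L < 0.
   \end{cases} $$

The clip rule encodes the hydrological assumption that convex
(shedding) terrain cannot stagnate water no matter how much drains
through it.

### Design choices the sources left open

* **Cross-sectional convexity.** The narrative description multiplies
  the water accumulation score "by convexities", but the published
  component table is only consistent with $W \times |C_L| \times 100$:
  one site has clearly negative cross-sectional convexity yet a zero
  score, which only the longitudinal clip explains, and all seven scores
  reproduce exactly (half-up, 2 decimals) under the longitudinal-only
  rule. The default is therefore `longitudinal_only`;
  `product_of_both` is available in `score_pipeline_config()`.
* **Normalization.** How the accumulation surface was normalized to
  [0, 1] is unstated; `inundr` uses min–max over the analysis extent.
  The caveat is inherited: a site's $W$ depends on the extent scored, so
  scores from different extents are not comparable.
* **Log base and offset.** "Logarithmic transformation" is
  unparameterized in the source; $\log_{10}(x+1)$ is used so that zero
  accumulation maps to zero and decades map to integers. Base $e$ is a
  config option (it cancels in the min–max normalization anyway).
* **Curvature source.** Whether convexity was computed on the raw,
  5×5-smoothed, or 25×25-smoothed DEM is ambiguous in the source; the
  default (`smoothed25`) applies one 25×25 pass to the 5×5-smoothed DEM
  before the stencil, matching the stated motivation ("remove
  microtopography before estimating convexity"). `smoothed5` and `raw`
  are available.
* **Edges and nodata.** Focal windows shrink to their valid
  intersection with the grid; nodata cells are omitted from every mean
  and propagate to the output. Convexity is nodata on the one-cell
  border. Consequently the outer ~14 cells of a scored grid are
  edge-affected; analyses on synthetic grids read the interior.
* **Pits and flats.** Filling uses the iterative
  Planchon–Darboux relaxation (fixed point = classical filled surface;
  `epsilon = 0` leaves level flats). Flats are then routed
  breadth-first from the cells that already drain, i.e. toward the spill
  point. Interior pits encountered on *unfilled* terrain act as
  terminal sinks by default (the usual GIS convention, and the behavior
  a closed basin physically has); `on_pit = "error"` makes them fatal
  instead.
* **Curvature magnitudes are stencil-specific.** The survey's own
  convexities came from a proprietary raster engine whose operator is
  not publicly specified; magnitudes from `convexity()` on real tiles
  will not match the published per-site components. The score
  *composition* stage is therefore validated against the published
  component values themselves, and the curvature code against analytic
  quadratics (exact to 1e-10).

## Packaged data

Three tables ship as CSVs and load with `load_site_terrain()` (7 sites:
soil group, $W$, $C_L$, cross-sectional convexity, score),
`load_field_trials()` (three-year site means ± SD of submergence days,
cumulative water depth in cm, and grain yield in Mg/ha under CT, NK,
NK+PR, NK+TSP), and `load_soil_horizons()` (38 horizons; texture,
C/N, pH, EC, Bray-P, exchangeable cations, CEC, BS, EBS). Values are
stored exactly as printed (the convexity exponent strings are kept
verbatim in `*_printed` columns); comparisons against them are made at
printed precision with half-up rounding (`round_half_up()`), never
pretending more accuracy than the tables carry. 34 horizons have
complete chemistry; correlation analyses use exactly that subset.

Two published numbers deserve a note:

* The group-summary yield rows were averaged over unpublished
  plot/year-level replicates, so they are not the means of the printed
  site means and are shipped as-is (`load_field_trials_groups()`).
* The correlation matrix accompanying the horizon table is reproduced by
  the *product-moment* (Pearson) correlation of the raw values (sand–clay
  −0.93, sand–silt −0.48, silt–clay 0.12, sand–CEC −0.82, …), although
  the accompanying text names Spearman; rank correlation on the same 34
  horizons gives sand–clay −0.87. `texture_correlations()` computes
  both; the reproduction tests pin the method that matches the numbers.

## Statistical layer

`ols_fit()` reports slope, intercept, $R^2$, the adjusted
$R^2 = 1-(1-R^2)(n-1)/(n-2)$, and the two-sided slope p-value;
`spearman_rho()` is the Pearson correlation of average ranks;
`welch_t()` is the unequal-variance t-test; `anova_tukey()` fits one-way
ANOVA with Tukey HSD (Tukey–Kramer under imbalance) and produces a
compact letter display from the maximal cliques of the
not-significantly-different graph, so two groups share a letter exactly
when their Tukey p ≥ α; `pca_standardized()` z-scores columns and
decomposes the correlation structure. α = 0.05 throughout.

Reproduced at desk scale from the packaged tables (see
`analysis/03_trial_regressions.R`):

* CT and NK yields regress on the score with slopes ≈ 1.73 and 1.71
  Mg/ha per score unit and intercepts ≈ 0.56 and 1.26 Mg/ha. Because
  the packaged scores are printed to 2 decimals, the recomputed
  coefficients carry that input rounding (CT comes out 1.7356 / 0.5517);
  agreement is asserted to one unit in the last published digit.
* Excluding Nandiala — whose submergence is dominated by groundwater
  and a road embankment, an exclusion recorded explicitly in the report
  rather than applied as automatic outlier removal — the score explains
  76% and 84% (adjusted $R^2$) of submergence duration and cumulative
  water depth over the remaining six sites.
* Base saturation indices recompute from the cations:
  EBS = bases/(bases+Al) reproduces within ±0.1 on the well-conditioned
  horizons and always within the interval implied by rounding each
  printed cation to 0.01 cmol~c~/kg; BS = bases/CEC is ill-conditioned
  at small printed CEC (one surface horizon moves by ~2 units within
  CEC's printed rounding), so only EBS is held to the tight tolerance.

The site-level PCA in `run_full_analysis()` uses the 7 sites × 8
variables (terrain, water regime, 0–20 cm depth-weighted topsoil
texture). The published PCA additionally used per-site-year cumulative
precipitation, which was never published, so its loading table is not
reproducible; the PCA implementation is instead validated by its
invariants (orthonormal loadings, proportions summing to one,
eigenvalues matching an independent eigendecomposition).

## Synthetic generators

`simulate_dem()` builds a tilted lowland: southward slope 0.005 at the
outlet, a concave longitudinal profile (slope increasing upstream at
2×10⁻⁵ m⁻¹ — without longitudinal concavity a uniform straight valley
has $C_L = 0$ on its axis and correctly scores zero), a 200 m wide, 2 m
deep parabolic channel, and 0.3 m white elevation noise on a 90×91 grid
of 5 m cells. The noise is structural, not cosmetic: dendritic hillslope
drainage only emerges on noisy terrain, and without it every column of a
planar hillslope accumulates as much flow as the valley axis. The
channel is deliberately wider than the 25-cell smoothing window, since
the pipeline by construction erases narrower (microtopographic)
channels. Axis cross-curvature is analytic
($-8\,\text{depth}/(\text{width}^2 L^2)$) and pinned in tests.

`simulate_trial()` draws per-site, per-treatment, per-year yields from
$y = a_t + b_t\,S + \varepsilon$, $\varepsilon \sim N(0, \sigma_t^2)$,
with defaults taken from the fitted packaged relationships
($b_{CT} = 1.73$, $b_{NK} = 1.71$, flat P-fertilized treatments at their
overall means) and noise SDs of 0.4–1.7 Mg/ha, typical of the
interannual SDs in the trial table. The generators emulate the *linear
mean structure plus independent Gaussian noise* only — not spatial
autocorrelation of real DEM error, year×site weather interactions, or
treatment-correlated errors — so passing recovery tests demonstrate
correctness of the estimation chain, not realism of those features.

## Problem sizes and determinism

All table-based analyses are exact arithmetic on 7–38 rows and run in
milliseconds. Synthetic end-to-end runs use the 90×91 default grid
(scores in ~0.5 s) and the parameter-recovery experiment uses 100
replicates of 40 sites × 1 year, sizes chosen so the whole suite stays
interactive while leaving the stochastic checks well-powered. Every
random draw flows through an explicit seed in the config objects, and
the generators restore the caller's RNG state, so identical inputs give
bit-identical outputs everywhere.

## Known limitations

* Scores depend on the normalization extent (min–max over the grid).
* Curvature magnitudes are stencil- and smoothing-dependent; compare
  scores only within one pipeline configuration.
* The raster I/O speaks ESRI ASCII grid only; reproject and convert
  real-world tiles before use (the pipeline assumes meter units).
* Seven sites is a small n: the published water-condition regressions
  rest on six points after the exclusion, and the package reproduces —
  it cannot strengthen — that evidence.
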