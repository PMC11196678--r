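---
title: "Forecasting macrophyte distributions: models, assumptions and design choices"
author: "macrocast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting macrophyte distributions: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis in one paragraph

`macrocast` forecasts where canopy-forming brown macroalgae and seagrasses
can live as the ocean warms. From point occurrence records it builds each
species' present-day *extent of occurrence* (EOO) with an iterative
alpha-hull procedure; it then fits random-forest habitat-suitability
models on monthly environmental predictors with equal-size pseudo-absence
sampling and iterative variable elimination, and projects a yearly
probability-of-occurrence map per species and scenario out to 2100.
Clipping each year's suitability by the fixed EOO gives the species'
*area of occupancy* (AOO) under a no-dispersal assumption; stacking the
clipped maps gives species richness; thresholding group-level maps gives
habitat extent. All downstream numbers — diversity trajectories, the
fraction of localities losing diversity, habitat percent change by
threshold and region, AOO trajectories with and without proportional
expansion — derive from these maps. Because the real inputs (hundreds of
thousands of records; CMIP6-class layer archives) are far beyond desk
scale, the package ships a virtual-species world whose ground truth is
known exactly, so every stage is testable end to end.

# The spatial data model

Grids are regular latitude/longitude rasters with half-open cells
`[lat, lat+res) x [lon, lon+res)`; a point on a southern or western edge
belongs to that cell, which makes point-in-cell assignment unambiguous.
Longitudes live in `[-180, 180]` and antimeridian-crossing grids are
rejected rather than silently wrapped. Cell areas use the spherical band
formula on the authalic radius 6371.0 km — every km² in the package
depends on that constant — and close exactly to the sphere's surface.
Regridding offers nearest-neighbour, bilinear (default for continuous
fields) and area-weighted block means; the block mean is computed as an
anchored weighted mean so constant fields survive bit-exactly and the
area-weighted global mean of a fully valid field is conserved.

Benthic macrophytes need light at the seabed: cells with yearly bottom
irradiance under 50 E m⁻² yr⁻¹ are excluded everywhere. The boundary is
inclusive (exactly 50 is habitable); in continuous fields the choice only
affects measure-zero boundary cells.

Raster layers travel in a plain-text CSV format (a `#` metadata header
plus a `row,col,value` table of valid cells) written and read by
`write_layer_csv()`/`read_layer_csv()`, which round-trips exactly and
keeps every artifact of a run human-readable and diffable.

# The extent-of-occurrence procedure

An alpha-shape generalizes the convex hull: triangulate the points
(Delaunay), then discard triangles whose circumradius exceeds `1/alpha`.
At `alpha -> 0+` the hull is convex; as alpha grows the hull tightens,
loses area, and may break into disjoint components (all components are
retained — disjunct ranges are real). The triangulation is a from-scratch
Bowyer–Watson construction; coordinates are treated as planar, which the
0.05-degree-scale rasterization downstream absorbs.

The selection loop starts at `alpha = 0.001` (essentially convex) and
raises alpha in steps of 0.005. Each step computes the ratio between the
relative area reduction (against the previous hull) and the relative loss
of contained records (against the species' total records); while area
shrinks cheaply the hull is too loose, and the first step where the ratio
drops below 10 is accepted — that alpha and its hull are returned. Steps
that lose area but no records leave the ratio undefined and are skipped,
which also avoids a division by zero. Records on a hull boundary count as
contained. If a step would empty the hull entirely the previous hull is
returned with a warning, since a retained species must keep a non-empty
extent. Species with fewer than three unique, non-collinear points cannot
support a hull; their extent is the fine cells containing their points,
buffered by one fine cell.

Rasterization covers a fine grid at one tenth of the analysis resolution
(0.05 under 0.5 degrees; 0.2 under the desk-scale 2 degrees): a fine cell
is covered when its center lies in a kept triangle, the fine cells of
hull vertices are marked explicitly (so sliver triangles cannot lose the
record that generated them), and an analysis cell is covered when any
nested fine cell is. The result is clipped by the light mask.

# The niche models

Presence cells are cells holding at least one record (species level) or
at least one member species (group level). Pseudo-absences are sampled
uniformly without replacement from light-valid cells without records,
matching the presence count. At desk scale a species group can occupy
more than half of the small coastal domain; the pipeline then saturates
the pseudo-absence sample at the available cells and proceeds with mildly
unbalanced classes rather than failing — the module-level sampler itself
still errors when asked for more cells than exist.

Features are monthly climatologies: for each dynamic variable (sea
surface temperature, air temperature, salinity, primary productivity,
sea-ice cover) the 2015–2020 mean of each calendar month, plus static
depth and shortwave radiation — 62 features. Climatological months keep
the feature count identical between calibration and projection, which
projection onto single years requires.

Forests are `ranger` probability forests (impurity importance, fixed
seed, single-threaded for exact reproducibility); out-of-bag accuracy is
the fraction of OOB class votes (p at least 0.5) matching the labels. The
species-level selection loop drops the ten least-important features
(ties broken by feature name, for determinism), refits, and finally keeps
the most accurate model across all steps, preferring fewer features on
ties. Group models keep all predictors. Projection builds the target
year's monthly features and predicts per cell; cells with missing inputs
are masked.

One model is fitted per species per scenario, because calibration uses
each scenario's own 2015–2020 layers.

# Derived quantities

* **AOO extent**: sum over EOO cells of `p * cell_area` — the
  probability-weighted occupied area, fixed to the present-day extent
  (no dispersal).
* **Suitable area `s`**: the same probability weighting over all
  light-valid cells. This operational definition keeps `R2015 = AOO/s` a
  clean occupied fraction; a thresholded alternative (`p >= 0.6`) is one
  argument away. **Proportional expansion** projects `R2015 * s_year`.
* **Richness**: per-cell sum of the clipped occurrence probabilities;
  exactly zero outside the union of extents.
* **Change maps**: `100 * ln(end/start)`, computed as a log difference so
  antisymmetry under argument swap is exact; cells below
  `epsilon = 1e-6` species on either side are masked (the zero-handling
  the change ratio needs but the definition leaves open).
* **Trajectories**: yearly means with cross-cell (diversity) or
  cross-species (AOO) standard errors, aggregated into 5-year bins
  labelled by bin start; the 95% CI is the normal approximation
  `mean ± 1.96 SE`. Cells are not spatially decorrelated — the CI
  describes the cell ensemble, not independent localities. Latitudinal
  and global means are unweighted across cells; percentage AOO
  trajectories are computed per species and then averaged.
* **Habitat extent**: area of light-valid cells with `p >= threshold`
  for thresholds 0.6–0.9 (inclusive boundary), globally and within
  twelve marine regions; at desk scale the regions are three latitude
  bands crossed with four longitude quadrants standing in for the world
  marine ecoregions, supplied as a label raster plus legend.

# The virtual world

The synthetic generator is the package's ground truth, not a fixture:
its defaults define the study conditions every recovery test runs under.

* **Geography** is fixed: continents from Gaussian blobs (including
  polar land so high-latitude coasts exist), depth rising smoothly away
  from the coasts, and bottom irradiance `L0(lat) * exp(-depth/25)`, so a
  contiguous coastal band passes the 50 E m⁻² yr⁻¹ mask (about 1,800 of
  11,600 ocean cells at 2 degrees).
* **Climate**: latitude-graded baselines with hemisphere-phased seasonal
  cycles; scenario trends are linear (0.18, 0.30, 0.45 °C per decade for
  the three SSP-like pathways — bracketing moderate-to-high emissions
  sea-surface warming), uniform in space so the global mean drifts
  exactly linearly; sea ice retreats poleward and thins with its own
  rate; shortwave and depth are static, mirroring the constant-radiation
  assumption of the projection setup. Observation noise is i.i.d.
  Gaussian per variable-year-month, seeded reproducibly; ground truth is
  always evaluated noise-free, separating process from observation error.
* **Species** have Gaussian product niches on sst, salinity and bottom
  light. Sea-surface optima are drawn between the 5% and 70% quantiles of
  present coastal sst — so warming erodes the warm edge of most ranges —
  with breadths of 2.5–5 °C; salinity and light responses are broad, so
  temperature is the dominant axis. Occupancy is deterministic
  (suitability at least 0.3), noise-free by design. About one species in
  five is a seagrass.
* **Sampling**: per-species record counts are negative binomial (mean
  150 scaled by detectability 0.9, dispersion 2), so a realistic minority
  of species falls under the 10-record filter; effort is clustered
  around hotspots with strength 0.5, interpolating uniform-to-clustered.

What the world does *not* emulate: ocean circulation, dispersal,
species interactions, interannual climate variability beyond white noise,
and the spatial autocorrelation structure of real survey effort. Passing
recovery tests therefore show that the pipeline recovers signals of the
planted kind — monotone thermal trends filtered through static
geography — not that it would be unbiased on real survey data.

# Reduced scale, seeds and runtime choices

The default configuration runs the whole study shape — three scenarios,
yearly projections 2015–2100 — on a 2-degree grid with 10 virtual species
and 300-tree forests, sized so a full end-to-end run takes a few minutes
on one core; the recovery analyses use 12 species under the warmest
pathway. The full-resolution setting (0.5 degrees, hundreds of species,
500-tree forests) is configuration, not code. `fit_with_elimination()`
itself defaults to 500 trees.

A single master seed fans out to per-stage child seeds (environment,
species, sampling, pseudo-absences, forests), so stages can be re-run
independently and a rerun with the same configuration reproduces every
output bit for bit — the reproducibility test compares the persisted
CSVs of two runs byte-wise.

# Recovery targets and their definitions

The estimator assumes no dispersal, so its ground-truth counterpart must
too: the true richness trajectory intersects each species' occupancy in
year Y with its 2015 occupancy. The diversity-change comparison then
isolates model error (probability-weighted richness versus boolean
counts) rather than mixing in dispersal effects the estimator excludes
by construction. The recovery tests assert agreement within 10 percentage
points for the end-of-century mean local diversity change and for the
fraction of localities losing at least 10% of their species, the planted
(negative) sign of the group-mean AOO change, and the poleward shift of
suitable habitat (the polar regions' share of `p >= 0.6` habitat grows by
2100). Shares, not absolute areas, carry that last check: even if polar
habitat only persists while lower latitudes decline, the share rises.

# Numerical choices and degenerate inputs

* Importance ties in elimination break by feature name; pseudo-absence
  draws, forests and noise fields all derive from child seeds.
* In-circle tests in the triangulation use a small relative tolerance;
  exact duplicate points are collapsed before triangulating (occurrence
  counts still refer to records).
* `log_pct_change` uses `log(end) - log(start)`; the block-mean regrid
  anchors its weighted mean — both so the exact identities asserted in
  tests hold to the last bit.
* Records on land or sub-threshold cells are dropped and counted, never
  snapped. Empty extents after clipping warn and contribute nothing
  downstream. A zero baseline area makes percent change undefined (`NA`,
  with a warning), and a zero baseline suitable area is an error for
  proportional expansion.

# Known limitations

The hull treats longitude/latitude as planar and does not wrap the
antimeridian, so ranges spanning it are handled as disjoint components.
The trajectory CIs ignore spatial autocorrelation. The no-dispersal and
proportional-expansion hypotheses bracket, but do not model, real
colonization. The desk-scale world's coastal domain is small enough that
group-level presence can approach half of it, where pseudo-absence
saturation (documented above) begins to blur the group models' absence
signal.
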