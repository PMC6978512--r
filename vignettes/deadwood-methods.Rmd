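---
title: "Methods: standing-dead biomass estimation and feedstock screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standing-dead biomass estimation and feedstock screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deadwood)
```

## The estimation problem

Aerial detection surveys record forest die-off as polygons, each with an
estimated count of newly dead trees, but carry no information about tree
size or biomass. Pre-disturbance forest-structure rasters carry live tree
density (TPH, trees/ha), live aboveground biomass (BPH, bone-dry tons/ha)
and live stem volume (VPH, m³/ha) on a 30-m grid, but no mortality.
`deadwood` converts counts to biomass by assuming that, within a survey
polygon, every live tree was equally likely to die: a polygon's count is
divided across its forested pixels proportionally to live tree density,
capped at each pixel's live tree count (0.09 ha per pixel), multiplied by
the pixel's mean live tree biomass (BPH/TPH), summed over survey years, and
finally capped at the pixel's live biomass.

Two assumptions deserve emphasis. First, *size-independent mortality within
a polygon*: the method cannot detect size-biased die-off (such as beetles
preferring large trees); the synthetic generator's `size_biased` mode exists
precisely to quantify the estimator's error when this assumption is broken.
Second, the *detection threshold*: aircraft reliably count only larger dead
trees. Running the allocation twice — once against structure layers
restricted to trees ≥ 25 cm DBH, once against all trees ≥ 2.5 cm — brackets
the truth. The upper bound attributes each death to a large (heavy) tree;
the lower bound dilutes the same counts over many small trees. Because
bark-beetle mortality concentrates in large trees, the upper bound is the
better point estimate, and both bounds are carried through every downstream
table.

## Choices where the method is under-determined

Several operational details are not fixed by the estimation equations. The
package resolves them as follows, and treats each as a stable convention
rather than a tunable:

* **Pixel membership** is by pixel-centre containment, with the boundary
  counting as inside. This is the standard rasterisation rule, is
  deterministic, and makes polygon partitions of the extent cover every
  pixel exactly once.
* **Cap surplus is not redistributed.** When a pixel's share of a polygon's
  count exceeds its live tree count, the excess is dropped (and logged in
  the per-polygon diagnostics), not reassigned to other pixels. Any
  redistribution rule would be an invention; the shortfall is visible in
  `diagnostics$requested - diagnostics$allocated`.
* **Overlapping polygons** (within or across years) are each allocated
  independently against the pristine pre-disturbance structure. No
  depletion is modelled; double-counting is reconciled only by the
  cumulative live-biomass cap. A consequence is that a *summed* yearly
  layer can locally exceed the per-pixel live-tree cap even though every
  per-polygon allocation respects it; the cumulative biomass never exceeds
  live biomass.
* **Yearly layers stay uncorrected.** The cumulative cap cannot be
  attributed to individual years, so per-year totals (and the yearly totals
  figure) are reported uncapped; only the cumulative grid is capped.
* **Fractional trees** are allowed throughout; proportional division of
  survey counts is inherently fractional and rounding would break
  conservation.

## Feasibility screening

Isolated pockets of mortality are uneconomical to harvest. Pixels with
positive cumulative dead biomass are clustered with DBSCAN on their centre
coordinates, with `min_pts = 112` pixels (≈ 10 ha); noise pixels are
zeroed. Conventions: a point's ε-neighbourhood includes itself (with this
convention, on a fully occupied 30-m lattice a 180-m disc holds exactly 113
centres while a 179-m disc holds 109 — so 112-pixel clusters are impossible
below ε = 180 m, which pins the lower end of the sweep); border points
attach to the first cluster that reaches them in index order, making runs
deterministic; core/noise status is order-invariant.

ε is chosen from a trade-off curve: for each candidate radius (default
sweep 180–400 m in 20-m steps), the biomass the filter would remove and the
mean per-cluster standard distance, `sqrt(var_x + var_y)` about the
centroid, are recorded. Both axes are min–max normalised and the discrete
(Menger) curvature is evaluated at each interior point; the ε of maximum
curvature is returned, ties going to the smaller radius because tighter
radii give more compact clusters. A curve with no curvature falls back to
the smallest interior ε with a warning. The sweep granularity and the
curvature formula are package conventions — only "the inflection of the
trade-off curve" is inherent to the method.

The remaining filters are deterministic masks: wilderness/National-Park
polygons (centre containment); mean tree volume `vpt = VPH/TPH ≥ 11.32 m³`
(inclusive — trees at the facility chipping limit are removed); cumulative
dead-tree density `< 2.5/ha` (strict — a pixel at exactly 2.5/ha is
retained). Filter order is fixed (isolation → wilderness → size/density)
because the removed-biomass attribution in the reduction ledger depends on
it.

**One footprint, two bounds.** Clustering and all masks are computed from
the upper-bound grid and applied identically to both variants. The
alternative — filtering each bound on its own grid — would produce two
different spatial footprints and make the paired totals incomparable. The
feasibility analysis describes one set of places with two biomass readings.

## Cost classification

Retained pixels are labelled on four axes: chipping class (`vpt ≤ 2.26 m³`
can be chipped on-site; the boundary value is assigned to the on-site class),
slope class from Horn's 3×3 gradient on the DEM (< 30% ground-based, 30–40%
transitional — closed below, open above — and ≥ 40% cable/helicopter; edge
pixels use clamped neighbourhoods), road proximity (straight-line distance
to the nearest road centreline, ≤ 2000 m inclusive; an empty road network
classifies everything as far), and hazard-zone tier / county by centre
containment (tiers may overlap; a pixel in no county is dropped from county
tables). `cost_effective` requires vpt ≤ 2.26, slope strictly < 40, and
road ≤ 2000 m. Road-buffer membership is implemented both as capsule-union
geometry and as distance thresholding; the two are exactly equivalent and
the test suite asserts it pixel-for-pixel.

Percent-of-gross columns in county tables are computed from unrounded totals
and rounded to two decimals only at serialisation, so rounding never
propagates.

## Energy and carbon accounting

Conversions are linear: 1 BDT/MWh for conventional boilers and 4.7 BDT/MWh
for small-scale gasifiers, an 80% default capacity factor, and
`MW × 8760 × CF` annual generation reported unrounded (a 25-MW plant gives
0.1752 TWh/yr, reported as ≈ 0.2). Supply-years round half away from zero.
`years_of_supply()` takes the annual generation explicitly, so published
round figures (for example 0.4 TWh/yr for a 50-MW programme plant, where
the exact product is 0.3504) can be used as inputs when reproducing
published arithmetic. Carbon mass uses 907.18474 kg/BDT (2,000 lb) and a
0.47 carbon fraction; 0.47 is not a measured constant of this package but
the conventional dry-wood carbon share, and it is configurable.

## Validation

For each survey polygon, the reference biomass loss (an independent raster)
is summed over member pixels, with net-gain (negative) pixels contributing
nothing, and compared with the pipeline's cumulative estimate over the same
years. Excluded: polygons under 2700 m² (three pixels — too small to align
reliably against a 30-m raster), polygons failing minimum feasibility
(polygon-mean vpt ≥ 11.3 m³, dead density ≤ 2.5/ha, or spatially isolated —
no member pixel in any cluster), and polygons where either side is zero.
Error is `sqrt(mean((ln est − ln ref)²))` over included polygons. The
**natural logarithm** is used; log-RMSE values are base-dependent, so
comparisons with numbers computed in another base require rescaling.

## What the synthetic generator emulates — and what it does not

`simulate_landscape()` builds every input from one master seed (component
substreams derive from it, so parts can be regenerated independently):

* **Structure fields** are white noise smoothed with a Gaussian kernel on
  the torus (scale = `tph_spatial_scale` pixels, default 8 ≈ 240 m). Each
  pixel carries large- and small-tree densities with per-tree volume and
  biomass tied to one latent size field, interpolated log-uniformly — tree
  size is right-skewed in real stands — over 0.3–13 m³ and 0.2–6 BDT. This
  construction guarantees the variant ordering (fewer, larger trees in the
  ≥ 25 cm subset) pixelwise by algebra, not by luck.
* **Mortality patches** are star-shaped radial-noise polygons (vertex
  radius `R(1 + 0.4·s(θ))` with smooth periodic `s`), which are always
  simple and valid. Buffered random walks would be an alternative blob
  model but require polygon-union machinery; the radial form exercises the
  same geometry paths.
* **Ground truth**: in `proportional` mode a patch kills a constant
  fraction of each pixel's detectable trees, so the allocation recovers the
  truth exactly — to rounding error — and the test suite asserts ≤ 1e-10
  relative error. Fractions above 1 make the surveyed count exceed the
  patch's capacity (over-reported counts), forcing the per-pixel caps to
  bind while the truth saturates at the cap. `size_biased` mode weights
  deaths by mean tree biomass so the density-proportional estimator is
  deliberately misspecified.
* **Reference loss** applies one lognormal factor per mortality patch —
  block-correlated noise, as a remote-sensing change product is biased at
  patch scale — plus optional injected net-gain pixels. Per-pixel i.i.d.
  noise would largely average out within polygons and the polygon-level
  RMSE would systematically under-read the injected σ; with patch-level
  noise the Monte-Carlo recovery study (500 patches on a 12 × 12 km extent,
  patch radii 40–100 m so patch overlap is negligible, σ = 0.5) recovers σ
  within the 15% band asserted in the tests.
* **Terrain** is flat, an inclined plane (analytic slope everywhere — the
  slope operator's exactness is tested on it), or smooth relief with a
  60-m amplitude giving mostly sub-40% slopes; **roads** are wavy
  crossings; **zones** are a wilderness disc, partially overlapping hazard
  tiers, and a 2 × 2 county partition.

The generator does **not** emulate allometry or species composition, beetle
epidemiology, wood decay (deliberately out of scope: dead wood density is
assumed constant over the short post-mortality window), survey-boundary
digitisation error, or co-registration error between rasters. Passing tests
therefore demonstrate the correctness of the estimator and screening
machinery under the stated assumptions — not the field accuracy of any
particular survey programme.

## Problem sizes and runtime conventions

Defaults are a 120 × 120-pixel (3.6 × 3.6 km) landscape with 8 mortality
patches in each of six years; the property suite uses 36–60-pixel grids for
its 50-bundle sweeps and a 400 × 400 grid for the 500-patch noise-recovery
study. These sizes give every stage thousands of active pixels — clusters
well above the 112-pixel minimum, non-trivial filter cascades — while a full
`run_pipeline()` stays in the seconds range on one core. All randomness
flows from explicit integer seeds; reruns are byte-identical, and the
serialised outputs (`write_pipeline_outputs()`) include the resolved
configuration.

## Known limitations

* No transport/hauling economics: "cost-effective" is a screening class,
  not a dollar figure.
* Single-CRS design: all layers must share one projected metric CRS; there
  is no reprojection or resampling.
* The per-polygon cap shortfall is logged, never reallocated, so severely
  over-reported counts under-count biomass rather than spreading it.
* Validation statewide error levels from any real survey programme are not
  reproducible from synthetic data; the package tests the procedure (exact
  self-comparison, scale invariance, noise recovery), not the published
  error magnitudes.
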