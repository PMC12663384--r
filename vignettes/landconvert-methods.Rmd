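---
title: "Methods: detecting and accounting agricultural conversion of natural land covers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and accounting agricultural conversion of natural land covers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landconvert)
```

## The analysis model

`landconvert` measures agriculture-driven conversion of natural land
covers by categorical map comparison. The unit of observation is a pixel
of a land-cover product, harmonized into five classes: cultivated
land/cropland, grassland & shrubland, non-forested wetland, forestland,
and OTHER (everything outside the analysis: water, ice, bare ground,
impervious surfaces, tundra). Given two harmonized epochs of one product,
a pixel's transition class is determined cell-for-cell:

* **conversion** — a natural class (grassland & shrubland, non-forested
  wetland, forestland) at the earlier epoch and cultivated land at the
  later one, kept separate by source class;
* **reversion** — cultivated land returning to any natural class, the
  diagnostic counterpart used to gauge plausibility of detected change
  (real landscapes show fallow, abandonment and restoration; a product
  showing conversion but implausible reversion patterns hints at
  classification noise);
* **stable** and **other change** complete the taxonomy.

The method is deliberately an *overlay of existing products*, not change
detection on imagery, and carries the products' classification errors
with it; comparing several products (and conversion against reversion) is
the built-in robustness check. No design-based (sampling) area estimation
is attempted.

Decadal periods are compared pairwise (epoch 2000 vs 2010, 2010 vs 2020),
and multi-decade totals are **sums of per-period conversion areas**, not
an endpoint comparison of the first and last maps. An endpoint comparison
would miss convert-then-revert trajectories; the per-period sum matches
the per-decade detection logic. This is a documented assumption of the
package. For overlays that need a single "converted during the whole
span" layer (protected areas, species ranges, KBAs), per-period rasters
are combined cell-wise with the earliest non-stable code winning.

### Areas

All accounting is in hectares on an equal-area footing. On a local
equal-area grid every cell contributes `cell_size^2 / 10^4` ha. On a
geographic grid the per-row spherical area
`R^2 (sin(lat_top) - sin(lat_bottom)) * dlon` is used with the authalic
radius R = 6 371 007.181 m, so summed cell areas over a latitude band
reproduce the closed-form zone area. Real-product workflows are expected
to run in an equal-area projection such as Mollweide; pixel counts then
translate linearly to hectares.

### Overlay rule

Exactly one geometric rule is used for every polygon-raster decision
(zones, PAs, KBAs, species ranges): a cell belongs to a polygon iff its
*center* lies inside it (even-odd ray casting). This makes zonal sums,
PA attribution, and range overlap mutually consistent, keeps partial
boundary cells unambiguous, and makes every overlay checkable by
exhaustive enumeration. The synthetic generators snap polygon vertices
off cell boundaries so the on-edge ambiguity does not arise. Where PAs of
different IUCN categories overlap, the cell goes to the
*strictest* (lowest-numbered) category; IUCN subcategories Ia/Ib are
collapsed to I. Nodata in either epoch removes a cell from every
numerator and denominator, avoiding asymmetric bias between epochs.

### Hotspots

Hotspot cells are defined on a coarse grid (the analysis-scale analogue
of the 10 km grid): per-cell converted areas are averaged across
datasets, cells are ranked descending (ties broken by cell id, for
determinism), and the smallest prefix whose cumulative share reaches the
target (default 90%) is selected. Hotspot countries are zones appearing
in the per-dataset top-*k* (default 10) by conversion area for at least
`min_datasets` (default 2) datasets, reported sorted by cross-dataset
mean; zones absent from one dataset's table count as zero area there,
since absence means no detected conversion.

### Protected areas and biodiversity

Conversion-rate comparisons inside vs outside PAs use, per zone, land
class and IUCN category, the converted area divided by the class's
baseline (first-epoch) area under the same mask; the OUTSIDE row uses the
complement of all PAs. Because land inside and outside PAs differs
systematically in accessibility and suitability, these rates are
*descriptive*, not causal estimates of PA effectiveness. Only PAs
established strictly before a period's start enter that period's
analysis; PAs with unknown establishment year are excluded and counted in
the run report, as are marine-flagged PAs.

Species impact summaries use range polygons with Red List category and
habitat affinities over the three natural classes. Only threatened
species (VU/EN/CR) are counted. A species is *affected* iff its range
overlaps at least one converted cell — any overlap, no minimum-fraction
rule. Affinity buckets follow set size: endemic (one habitat), two,
three; a two-habitat species counts once under *each* of its two classes,
so buckets partition species within a focal class but the same species
may appear under two focal classes. Habitat classes outside the three
natural classes are ignored for bucketing. Richness is computed on a
coarse equal-area *square* grid rather than a hexagon tessellation: the
package targets the exported-raster form of such analyses, and squares
keep the block arithmetic exact and dependency-free. Richness at fine
(pixel) resolution is deliberately not offered: biodiversity threat
extends beyond converted pixels, and pixel-scale richness flattens
regional contrasts.

The affected-species overlay runs against a single designated dataset
(configurable, default the first), reflecting that fine-resolution
species overlays are typically run once against the product whose
cultivated-land class is most inclusive.

## The synthetic generator

The generator emulates the *statistical structure* the analysis consumes,
with known ground truth:

* **Landscape**: one Gaussian random field, smoothed by a separable
  Gaussian kernel with standard deviation `autocorrelation_range` cells
  (default 3) and reflected edges, is cut at the class-proportion
  quantiles. Realized class proportions are therefore exact to within one
  cell while classes form contiguous patches. A second independent field
  masks a `nodata_fraction` (default 2%) of cells.
* **Transitions**: applied independently per cell from a row-stochastic
  matrix. Defaults per decade: grassland & shrubland → cultivated 0.10,
  non-forested wetland → cultivated 0.05, forest → cultivated 0.08,
  cultivated → grassland & shrubland (reversion) 0.02. The i.i.d. choice
  makes recovery tests analytically checkable (binomial standard
  errors); it does *not* claim real conversion is spatially unclustered.
  Realized (from, to) counts are recorded as ground truth and equal a
  direct cell-by-cell comparison by construction.
* **Conservation layers**: PAs are rectangles (vertices snapped off cell
  boundaries) with IUCN category drawn from weights loosely shaped like
  the global PA record (IV–VI most common), establishment years uniform
  on 1950–2010 — the record a before-2000 cutoff analysis presumes is
  dominated by earlier establishments — with a 5% unknown-year and 5%
  marine fraction; candidate rectangles overlapping an accepted one by
  more than 50% are rejected, and a warning reports when fewer than
  requested fit. KBAs are convex blobs. Zones split the extent into
  vertical strips of seeded random widths.
* **Species**: convex ranges; taxa weighted amphibian 0.30 / mammal 0.25
  / reptile 0.25 / bird 0.20 (amphibians lead affected-species counts in
  this literature); 60% threatened, split VU 0.5 / EN 0.3 / CR 0.2;
  habitat-set sizes weighted 0.5 / 0.3 / 0.2. A per-species ground-truth
  flag records overlap with first-step converted cells.
* **Dataset styles**: the emitted per-product rasters are co-registered
  *copies* of the one truth landscape, tagged with product identities.
  Classification-error processes are intentionally not emulated, so
  cross-dataset disagreement (consensus logic, hotspot-country voting
  across discordant tables) is exercised with purpose-built fixtures
  rather than generator output.

All randomness flows from one scenario seed through named per-module
substreams, so any object can be regenerated independently of the
others; a fixed seed reproduces every raster, polygon and attribute
exactly, and every pipeline CSV byte-identically (floats are serialized
with 6 significant digits).

What passing tests on this generator show — and what they do not: they
validate the *bookkeeping* (transition coding, equal-area sums, overlay
attribution, ranking logic) and the estimator's statistical behaviour
under known rates. They cannot validate robustness to co-registration
error, legend ambiguity, classification noise, or spatially clustered
change, none of which the generator produces.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `grid_shape` | 200 × 200 | cells | large enough that a 3-SE binomial recovery band is tight (~40k cells) yet runs in seconds |
| `cell_size` | 100 | m | 1 ha cells make areas equal cell counts, easing inspection |
| `threshold` | 0.90 | share | hotspot-cell coverage target |
| `k`, `min_datasets` | 10, 2 | — | hotspot-country ranking: top ten per dataset, confirmed by at least two |
| `block_size_m` | 10 × cell size | m | coarse grid for fractions/hotspots/richness |
| `pa_cutoff_year` | first period start | year | strict `<` comparison; per-period analyses use each period's start |
| `autocorrelation_range` | 3 | cells | patch scale; 0 gives i.i.d. cells |

## Numerical and degenerate-input choices

* Transition, zonal and block computations are exact integer/double
  arithmetic; no tolerance enters until areas are serialized (6
  significant digits).
* Ties in hotspot ranking break by ascending cell/zone id; results are
  invariant to input row order.
* Zero total conversion yields an empty hotspot set with a warning; zero
  baselines yield `NA` rates, flagged and excluded from summaries, never
  0/0.
* Valid cells outside every zone are reported under a reserved
  `unassigned` zone so zonal tables always reconcile with global totals.
* Coarse block sizes must be integer multiples of the cell size; the
  error message suggests the nearest valid value.

## Test problem sizes

Oracle-equivalence tests run exhaustive enumerations on grids up to
100 × 100 with ≤ 50 polygons. Parameter recovery uses 100 replicates of
the default 200 × 200 scenario, checking each class-conditional
conversion rate against its truth within three binomial standard errors.
The null-effect check (no artefactual inside/outside PA difference under
spatially uniform transition probabilities) uses 100 replicates of a
100 × 100 scenario with randomly placed PAs and a two-proportion z-test.
Hotspot logic is verified against exhaustive prefix/ranking search on
1,000 randomized tables each. These sizes were chosen so the full suite
documents the statistical claims while remaining fast enough to run on
every change.

## Known limitations

* No tiled or out-of-core processing: rasters must fit in memory, so
  true 30 m global extents are out of reach (the package's own studies
  run at reduced extents or coarser cells).
* Polygon features are single exterior rings; no holes or multipolygons.
* Resampling for co-registration of real products is limited to
  nearest-neighbour (categorical data); the package does not reproject.
* The conversion/reversion comparison and cross-product spread are the
  only uncertainty handles; no accuracy assessment or confidence
  intervals for areas.
* No edge-effect buffering around converted cells in the species
  overlay, and no interspecific-interaction modelling.
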