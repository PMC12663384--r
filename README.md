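# landconvert

Quantifying agricultural expansion into natural ecosystems from
multi-epoch categorical land-cover maps.

Global land-cover products (GlobeLand30, GLCLUC, GLC_FCS30D) describe the
Earth's surface at 30 m resolution for 2000, 2010 and 2020, each with its
own class legend. Agricultural encroachment on *non-forest* natural
ecosystems — grasslands, shrublands and non-forested wetlands — is far less
studied than deforestation, yet these ecosystems hold a large share of
terrestrial carbon and biodiversity. `landconvert` provides the analysis
machinery to measure that encroachment consistently across products, for
conservation scientists and land-use analysts:

* **Harmonization** — map each product's native legend into a common
  scheme: cultivated land/cropland (C), grassland & shrubland (G),
  non-forested wetland (W), forestland (F), plus OTHER. The shipped tables
  encode the cross-product correspondence rules (tree-height split for
  GLCLUC; woody wetlands counted as forest in GLC_FCS30D; GlobeLand30's
  undivided wetland class kept out of forest).
* **Transition detection** — per-pixel overlay of two harmonized epochs,
  coding conversions G→C, W→C, F→C, reversions C→{G,W,F}, stable cells and
  other changes; nodata in either epoch excludes the pixel everywhere.
* **Equal-area accounting** — per-cell areas in hectares (constant on an
  equal-area grid, spherical per-row areas on a geographic grid), zonal
  (country) aggregation, and per-block conversion fractions
  `f = n_converted / n_valid` on a coarse grid (the "10 km grid").
* **Hotspots** — the minimal set of coarse cells whose cross-dataset mean
  converted area covers 90% of the total, and hotspot countries: zones in
  the per-dataset top-*k* (by conversion area) for at least *m* datasets.
* **Protected areas** — conversion inside PAs by IUCN category I–VI
  (strictest category wins on overlap), establishment-year filtering, and
  inside/outside rates: `rate = converted area / baseline class area` per
  zone, class and category.
* **Biodiversity** — consensus-conversion cells (detected by every
  dataset), threatened-species (VU/EN/CR) richness on a coarse equal-area
  grid, species affected by conversion bucketed by taxon and
  habitat-affinity size (endemic / two / three habitats), and conversion
  inside Key Biodiversity Areas compared with PA coverage.
* **Synthetic landscapes** — a seeded generator producing co-registered
  epoch rasters with known class proportions, spatial autocorrelation and
  per-cell transition probabilities, plus PA/KBA/zone polygons and species
  ranges with ground truth, so the whole pipeline is testable without the
  multi-gigabyte global inputs.

Rasters are lightweight matrix-backed objects exchanged as Arc/Info ASCII
grids; vector layers travel as GeoJSON, tables as CSV, scenarios and
configurations as YAML. All overlay decisions use one rule: a cell belongs
to a polygon iff its center lies inside it.

## Worked example

```r
library(landconvert)

scn  <- synthetic_scenario(grid_shape = c(120, 120), seed = 42)
land <- generate_landscape(scn, n_epochs = 3)
tr   <- detect_transitions(land$epochs[[1]], land$epochs[[2]])
tr
#> <transition_raster> synthetic, 2000-2010: 120 x 120 cells

layers <- generate_conservation_layers(scn, land)
at <- aggregate_by_zone(tr, layers$zones)
subset(at, transition_code %in% c("CONV_GRASS", "CONV_WETLAND"))
#>   zone_id dataset_id    period transition_code area_ha
#> 1     Z01  synthetic 2000-2010      CONV_GRASS     147
#> 2     Z02  synthetic 2000-2010      CONV_GRASS     164
#> 3     Z03  synthetic 2000-2010      CONV_GRASS     166
#> 4     Z01  synthetic 2000-2010    CONV_WETLAND      20
#> 5     Z02  synthetic 2000-2010    CONV_WETLAND       9
#> 6     Z03  synthetic 2000-2010    CONV_WETLAND      13

gs <- grid_fraction(tr, 1200)            # 1.2 km blocks of 100 m cells
hotspot_cells(list(gs), threshold = 0.9)
#> <hotspot_cells> 79 cell(s) covering 90.5% (target 90%) of 782.0 ha
```

Each `area_ha` row is the summed equal-area extent (1 ha cells here) of
one transition class within one zone ("country") for the 2000–2010
decade: e.g. 147 ha of grassland & shrubland converted to cultivated land
in zone Z01. The hotspot set is the smallest group of coarse cells — 79 of
144 — whose conversion areas, ranked descending, cover at least 90% of the
782 ha total.

Protected-area rates compare conversion inside PAs (by IUCN category)
with the unprotected remainder:

```r
pas <- filter_by_year(layers$pas, 2000)  # established before 2000
rt  <- conversion_rates(tr, land$epochs[[1]], pas, layers$zones)
subset(rt, category == "OUTSIDE" & land_class == "GRASS_SHRUB")
#>    zone_id dataset_id    period  land_class category converted_area_ha
#> 55     Z01  synthetic 2000-2010 GRASS_SHRUB  OUTSIDE               133
#> 56     Z02  synthetic 2000-2010 GRASS_SHRUB  OUTSIDE               156
#> 57     Z03  synthetic 2000-2010 GRASS_SHRUB  OUTSIDE               162
#>    baseline_area_ha       rate
#> 55             1493 0.08908238
#> 56             1587 0.09829868
#> 57             1611 0.10055866
```

With the default scenario's uniform 10% per-decade grass-to-cultivated
probability, outside-PA rates land near 0.10, as they should.

A whole run — transitions, zonal tables, grid summaries, hotspots, PA
rates, biodiversity summaries and a reconciling run report — is one call:

```r
cfg <- run_config(mode = "synthetic", scenario = scn)
run_pipeline(cfg, "out_dir")
```

or, from a shell, via the thin CLI in `inst/cli/landconvert.R`
(`run`, `simulate`, `report` subcommands).

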