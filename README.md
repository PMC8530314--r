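# meshfrag

Landscape fragmentation of protected-area networks, measured by effective
mesh size and density.

## The problem

Protected areas are meant to shelter habitats from anthropogenic development,
but roads, railways and built-up areas do not stop at their borders. A
landscape-scale way to quantify this pressure is the **effective mesh size**
(*m*<sub>eff</sub>, km²): the probability that two randomly chosen points in a
reporting unit are connected — lie in the same barrier-free patch —
multiplied by a reference area; equivalently, the expected area accessible
from a random point without crossing a barrier. Its reciprocal, the
**effective mesh density** *s*<sub>eff</sub> = 1000 / *m*<sub>eff</sub>
(meshes per 1000 km²), grows with fragmentation. meshfrag is for
conservation scientists and geoinformatics practitioners who want to ask, for
every site of a protected-area network: *how fragmented is the site inside,
how fragmented is its immediate surrounding, and which is worse?*

The package implements the full analysis chain:

* per-cell *m*<sub>eff</sub> from a binary barrier raster, by the
  **cross-boundary connections** procedure
  (CBC, Σᵢ A<sub>ik</sub>·A<sub>i</sub> / A<sub>k</sub>, free of the
  reporting-unit boundary problem and area-proportionately additive) and by
  the classical cutting-out procedure
  (CUT, Σᵢ A<sub>ik</sub>² / A<sub>k</sub>), with 4-connected patch labeling
  at subcell resolution (C++ backend);
* site-level aggregation: cell-center rasterization of site polygons,
  exclusion of marine and center-less sites, a 5-km buffer annulus,
  mean aggregation of per-cell values (valid by additivity), densities,
  the difference *s*<sub>eff,diff</sub> =
  *s*<sub>eff,surrounding</sub> − *s*<sub>eff,within</sub>, five standard
  density categories (≤ 1.5 / 10 / 50 / 250 / > 250 meshes per 1000 km²),
  a marginal-fragmentation flag (both sides ≤ 0.9), protection ages from a
  WDPA-like registry (earliest designated year), and per-region medians;
* closed-form OLS regressions (within ~ surrounding overall and per
  biogeographical region on the log(x+1) scale, density ~ area,
  difference ~ age) with an independent Monte-Carlo oracle suite validating
  the mesh computations;
* a seeded synthetic-landscape generator (Cox-thinned random road chords,
  settlement disks, a smooth log-Gaussian pressure field, star-shaped site
  polygons, region tessellations, age registries) so the whole pipeline runs
  reproducibly with known ground truth and no external data.

## Worked example

```r
library(meshfrag)

# a 100 x 100 km landscape at 200-m barrier resolution, 20 protected sites
cfg <- scenario_config(seed = 42,
                       grid = grid_spec(100, 100, cell_size = 1, subcell_factor = 5),
                       n_sites = 20, site_area_range = c(1, 400),
                       road_intensity = 0.5, settlement_intensity = 1.5,
                       field_length_scale_km = 15)
bundle  <- generate_scenario(cfg)
patches <- label_patches(bundle$barrier)
mesh    <- meff_cbc(patches)

patches
#> patch_map: 420 patches, open area 9133 km2 of 1e+04 km2
mesh
#> mesh_raster (CBC): 100 x 100 cells, meff range [0, 1269] km2

res <- analyze_sites(bundle$sites, mesh, registry = bundle$registry,
                     regions_admin = bundle$regions$admin)
head(res$records[, c("site_id", "seff_within_per1000km2",
                     "seff_surrounding_per1000km2", "diff_class",
                     "category_within", "age_years")])
#>   site_id seff_within_per1000km2 seff_surrounding_per1000km2      diff_class
#> 1   S0001             24.2227913                  19.3168762 more_fragmented
#> 2   S0002             57.1230856                  15.3229504 more_fragmented
#> 3   S0004             32.8394283                  51.5813866 less_fragmented
#> 4   S0005              7.8576720                   6.2054929 more_fragmented
#> 5   S0006              0.7924498                   0.9992447 less_fragmented
#> 6   S0007              8.3795654                  11.6851560 less_fragmented
#>   category_within age_years
#> 1          medium        33
#> 2            high        10
#> 3          medium        15
#> 4             low        21
#> 5        very_low         4
#> 6             low        32
```

Reading the records: site `S0001` has an interior density of 24.2 meshes per
1000 km² (category *medium* — its interior is effectively divided into
meshes of ≈ 41 km²) against 19.3 in its 5-km surroundings, so it is **more**
fragmented than its matrix; `S0004` is the opposite case. Ages come from the
earliest designated year in the bundled registry. Three of the twenty sites
were excluded (marine flag or no covered cell center) and appear in
`res$exclusions` with reasons.

```r
summ <- summarize_records(res$records)
summ$regressions[summ$regressions$group == "all",
                 c("slope", "intercept", "r_squared", "n")]
#>      slope intercept r_squared  n
#> 1 1.019435 0.1322734 0.7813873 17
summ$tables$diff_class
#>             class n  fraction
#> 1 less_fragmented 8 0.4705882
#> 2           equal 0 0.0000000
#> 3 more_fragmented 9 0.5294118
```

Interior fragmentation tracks the surroundings closely (R² = 0.78 on the
log(x+1) scale, slope ≈ 1): sites are embedded in, not insulated from, the
development pressure of their matrix.

File-based equivalents (`run_simulate`, `run_compute_mesh`, `run_analyze`,
`run_summarize`) read and write ESRI ASCII grids, GeoJSON and CSV; a thin
command-line dispatcher with the same four subcommands is installed at
`inst/cli/meshfrag.R`.

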