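---
title: "Effective mesh density in and around protected areas: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective mesh density in and around protected areas: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The fragmentation metric

meshfrag quantifies landscape fragmentation with the *effective mesh size*
(`meff`, km²): the probability that two points chosen uniformly at random in a
reporting unit are connected — lie in the same barrier-free patch — multiplied
by a reference area. Equivalently, `meff` is the expected size of the area
accessible to an animal from a random starting point without crossing a
barrier. Its reciprocal, scaled to the reporting convention of European
fragmentation products, is the *effective mesh density*
`seff = 1000 / meff`, in meshes per 1000 km²; higher densities mean finer
subdivision, i.e. stronger fragmentation. A landscape completely covered by
barriers has `meff = 0`; the package carries the corresponding density as an
`Inf` sentinel which falls into the top fragmentation category downstream.

Two per-cell procedures are implemented for a reporting cell $k$ with full
cell area $A_k$, intersecting patches $i$ with intersection areas $A_{ik}$ and
complete patch areas $A_i$:

* **CUT** (cutting-out): cell boundaries act as additional barriers,
  $\mathrm{meff}_{CUT}(k) = \frac{1}{A_k}\sum_i A_{ik}^2$. Values never exceed
  the cell area; cells on a patch boundary are penalized (the "boundary
  problem").
* **CBC** (cross-boundary connections): connections reaching beyond the cell
  are credited to the cell,
  $\mathrm{meff}_{CBC}(k) = \frac{1}{A_k}\sum_i A_{ik} A_i$. This removes the
  boundary problem and makes the metric *area-proportionately additive*: the
  arithmetic mean of per-cell CBC values over any set of equal-area cells
  equals the CBC value of the merged set treated as one reporting unit, and
  the mean over the whole grid equals the global
  $\sum_i A_i^2 / A_{total}$. The test-suite asserts this identity to
  1e-9 relative on every landscape it generates — it is the property that
  justifies aggregating per-cell values over protected sites by a plain mean.

The denominator $A_k$ always includes barrier area; this is forced by the
convention that a fully sealed cell has `meff = 0` (excluding barrier area
would leave that case undefined).

Both procedures are validated against seeded Monte-Carlo oracles that
implement the probability definitions directly (sampling accessible-area for
CBC, same-patch indicators for CUT); the closed-form values agree with the
oracles within three standard errors across randomized landscapes.

## From barrier geometry to site records

The input is a *fragmentation geometry*: a binary mask of major and medium
anthropogenic constructions (roads, railways, built-up areas) at subcell
resolution (default 10 subcells per axis under a 1-km reporting cell, i.e.
100 m) on an equal-area grid in km units. All geometry is planar; inputs must
share one equal-area CRS — the package checks nothing and fixes nothing about
projections. Patches are 4-connected (rook) components of open subcells:
one-subcell-wide rasterized roads must sever patches, which 8-connectivity
would leak across diagonally. Patch areas are exact subcell counts times the
subcell area. Patches truncated by the study-area edge use their within-extent
area as their complete area — the dataset boundary is treated as the edge of
the world, the same limitation any finite raster product has.

The site-level analysis mirrors the standard protected-area workflow:

1. **Filter**: marine sites are excluded, then sites covering no reporting
   cell center (closed polygon test: a center exactly on the boundary counts
   as covered — a deterministic, documented tie-break). Every exclusion is
   reported with its reason.
2. **Assign**: interior cells are those with centers inside the site; buffer
   cells are those with centers within the 5-km Euclidean buffer annulus and
   not in the interior. Within one site's analysis each cell is assigned only
   once, never to both the site and its buffer. Distinct sites may share
   cells — per-site independence keeps each site's statistic self-contained.
   Buffer membership uses the exact distance predicate
   (`0 < dist(center, site) <= 5 km`), which is the mathematically exact
   buffer, with no polygonal approximation. Would-be buffer centers beyond the
   raster extent are dropped and counted.
3. **Aggregate**: the site's `meff` is the arithmetic mean of its interior
   cells' CBC values (valid by additivity); likewise for the buffer. Densities
   follow as `1000/meff`, and
   `seff_diff = seff_surrounding - seff_within` is positive when the site is
   less fragmented than its surroundings. "Equally fragmented" means exact
   equality of the computed densities — no epsilon; exact ties arise from
   identical aggregates (e.g. both sides inside one patch) and are rare.
   If both densities are the `Inf` sentinel the difference is defined as 0.
4. **Classify**: densities map to five categories with upper-closed bounds
   (meshes per 1000 km²): very low (≤ 1.5), low (> 1.5–10), medium (> 10–50),
   high (> 50–250), very high (> 250, including the sentinel — the fully
   sealed "anthropogenic" class is merged into very high). Sites with both
   densities at or below 0.9 meshes per 1000 km² are flagged as *marginal
   fragmentation*, independently of the difference class.
5. **Ages**: a registry (WDPA-like) may carry several entries per site; the
   site's age is the reference year (default 2017) minus the earliest year
   among entries with status `"designated"` — other statuses (e.g.
   `"proposed"`) are ignored; sites without a designated entry get a missing
   age and drop out of the age regression. Registry linkage is by site id.
6. **Regions**: each site belongs to exactly one admin region, assigned by a
   deterministic representative point (the center of its first interior cell
   in row-major cell order). Regional summaries report the *median* of the
   raw site densities — never medians of categories, and never means, to damp
   the influence of outliers — and then categorize the median.

## Regressions

Fits are closed-form ordinary least squares (normal equations, $R^2 = 1 -
SSE/SST$, two-sided $t$ test on the slope with $n-2$ df), re-implemented so
the fitting contract has no external dependency; `stats::lm` serves as an
independent cross-check in the tests. Three relationships are fitted:

* interior density on surrounding density, overall and per biogeographical
  region — both sides log(x+1)-transformed by default, because the density
  distributions are strongly right-skewed. Reported coefficients live on the
  transformed scale and carry a transform tag; a raw-scale option exists
  because the transformed and raw conventions are both in circulation for
  this analysis. Regions with fewer than 3 usable records are flagged
  `"insufficient n"`, not fitted.
* interior density on site area (log(x+1) both sides for comparability, raw
  behind the same flag);
* the fragmentation difference on site age, on the raw scale (the difference
  is signed).

No multiple-testing correction is applied across the per-region fits, and
p-values are two-sided. Records with undefined surrounding density (empty
buffer) or missing age are excluded per fit.

## The synthetic-landscape generator

Real European-scale inputs (a continental mesh raster, the protected-site
vector set, a registry) are large, partly on-demand datasets. The generator
replaces them with seeded scenarios whose ground truth is known, so every
pipeline stage and every acceptance property runs reproducibly from a single
integer seed. It emulates, statistically rather than cartographically:

* **A smooth development-pressure field**: seeded white noise at
  reporting-cell resolution, smoothed with a circular Gaussian kernel
  (length-scale 40 km), standardized to sd 1.2 on the log scale, clamped at
  ±2.5 sd (keeping the Cox thinning bound finite without visibly changing the
  body of the distribution), exponentiated and normalized to mean exactly 1.
  Because a site and its 5-km surroundings share the local field value, the
  field is the mechanism that couples interior and exterior fragmentation —
  the correlation the analysis is designed to detect.
* **Roads** as a Poisson process of random chords (uniform angle and offset),
  thinned per whole chord with probability proportional to the mean field
  along it. Chords partition the plane, which finite road segments would not:
  patch structure — the substance of the metric — requires barriers that
  close. Chords are rasterized one subcell wide with a supercover traversal
  so that 4-connected patches are properly severed.
* **Settlements** as a field-thinned point process of disks (lognormal radii,
  0.1–2 km).
* **Protection**: inside each site, each chord's and each settlement's
  in-site portion is removed with probability $1-f$, independently per
  object-site pair. $f = 1$ is the null (no protection effect); $f = 0$
  clears interiors of barriers entirely. Intensity coupling is monotone: with
  one seed, raising an intensity yields a superset of barrier subcells
  (inverse-CDF count coupling plus fixed-stride parameter streams).
* **Sites**: star-shaped polygons (perturbed rotated ellipses) with areas
  log-uniform on [1, 5556] km², rescaled to the drawn area exactly and placed
  to fit the grid; a configurable fraction is flagged marine (a labeled
  stratum that exercises the filter — no ocean geometry is simulated).
  Biogeographical labels come from a nearest-seed tessellation with nine
  regions; a finer tessellation plays the role of admin (NUTS-3-like)
  regions.
* **Ages**: uniform on [2, 37] years against a 2017 reference, delivered
  through a registry with 1–3 entries per site mixing designated and proposed
  statuses, with the planted earliest designated year recorded as ground
  truth.

### Default study conditions and their rationale

The defaults were chosen once, against the emulation targets, and then
frozen:

* grid 600 × 600 km with 1-km reporting cells: with 100 sites of mean area
  ≈ 645 km² (the log-uniform mean), expected site coverage is ≈ 18% of the
  window — the terrestrial protected-area share of the emulated network.
  The generator's default subcell factor is 5 (200 m), a deliberate
  scale-down from the 100-m modeling default that leaves patch topology
  intact (chords sever patches at any resolution).
* road intensity 0.12 chords and 0.6 settlements per 100 km², field sd 1.2,
  length-scale 40 km: produce a modal "medium" interior category with a
  substantial high/very-high tail, a median interior density of ~15–20
  meshes per 1000 km², and an interior~surrounding $R^2$ of ~0.75–0.8 on the
  log(x+1) scale — the qualitative shape of the European analysis this
  package emulates.
* protection factor 0.8: a mild protection effect under which roughly 57–63%
  of sites come out less fragmented than their surroundings — a narrow
  majority, as observed for real protected-area networks.

### What the generator does not emulate

Passing tests on these scenarios demonstrate the pipeline's correctness and
the stated statistical properties; they do not certify behaviour on real
data, which differs in at least these ways:

* No real geography: no coastlines, no land-cover classes, no road
  hierarchies, no true marine geometry.
* The log-uniform site-area distribution matches the documented range
  [1, 5556] km² but is far less skewed than real networks, whose mean site
  area (~52 km²) is dominated by many small sites. Results conditional on
  site-size composition will differ.
* No truly roadless regions: the clamped lognormal field makes low-intensity
  areas sparse in barriers but almost never empty, so the *marginal
  fragmentation* class (both densities ≤ 0.9) is nearly unpopulated at the
  defaults — it is exercised by constructed landscapes in the unit tests
  instead.
* Sites are placed independently of the barrier process (before protection
  thinning). Real protected areas are preferentially designated in remote,
  low-pressure regions; the generator has no such confounding, which is
  precisely what makes it a clean null/recovery instrument.

### A note on the null symmetry of the difference statistic

With $f = 1$ the barrier process is identical inside and outside sites, and
one might expect exactly half of all sites to score "less fragmented than
surroundings". The acceptance suite measures this fraction at the default
conditions and finds ≈ 0.43 — reproducibly below one half, and the package
treats this as a real property of the estimator rather than a defect: the
per-cell CBC distribution is heavily right-skewed (a few cells sit in very
large patches), the compact interior mean is a noisier, right-skewed average
whose median lies below its mean, while the larger surrounding annulus
averages more values; inverting through `1000/mean` then tips slightly more
than half of null sites to "more fragmented". The same experiment with
independently placed circular pseudo-sites, and with spatially shuffled cell
values, reproduces the effect, ruling out a site-generation artefact.
Consequence for interpretation: under mean-then-invert aggregation of a
skewed mesh raster, a measured less-fragmented share of ~50% does *not*
indicate absence of a protection effect — the no-effect baseline sits below
one half.

## Numerical and engineering choices

* Areas are exact subcell counts times the subcell area; additivity
  identities hold to floating-point accuracy (asserted at 1e-9 relative,
  observed far tighter).
* Degenerate inputs: an empty grid errors ("empty landscape"); an all-barrier
  landscape yields zero mesh sizes, `Inf` densities, top category; an empty
  interior cell set errors; an empty buffer set yields a record with missing
  surrounding values, excluded from difference statistics.
* Determinism: every random choice in the generator derives from the scenario
  seed through fixed tags; identical (config, seed) reproduce byte-identical
  scenario files and analysis CSVs. CSV output is locale-independent
  ("." decimal, 6 significant digits, `Inf` serialized as the literal
  `"inf"`).
* Raster I/O uses the plain-text ESRI ASCII grid format (georeferenced by
  corner and cell size); site vectors use GeoJSON. A procedure sidecar tag
  records whether a mesh raster is CBC or CUT; externally produced mesh
  rasters can be read directly, bypassing the barrier stage.
* Patch labeling, per-cell patch tabulation, point-in-polygon and distance
  kernels, and supercover traversal are implemented in C++ (Rcpp); everything
  else is vectorized R.

## Problem sizes used by the test-suite

The suite validates the Monte-Carlo oracle equivalence on twenty 50 × 50-cell
landscapes at the 100-m subcell default (100 000 samples per audited cell),
monotonicity on 200 single-subcell perturbations, assignment oracles on 50
random sites, the null-symmetry and protection-ordering experiments on
600 × 600-km scenarios with 100 sites each (30 seeds at $f=1$; 8 seeds at
each of three protection levels) at a 333-m subcell resolution, regression
calibration on 5000 null replicates and 100 recovery replicates at n = 2000,
and byte-level determinism on a 60 × 60-km double run. These sizes are the
package's chosen validation scale: large enough for the asserted tolerances,
small enough to run routinely.

## Known limitations

* No vector-native mesh computation: the raster approximation at subcell
  resolution is the method; vector overlays are out of scope.
* No reprojection: inputs must already share one planar equal-area CRS.
* No hole-in-polygon site geometry (outer rings only), matching the
  generator's output; real-world site files with holes need preprocessing.
* Registry linkage is by site id, not by spatial overlay.
* Single-epoch barrier masks only; no change metrics between fragmentation
  states.
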