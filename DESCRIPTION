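Package: meshfrag
Title: Effective Mesh Size and Density Analysis of Protected-Area Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes landscape fragmentation from a fine-resolution barrier
    geometry using the effective mesh size (meff) and effective mesh density
    (seff) metrics, with both the cross-boundary connections (CBC) and the
    cutting-out (CUT) reporting procedures. Aggregates per-cell mesh values
    inside protected-area polygons and in a surrounding buffer ring,
    classifies fragmentation into standard density categories, compares
    interior against exterior fragmentation, joins protection ages from a
    registry, and summarises results per region with closed-form linear
    regressions. Includes a seeded synthetic-landscape generator (random
    chord road networks, settlement disks, a smooth log-Gaussian intensity
    field, protected-site polygons, region tessellations and age registries)
    so the whole pipeline runs reproducibly without external data, plus
    Monte-Carlo oracles for validating the mesh computations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
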