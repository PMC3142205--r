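Package: twostepfca
Title: Conventional and Optimized Two-Step Floating Catchment Area Accessibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures potential spatial accessibility of a population to
    clinics with the two-step floating catchment area (2SFCA) method, in
    both its conventional form (clinic counts against total population)
    and an optimized form that weights supply by physician counts and
    demand by age-specific utilization proportions. Includes Euclidean
    and street-network travel distances, catchment construction, spatial
    weight matrices (queen contiguity, inverse distance squared), global
    Moran's I, centrography (weighted mean center, standard deviational
    ellipse, nearest-neighbour index), method-comparison statistics
    (0-100 rescaling, difference scores, Spearman rank correlation,
    t-tests), a seeded generator of synthetic city instances, and
    CSV/GeoJSON readers and writers tying the workflow together.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
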