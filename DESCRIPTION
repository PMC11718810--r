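Package: cephaloid
Title: Polyhedral Morphogenesis Models of Sea Turtle Head Scute Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Combinatorial and geometric tools for modelling the head scute
    pattern of the flatback sea turtle hatchling as a convex polyhedron.
    Provides a validated polyhedral-complex representation with censuses and
    dorsal (basal-face) planar projections; canonical cephaloid dodecahedron
    and tetradecahedron templates; the two foam-dynamics operators (T1 edge
    formation at a tetravalent vertex and edge-interior facet splitting) with
    exact element bookkeeping; a convergent-extension construction taking a
    regular hexagon to a kite with in-plane symmetry-axis detection; an
    in-silico replacement of the putty experiment that packs fifteen oblate
    spheroids in a 1-6-6-1 cluster, stretches and pinches it, and extracts the
    surface region-adjacency pattern; and specimen-to-template matching with
    dorsal-visibility scoring. Synthetic-data generators (perturbed clusters,
    random observations, random sphere-like complexes) make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
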