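# cephaloid

Polyhedral morphogenesis models of sea turtle head scute patterns.

The head of the flatback sea turtle hatchling, viewed dorsally, is
segmented by its scutes into a pattern that matches a specific convex
zygomorphic polyhedron: a dodecahedron of twelve quadrilateral facets
(F = 12, V = 14, E = 24), and even more closely a derived tetradecahedron
with ten quadrilaterals, three pentagons and one heptagon
(F = 14, V = 19, E = 31 — 64 discrete elements), whose edge-sharing
pentagonal frontal and heptagonal frontoparietal scutes form a striking
dorsal pentagon–heptagon pair. `cephaloid` is for researchers in
morphometrics, herpetology and mathematical biology who want to work with
this model quantitatively. It provides:

- a validated combinatorial **polyhedral-complex** representation (closed
  orientable surface, Euler characteristic V − E + F = 2, handshake
  identities), with element censuses, facet-adjacency graphs, and planar
  **dorsal projections** through the basal facet (Tutte/barycentric
  embedding);
- the canonical **cephaloid templates** (dodecahedron, intermediate
  dodecahedron, tetradecahedron) with head-scute role labels, plus
  auxiliary solids;
- the two **foam-dynamics operators** with exact bookkeeping: T1 edge
  formation at a tetravalent vertex (ΔF = 0, ΔV = +1, ΔE = +1) and
  edge-interior facet splitting (ΔF = +1, ΔV = +2, ΔE = +3), which connect
  the templates: T1 at the interorbital vertex followed by bilateral
  supraocular splits turns the 50-element dodecahedron into the 64-element
  tetradecahedron;
- an **in-silico putty experiment**: fifteen oblate spheroids
  (aspect ratio c/a = 0.9) packed 1-6-6-1 around a central one, deformed by
  a convergent-extension strain protocol (anterior stretch, dorsal midline
  convergence, flattening) with prescribed anterolateral fusions — the
  deformed cluster's twelve surface regions reproduce the dodecahedron's
  facet-adjacency graph exactly;
- the planar **hexagon-to-kite** convergent-extension construction with
  in-plane symmetry-axis counting (six C2 axes reduce to one);
- **specimen matching**: labelled graph isomorphism, dorsal visibility
  (63 of 64 elements), and the identification-success score;
- **synthetic-data generators** (perturbed clusters, dropout observations,
  random sphere-like complexes) so every stage is testable with no
  external data.

## Worked example

The full pipeline — pack, stretch, match to the dodecahedron, apply the
foam operators, match and project the tetradecahedron:

```r
library(cephaloid)
rep <- run_pipeline(pipeline_config(seed = 1))
print(rep)
#> <cephaloid_report>
#>   pack:    14/14 central contacts
#>   stretch: 12 surface regions, dodecahedron match: TRUE
#>   pathway: tetradecahedron census {4:10, 5:3, 7:1}, total 64, match: TRUE
#>   dorsal projection: 63 of 64 elements visible
```

Line by line: all fourteen outer spheroids of the relaxed 1-6-6-1 cluster
touch the central one; after convergent extension and the two prescribed
anterolateral fusions the cluster's twelve surface regions are
role-respecting isomorphic to the dodecahedron's facet graph (the
mandibular spheroid lands on the basal facet); the T1 + bilateral-split
pathway then yields the tetradecahedron with the printed census and
64 elements; and its dorsal projection hides only the basal facet.

Scoring a specimen annotation that misses the one edge that is not
readily apparent on flatbacks (caudal apex to the heptagon's caudal
vertex):

```r
tet <- cephaloid_tetradecahedron()
vis <- visible_elements(tet, "basal")
obs <- observation_set(tet, facets = vis$facets, vertices = vis$vertices,
                       edges = setdiff(vis$edges, edge_id("p", "pn")))
identification_score(tet, "basal", obs)
#> identification score: 62/63 = 0.984
#>   facets    13 of 13
#>   vertices  19 of 19
#>   edges     30 of 31  (missing: p--pn)
```

And the planar construction:

```r
k <- stretch_to_kite(regular_hexagon(1))
sort(edge_lengths(k))   # 1 1 2 2  (anterior edges twice the caudal ones)
perimeter(k)            # 6        (rigid strips conserved)
c2_axes(k)$count        # 1        (down from the hexagon's 6)
```

A thin command-line front end ships at `inst/scripts/cephaloid`
(subcommands `run`, `templates`, `hex2kite`, `match`, `synth`).

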