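---
title: "Polyhedral morphogenesis of the sea turtle head: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polyhedral morphogenesis of the sea turtle head: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cephaloid)
library(igraph)
```

## The model

The head scute pattern of the flatback sea turtle hatchling, seen in dorsal
view, closely matches the topology of a particular convex bilaterally
symmetric (zygomorphic) polyhedron. `cephaloid` implements that observation
as a fully testable geometric model with three linked parts:

1. **Combinatorial polyhedra.** A *polyhedral complex* is a closed
   orientable sphere-like surface given purely combinatorially: facets as
   consistently oriented cyclic vertex sequences. The package's canonical
   templates are the *cephaloid dodecahedron* (twelve quadrilateral facets,
   14 vertices, 24 edges), an *intermediate dodecahedron* in which the
   frontal and frontoparietal facets have become an edge-sharing pentagon
   pair, and the *cephaloid tetradecahedron* (ten quadrilaterals, three
   pentagons, one heptagon; 19 vertices, 31 edges — 64 discrete elements).
   Facet roles carry the head-scute nomenclature: frontal, frontoparietal,
   paired prefrontals and supraoculars, rostral, paired temporals, a caudal
   pair, and the kite-shaped basal (mandibular) facet.

2. **Foam operators.** Two topological moves connect the templates. *T1
   edge formation* (the forward half of a foam neighbour exchange) replaces
   a tetravalent vertex by a new edge between the two opposite "gaining"
   facets: facet count unchanged, one new vertex, one new edge; the other
   two facets are pushed apart and keep their degree. *Edge-interior facet
   splitting* draws a chord between points interior to two boundary edges
   of a facet: one new facet, two new vertices, three new edges, and each
   neighbour across a chosen edge gains one degree. Applied to the
   dodecahedron — T1 at the interorbital vertex, then one mirror-symmetric
   split per supraocular facet with a split point on each
   frontoparietal-shared edge — they produce the tetradecahedron exactly:
   12+14+24 = 50 elements become 64, the frontal pentagon and
   frontoparietal heptagon share an edge, and the supraoculars each split
   into two quadrilaterals (which forces the paired prefrontals to become
   the remaining two pentagons of the census — the only assignment
   compatible with ten quadrilaterals).

3. **The packing-and-stretching experiment.** The dodecahedral pattern is
   itself derived: fifteen identical slightly oblate spheroids (aspect
   ratio 0.9) packed 1-6-6-1 around a central one, stretched
   anteroposteriorly with anterior narrowing, develop exactly the
   dodecahedron's twelve surface regions. The package replaces the original
   hand-shaped putty model with a deterministic simulation
   (`build_1661_cluster()` + `convergent_extension()`).

## Template reconstruction

The templates are encoded from their structural constraints: twelve
quadrilaterals with V = 14 and E = 24 (forced by the Euler relation for an
all-quadrilateral sphere), zygomorphy, a kite-shaped basal facet whose four
edges form the dorsal-projection perimeter, a frontal facet that meets the
frontoparietal facet in exactly one tetravalent vertex, and a downstream
tetradecahedron with census {4:10, 5:3, 7:1} whose caudal-most vertex is
joined by an edge to the caudal-most vertex of the heptagon. These
constraints admit the incidence structure shipped in
`cephaloid_dodecahedron()`; its vertex degrees come out six tetravalent and
eight trivalent, and every constraint above is enforced in the test suite.
Coordinates are deliberately optional: all scientific claims here are
combinatorial, and embeddings (the Tutte dorsal projection, the unit-sphere
export embedding) are cosmetic.

```{r templates}
census(cephaloid_dodecahedron())
census(cephaloid_tetradecahedron())
check_zygomorphy(cephaloid_tetradecahedron())
```

## The in-silico putty experiment

### Packing

`build_1661_cluster()` seeds the fourteen outer spheroids geometrically
(axial singletons, two staggered six-rings at polar angle 60 and 120
degrees) and relaxes with a deterministic position-based scheme: batch
resolution of pairwise overlaps plus projection of every outer spheroid
onto the central-contact shell. Inter-spheroid distance uses a centre-line
surface approximation (the gap along the centre-centre line against both
spheroid surfaces, relative to the sum of the two surface radii); the
contact tolerance (default 0.02 relative) absorbs the approximation error.
All fourteen outer spheroids end in central contact; ring neighbours retain
slight overlaps, as soft putty would. The six-ring cannot simultaneously
touch the centre and be overlap-free — the relaxation's equilibrium
reflects a genuinely jammed packing, not a numerical failure.

### Deformation

A global linear taper of transverse coordinates — the simplest reading of
"anterior narrowing" — cannot reproduce the putty's rearrangement when the
spheroids are rigid: the six-ring is jammed, so a pure pinch is undone by
overlap resolution, and the prefrontal pair can only meet once the
medial-nasal spheroid has been expelled antero-ventrally out of the ring
(as the deformable putty does spontaneously). The deformation is therefore
modelled as a *calibrated strain program*: a per-region displacement field
composed of four named motions,

* **anterior traction** — the front of the cluster, most strongly its
  ventral (jaw) portion, is drawn rostrally;
* **dorsal midline convergence** — the dorso-anterior spheroids swing
  azimuthally toward the sagittal plane (the convergent-extension
  narrowing; it squeezes the medial-nasal spheroid forward and down);
* **rostral descent** — the medial-nasal spheroid drops toward the snout
  tip, wedging the two premandibulars apart (the analogue of nasal-placode
  migration);
* **dorsoventral flattening** — the whole cluster flattens, seating the
  apical spheroids on the rings.

The endpoint of the program was calibrated once, by constrained
optimisation over mirror-symmetric configurations of fourteen identical
spheroids, to the unique contact pattern in which every facet-adjacent
region pair of the dodecahedron rests in shallow surface contact and every
pair that shares only a polyhedron vertex keeps a clear margin (relative
gap at least 0.08, four times the contact tolerance). That such a
configuration exists is itself a nontrivial geometric fact the package
establishes; the calibrated coordinates are part of the model definition
(`cephaloid:::ce_endpoint`). The protocol scalars `stretch` (anterior
elongation, nominal 1.36) and `pinch` (transverse dorsal narrowing, nominal
0.38) scale the longitudinal/vertical and transverse components of the
program, so `stretch = 1, pinch = 0` is the identity and stretching without
pinching is a true negative control: it never creates the prefrontal
contact.

The program is applied incrementally (20 increments by default) under a
position-based relaxation that supplies the material behaviour:

* overlapping spheroids push apart along their centre line;
* *adhesion bonds* — every initial contact — hold neighbours together in
  tension until the relative gap exceeds a tear threshold (0.025), after
  which the interface is torn and never re-fuses (torn putty surfaces do
  not re-join without pressure); new bonds form on first touch
  (gap ≤ 0.005);
* the central spheroid acts as a deforming incompressible core: its
  semi-axes follow the imposed strain, it supports the shell from inside
  but can be squashed (tension-free).

Fusions are prescribed by label, as in the hand-built model: the left and
right anterolateral lower pairs (premandibular + maxillomandibular) merge
once in contact, reducing fourteen outer regions to twelve. The prescribed
new contact between the two lateral-nasal (prefrontal) spheroids is
asserted after deformation. The returned region-adjacency graph is the
plain geometric contact graph of the deformed cluster at the contact
tolerance — the calibrated margins make it insensitive to the seed jitter,
so the pipeline's headline property (region graph isomorphic, respecting
anatomical roles, to the dodecahedron's facet-adjacency graph, with the
mandibular spheroid on the basal facet) holds across seeds.

```{r pipeline, eval = FALSE}
res <- convergent_extension(build_1661_cluster(), strain_protocol())
res$n_regions                      # 12
match_to_dodecahedron(res)$mapping["mandibular"]   # "basal"
```

## The planar construction

The kite-shaped basal perimeter has its own two-dimensional rationale:
six rigid strips forming a regular hexagon (the perimeter of six-around-one
hexagonal packing), with the two caudal edges immobilized, fold under a
rostral pull into a kite whose two anterior edges are exactly twice the
strip length (two strips turned collinear). The construction is closed
form — the model fixes the endpoint, not the pulling trajectory — with the
lateral vertices kept at their hexagon positions (they belong to the
immobilized edges). Perimeter is conserved exactly, and the in-plane
two-fold symmetry axes drop from the hexagon's six to the kite's single
axis; axes are detected by testing candidate axes through the centroid and
every vertex and edge midpoint at a relative tolerance of 1e-9
(closed-form inputs need no looser setting).

## Matching and scoring

Specimen observations are element subsets of a template (facets, vertices,
edges), never including the basal facet, which is the only element hidden
in dorsal view: of the tetradecahedron's 64 elements, 63 are visible. The
identification score weights all element classes equally —
|identified ∩ visible| / |visible| — so an observation missing exactly the
edge joining the caudal-most vertex to the caudal-most heptagon vertex
(the one edge not readily apparent on flatback specimens) scores
62/63 ≈ 0.984. Scoring is presence/absence only; a present but mis-shaped
element counts as identified. Graph matching (region graphs against
template facet graphs) is vertex-coloured VF2 with degree and/or role
colours; role labels participate only when both graphs carry complete
labels, so anonymous observations fall back to degree-labelled matching.

## Synthetic data

Three generators emulate the study's inputs so that every stage is
testable without external data: `perturbed_cluster()` (isotropic Gaussian
jitter of spheroid centres; dropout-free analogue of hand placement
error), `random_observation()` (independent per-element dropout per class —
the simplest null for "not readily apparent" elements; no spatial
correlation), and `random_sphere_complex()` (convex hulls of uniform
spherical point samples: triangulated sphere-like complexes for
property-testing the operators and the matcher). All are seed-determined.
What passing tests on these generators do *not* show: real specimen
annotation errors are certainly spatially correlated (a blurred region
hides neighbouring edges together), and real hatchling scute patterns vary
in ways the fixed templates do not capture (the package models the modal
morphotype only).

## Numerical choices and problem sizes

* Contact tolerance 0.02 relative, tear 0.025, bond formation 0.005:
  ordered so that held contacts (≈0), newly formed contacts (≤0.005) and
  torn interfaces (≥0.08 at the endpoint) are separated by wide margins.
* Relaxation: 20 increments of 15 iterations, displacement weights 0.3
  (overlap and bond), 0.25 (strain guidance), 0.5 (core support) — chosen
  for smooth convergence of the guided trajectory; the result is
  deterministic given cluster, protocol and seed.
* Seeds only perturb the initial symmetry-breaking jitter (relative
  magnitude 1e-3); robustness across seeds is part of the test suite
  (at least 18 of 20 seeds must reach the dodecahedral pattern; in
  practice all 20 do).
* Test-suite problem sizes: random sphere complexes with up to 16 points,
  exhaustive-permutation isomorphism oracles up to 8 nodes, Monte-Carlo
  observation means at 600 draws — all chosen as the smallest sizes at
  which the checked properties are non-trivial.

## Known limitations

* The spheroids are rigid; all deformability is carried by the
  displacement program, the adhesion bonds and the squashable core. No
  viscoelastic rheology, surface-energy minimisation or tissue-mechanics
  PDE is modelled, and the densest-packing literature result for oblate
  spheroids is taken as a starting arrangement, not re-derived.
* Convexity of the polyhedral templates is an assumption tracked
  combinatorially, not certified geometrically (no rigidity or curvature
  computation).
* The T1 operator implements only the edge-formation half of the foam
  neighbour exchange; the collapse half exists solely as a test oracle.
* Whether the prefrontal contact arises from narrowing, proliferation or
  both is left open by the biology; only narrowing is modelled.
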