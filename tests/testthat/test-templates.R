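test_that("cephaloid templates satisfy their structural constraints", {
  d <- cephaloid_dodecahedron()
  i <- intermediate_dodecahedron()
  t <- cephaloid_tetradecahedron()

  expect_identical(census(d)$total, 50L)   # 12 + 14 + 24
  expect_identical(census(i)$histogram, c("4" = 10L, "5" = 2L))
  expect_identical(c(census(i)$V, census(i)$E), c(15L, 25L))
  expect_identical(census(t)$total, 64L)
  expect_identical(unname(census(t)$histogram["7"]), 1L)

  ## zygomorphy: the left/right relabelling is an automorphism
  expect_true(check_zygomorphy(d))
  expect_true(check_zygomorphy(i))
  expect_true(check_zygomorphy(t))

  ## frontal and frontoparietal share one tetravalent vertex in the
  ## dodecahedron, and an edge (the T1 edge) thereafter
  expect_identical(shared_tetravalent_vertex(d, "frontal", "frontoparietal"),
                   "o")
  expect_false(shared_edge(d, "frontal", "frontoparietal"))
  expect_true(shared_edge(i, "frontal", "frontoparietal"))
  expect_true(shared_edge(t, "frontal", "frontoparietal"))

  ## the two pentagons of the intermediate are the frontal/frontoparietal
  pents <- names(which(facet_degrees(i) == 5L))
  expect_setequal(pents, c("frontal", "frontoparietal"))

  ## frontal stays pentagonal, frontoparietal becomes the lone heptagon
  expect_identical(unname(facet_degrees(t)["frontal"]), 5L)
  expect_identical(unname(facet_degrees(t)["frontoparietal"]), 7L)

  ## quadrilateral kite-shaped base in every template
  for (x in list(d, i, t))
    expect_identical(unname(facet_degrees(x)["basal"]), 4L)
})

test_that("dodecahedron vertex degrees are six tetravalent, eight trivalent", {
  vd <- table(vertex_degrees(cephaloid_dodecahedron()))
  expect_identical(as.integer(vd[c("3", "4")]), c(8L, 6L))
})

test_that("auxiliary solids have their standard censuses", {
  expect_identical(census(poly_cube())$histogram, c("4" = 6L))
  expect_identical(census(poly_tetrahedron())$histogram, c("3" = 4L))
  cs <- census(poly_pentagonal_prism())
  expect_identical(cs$histogram, c("4" = 5L, "5" = 2L))
  expect_identical(cs$F, 7L)
})

test_that("the canonical pathway reproduces the template constants exactly", {
  mv <- canonical_pathway()
  i <- t1_edge_formation(cephaloid_dodecahedron(), mv$t1)
  ref_i <- intermediate_dodecahedron()
  expect_true(same_facet_cycles(i, ref_i))

  t <- bilateral_split(i, mv$left, mv$right)
  ref_t <- cephaloid_tetradecahedron()
  expect_true(same_facet_cycles(t, ref_t))
  expect_identical(t$labels[sort(names(t$labels))],
                   ref_t$labels[sort(names(ref_t$labels))])

  ## and up to label-respecting facet-graph isomorphism
  m <- graph_isomorphic(facet_adjacency(t), facet_adjacency(ref_t),
                        respect_roles = TRUE)
  expect_true(m$isomorphic)
})

test_that("the caudal edge of the heptagon exists (the 62/63 edge)", {
  t <- cephaloid_tetradecahedron()
  ## most caudal vertex 'p' connects to the heptagon's most caudal
  ## vertex 'pn'
  expect_true(edge_id("p", "pn") %in% complex_edges(t)$edge)
  expect_true("pn" %in% t$facets$frontoparietal)
  expect_false("p" %in% t$facets$frontoparietal)
})
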