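test_that("valid complexes are accepted with correct censuses", {
  cube <- poly_cube()
  cs <- census(cube)
  expect_identical(cs$histogram, c("4" = 6L))
  expect_identical(c(cs$F, cs$V, cs$E, cs$total), c(6L, 8L, 12L, 26L))

  tet <- cephaloid_tetradecahedron()
  cs <- census(tet)
  expect_identical(cs$histogram, c("4" = 10L, "5" = 3L, "7" = 1L))
  expect_identical(c(cs$F, cs$V, cs$E, cs$total), c(14L, 19L, 31L, 64L))

  ## all-quadrilateral 12-facet sphere forces E = 24, V = 14
  dode <- cephaloid_dodecahedron()
  cs <- census(dode)
  expect_identical(cs$histogram, c("4" = 12L))
  expect_identical(c(cs$V, cs$E), c(14L, 24L))
})

test_that("each validation failure has its own condition class", {
  sq <- poly_cube()$facets
  expect_error(polyhedral_complex(sq[-1]),            # open box
               class = "cephaloid_nonmanifold_error")
  sq_rev <- sq; sq_rev$top <- rev(sq_rev$top)
  expect_error(polyhedral_complex(sq_rev),
               class = "cephaloid_orientation_error")
  expect_error(polyhedral_complex(list(a = c("1", "2"), b = c("2", "1"),
                                       c = c("1", "2"), d = c("2", "1"))),
               class = "cephaloid_degree_error")
  ## two disjoint tetrahedra: manifold but Euler characteristic 4
  t1 <- poly_tetrahedron()$facets
  t2 <- lapply(t1, function(cyc) paste0(cyc, "x"))
  names(t2) <- paste0(names(t1), "x")
  expect_error(polyhedral_complex(c(t1, t2)),
               class = "cephaloid_euler_error")
})

test_that("handshake identities hold for every accepted complex", {
  for (x in list(poly_cube(), poly_tetrahedron(), poly_pentagonal_prism(),
                 cephaloid_dodecahedron(), intermediate_dodecahedron(),
                 cephaloid_tetradecahedron())) {
    cs <- census(x)
    expect_identical(cs$V - cs$E + cs$F, 2L)
    expect_identical(sum(facet_degrees(x)), 2L * cs$E)
    expect_identical(sum(vertex_degrees(x)), 2L * cs$E)
  }
})

test_that("facet adjacency graphs have the expected structure", {
  ## each cube face touches its four neighbours (the octahedron graph)
  g <- facet_adjacency(poly_cube())
  expect_equal(igraph::vcount(g), 6)
  expect_true(all(igraph::degree(g) == 4))
  expect_equal(igraph::ecount(g), 12)

  g <- facet_adjacency(poly_tetrahedron())
  expect_equal(igraph::ecount(g), 6)  # complete graph on 4 nodes

  g <- facet_adjacency(cephaloid_tetradecahedron())
  expect_equal(igraph::vcount(g), 14)
  expect_equal(igraph::ecount(g), 31)
})

test_that("multi-adjacent facet pairs are rejected as non-simple", {
  ## hand-built (unvalidated) triangular dihedron: both facets share all
  ## three edges
  bad <- structure(list(
    facets = list(A = c("1", "2", "3"), B = c("1", "3", "2")),
    vertices = c("1", "2", "3"),
    labels = c(A = NA_character_, B = NA_character_), coords = NULL),
    class = "polyhedral_complex")
  expect_error(facet_adjacency(bad), class = "cephaloid_multiadjacency_error")
})

test_that("dorsal projection exposes all elements but the basal facet", {
  expect_identical(dorsal_projection(cephaloid_tetradecahedron(),
                                     "basal")$n_visible, 63L)
  expect_identical(dorsal_projection(poly_cube(), "bottom")$n_visible, 25L)
  expect_identical(dorsal_projection(cephaloid_dodecahedron(),
                                     "basal")$n_visible, 49L)
  ## visible count is always total - 1, for any choice of facet
  x <- poly_pentagonal_prism()
  for (f in names(x$facets))
    expect_identical(dorsal_projection(x, f)$n_visible,
                     census(x)$total - 1L)
})

test_that("dorsal projection is a crossing-free straight-line drawing", {
  pr <- dorsal_projection(cephaloid_tetradecahedron(), "basal")
  co <- pr$coords
  ed <- complex_edges(pr$complex)
  segs <- cbind(co[ed$from, , drop = FALSE], co[ed$to, , drop = FALSE])
  crosses <- function(p1, p2, q1, q2) {
    d1 <- p2 - p1; d2 <- q2 - q1
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
    u <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  n <- nrow(segs)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (length(intersect(unlist(ed[i, 2:3]), unlist(ed[j, 2:3])))) next
    expect_false(crosses(segs[i, 1:2], segs[i, 3:4],
                         segs[j, 1:2], segs[j, 3:4]))
  }
})
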