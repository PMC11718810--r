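test_that("T1 edge formation has exact bookkeeping", {
  d <- cephaloid_dodecahedron()
  mv <- t1_move("o", c("frontal", "frontoparietal"))
  out <- t1_edge_formation(d, mv)
  cs0 <- census(d); cs1 <- census(out)
  expect_identical(cs1$F - cs0$F, 0L)
  expect_identical(cs1$V - cs0$V, 1L)
  expect_identical(cs1$E - cs0$E, 1L)
  ## gaining facets +1 degree, separated facets unchanged
  expect_identical(unname(facet_degrees(out)[c("frontal", "frontoparietal")]),
                   c(5L, 5L))
  expect_identical(
    unname(facet_degrees(out)[c("supraocular.L", "supraocular.R")]),
    c(4L, 4L))
  ## separated facets no longer share any vertex
  expect_length(intersect(out$facets$supraocular.L,
                          out$facets$supraocular.R), 0L)
})

test_that("T1 at a square pyramid apex adds one vertex and one edge", {
  pyr <- polyhedral_complex(list(
    base = c("b1", "b4", "b3", "b2"),
    s1 = c("b1", "b2", "apex"), s2 = c("b2", "b3", "apex"),
    s3 = c("b3", "b4", "apex"), s4 = c("b4", "b1", "apex")))
  out <- t1_edge_formation(pyr, t1_move("apex", c("s1", "s3")))
  cs <- census(out)
  expect_identical(c(cs$V, cs$E, cs$F), c(6L, 9L, 5L))
  out2 <- t1_edge_formation(pyr, t1_move("apex", c("s2", "s4")))
  expect_identical(census(out2)$total, census(out)$total)
})

test_that("T1 rejects invalid targets with named errors", {
  d <- cephaloid_dodecahedron()
  expect_error(t1_edge_formation(d, t1_move("n", c("prefrontal.L",
                                                   "prefrontal.R"))),
               class = "cephaloid_t1_degree_error")
  expect_error(
    t1_edge_formation(d, t1_move("o", c("frontal", "supraocular.L"))),
    class = "cephaloid_t1_pair_error")
})

test_that("T1 is inverted by collapsing the new edge (oracle)", {
  d <- cephaloid_dodecahedron()
  out <- t1_edge_formation(d, t1_move("o", c("frontal", "frontoparietal"),
                                      new_vertices = c("u", "v")))
  back <- collapse_edge(out, "u", "v", merged = "o")
  expect_true(same_facet_cycles(back, d))
})

test_that("facet split adds one facet, two vertices, three edges", {
  ## exhaustively over every facet and every edge pair of the templates
  for (x in list(poly_cube(), cephaloid_dodecahedron())) {
    cs0 <- census(x)
    for (f in names(x$facets)) {
      cyc <- x$facets[[f]]
      nxt <- c(cyc[-1], cyc[1])
      edges <- lapply(seq_along(cyc), function(i) c(cyc[i], nxt[i]))
      pairs <- utils::combn(length(edges), 2)
      for (q in seq_len(ncol(pairs))) {
        out <- facet_split(x, split_spec(f, edges[pairs[, q]]))
        cs <- census(out)
        expect_identical(c(cs$F - cs0$F, cs$V - cs0$V, cs$E - cs0$E),
                         c(1L, 2L, 3L))
        ## offspring degrees sum to parent degree + 4
        d_off <- facet_degrees(out)[paste0(f, c(".1", ".2"))]
        expect_identical(sum(d_off), length(cyc) + 4L)
      }
    }
  }
})

test_that("splitting a cube square reproduces pentagonal prism combinatorics", {
  cb <- poly_cube()
  opp <- facet_split(cb, split_spec("top", list(c("e", "f"), c("g", "h"))))
  expect_identical(census(opp)$histogram,
                   census(poly_pentagonal_prism())$histogram)
  expect_identical(census(opp)$F, 7L)
  m <- graph_isomorphic(facet_adjacency(opp),
                        facet_adjacency(poly_pentagonal_prism()))
  expect_true(m$isomorphic)

  adj <- facet_split(cb, split_spec("top", list(c("e", "f"), c("f", "g"))))
  expect_setequal(unname(facet_degrees(adj)[c("top.1", "top.2")]), c(3L, 5L))
  expect_identical(census(adj)$total, census(cb)$total + 6L)
})

test_that("split specs validate their edges", {
  cb <- poly_cube()
  expect_error(split_spec("top", list(c("e", "f"), c("f", "e"))),
               class = "cephaloid_split_edge_error")
  expect_error(facet_split(cb, split_spec("top", list(c("e", "f"),
                                                      c("a", "b")))),
               class = "cephaloid_split_edge_error")
})

test_that("bilateral split enforces mirror symmetry and bookkeeping", {
  i <- intermediate_dodecahedron()
  left <- split_spec("supraocular.L", list(c("oc.L", "ot.L"),
                                           c("or.L", "nl.L")))
  right <- split_spec("supraocular.R", list(c("oc.R", "ot.R"),
                                            c("or.R", "nl.R")))
  out <- bilateral_split(i, left, right)
  cs0 <- census(i); cs <- census(out)
  expect_identical(c(cs$F - cs0$F, cs$V - cs0$V, cs$E - cs0$E),
                   c(2L, 4L, 6L))
  expect_identical(unname(facet_degrees(out)["frontoparietal"]), 7L)

  wrong <- split_spec("supraocular.R", list(c("oc.R", "ot.R"),
                                            c("nl.R", "oc.R")))
  expect_error(bilateral_split(i, left, wrong),
               class = "cephaloid_mirror_error")
})

test_that("Euler characteristic is invariant under both foam operators", {
  for (seed in 1:5) {
    x <- random_sphere_complex(10, seed = seed)
    cs <- census(x)
    expect_identical(cs$V - cs$E + cs$F, 2L)
    f <- names(x$facets)[1L]
    cyc <- x$facets[[f]]
    sp <- split_spec(f, list(c(cyc[1], cyc[2]), c(cyc[2], cyc[3])))
    y <- facet_split(x, sp)
    csy <- census(y)
    expect_identical(csy$V - csy$E + csy$F, 2L)
    expect_identical(csy$total, cs$total + 6L)
    ## T1 at any tetravalent vertex, if one exists
    v4 <- names(which(vertex_degrees(x) == 4L))
    if (length(v4)) {
      ring <- cephaloid:::facets_around_vertex(x, v4[1])
      z <- t1_edge_formation(x, t1_move(v4[1], ring[c(1, 3)]))
      csz <- census(z)
      expect_identical(csz$V - csz$E + csz$F, 2L)
    }
  }
})

test_that("region fusion merges adjacent regions and unions neighbours", {
  tri <- igraph::make_graph(~ A - B, B - C, C - A)
  out <- region_fusion(tri, c("A", "B"))
  expect_equal(igraph::vcount(out), 2)
  expect_equal(igraph::ecount(out), 1)
  expect_true("A+B" %in% igraph::V(out)$name)

  ## the 14-region cluster graph drops to 12 after the two prescribed
  ## anterolateral fusions
  cl <- build_1661_cluster()
  g <- contact_graph(cl)
  g <- igraph::delete_vertices(g, which(igraph::V(g)$name == "central"))
  g <- region_fusion(g, c("premandibular.L", "maxillomandibular.L"))
  g <- region_fusion(g, c("premandibular.R", "maxillomandibular.R"))
  expect_equal(igraph::vcount(g), 12)

  ## fusing everything leaves one region and no edges
  h <- igraph::make_full_graph(4)
  igraph::V(h)$name <- letters[1:4]
  while (igraph::vcount(h) > 1L) {
    e <- igraph::as_edgelist(h)[1L, ]
    h <- region_fusion(h, e)
  }
  expect_equal(igraph::vcount(h), 1)
  expect_equal(igraph::ecount(h), 0)

  expect_error(region_fusion(igraph::make_graph(~ A - B, C - D),
                             c("A", "C")),
               class = "cephaloid_fusion_error")
})

test_that("T1-then-split and split-then-T1 give isomorphic tetradecahedra", {
  d <- cephaloid_dodecahedron()
  mv <- canonical_pathway()
  t_first <- bilateral_split(t1_edge_formation(d, mv$t1), mv$left, mv$right)

  ## split the dodecahedral supraoculars first (split points on the
  ## frontoparietal- and prefrontal-shared edges), then T1 at 'o'
  s_left <- split_spec("supraocular.L", list(c("oc.L", "o"),
                                             c("or.L", "nl.L")))
  s_right <- split_spec("supraocular.R", list(c("oc.R", "o"),
                                              c("or.R", "nl.R")))
  s <- facet_split(facet_split(d, s_left), s_right)
  s_first <- t1_edge_formation(s, t1_move("o", c("frontal",
                                                 "frontoparietal")))
  expect_identical(census(s_first)$histogram, census(t_first)$histogram)
  ## offspring labels mirror-swap on the right, so match structure only
  m <- graph_isomorphic(facet_adjacency(s_first), facet_adjacency(t_first),
                        respect_roles = FALSE)
  expect_true(m$isomorphic)
})
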