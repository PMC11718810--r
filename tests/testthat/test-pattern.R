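test_that("visible elements omit only the basal facet", {
  expect_identical(visible_elements(cephaloid_tetradecahedron(),
                                    "basal")$n, 63L)
  expect_identical(visible_elements(poly_cube(), "bottom")$n, 25L)
  expect_identical(visible_elements(intermediate_dodecahedron(),
                                    "basal")$n, 51L)
  expect_error(visible_elements(poly_cube(), "nope"))
})

test_that("identification score reproduces the 62/63 benchmark", {
  tet <- cephaloid_tetradecahedron()
  obs <- full_observation(tet, "basal")
  expect_equal(identification_score(tet, "basal", obs)$score, 1)

  ## drop exactly the edge from the caudal-most vertex to the caudal-most
  ## vertex of the heptagonal frontoparietal facet
  vis <- visible_elements(tet, "basal")
  missing_edge <- edge_id("p", "pn")
  obs62 <- observation_set(tet, facets = vis$facets,
                           vertices = vis$vertices,
                           edges = setdiff(vis$edges, missing_edge))
  sc <- identification_score(tet, "basal", obs62)
  expect_equal(sc$score, 62 / 63)
  expect_equal(round(sc$score, 3), 0.984)
  bd <- sc$breakdown
  expect_identical(bd$identified[bd$class == "edges"], 30L)
  expect_identical(bd$visible[bd$class == "edges"], 31L)
  expect_identical(sc$missing$edges, missing_edge)

  empty <- observation_set(tet)
  expect_equal(identification_score(tet, "basal", empty)$score, 0)
})

test_that("score is monotone as elements are added", {
  tet <- cephaloid_tetradecahedron()
  vis <- visible_elements(tet, "basal")
  ids <- c(vis$facets, vis$vertices, vis$edges)
  classes <- rep(c("facets", "vertices", "edges"),
                 c(length(vis$facets), length(vis$vertices),
                   length(vis$edges)))
  ord <- order(ids)  # deterministic order
  prev <- -1
  sets <- list(facets = character(), vertices = character(),
               edges = character())
  for (i in ord[seq(1, length(ord), by = 7)]) {
    sets[[classes[i]]] <- c(sets[[classes[i]]], ids[i])
    obs <- observation_set(tet, facets = sets$facets,
                           vertices = sets$vertices, edges = sets$edges)
    s <- identification_score(tet, "basal", obs)$score
    expect_gte(s, prev)
    expect_true(s >= 0 && s <= 1)
    prev <- s
  }
})

test_that("observations validate ids and exclude the basal facet", {
  tet <- cephaloid_tetradecahedron()
  expect_error(observation_set(tet, facets = "nonsense"))
  expect_error(observation_set(tet, edges = list(c("p", "o"))))
  expect_error(observation_set(tet, facets = "basal"))
})

test_that("isomorphism matcher agrees with the permutation oracle", {
  for (seed in 1:12) {
    n <- 5 + (seed %% 4)
    g1 <- with_seed(seed, igraph::sample_gnp(n, 0.5))
    igraph::V(g1)$name <- paste0("a", seq_len(n))
    ## isomorphic relabelling
    perm <- with_seed(seed + 100, sample(n))
    g2 <- igraph::permute(g1, perm)
    ## a non-isomorphic variant with the same size where possible
    g3 <- with_seed(seed + 200, igraph::sample_gnp(n, 0.5))
    igraph::V(g3)$name <- paste0("b", seq_len(n))
    expect_true(graph_isomorphic(g1, g2,
                                 respect_degrees = FALSE)$isomorphic)
    expect_identical(graph_isomorphic(g1, g3,
                                      respect_degrees = FALSE)$isomorphic,
                     brute_force_isomorphic(g1, g3))
  }
})

test_that("wheel and prism on six nodes are not isomorphic", {
  wheel <- igraph::make_star(6, mode = "undirected")
  wheel <- igraph::add_edges(wheel, c(2, 3, 3, 4, 4, 5, 5, 6, 6, 2))
  igraph::V(wheel)$name <- paste0("w", 1:6)
  prism <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d,
                              a - d, b - e, c - f)
  expect_false(graph_isomorphic(wheel, prism,
                                respect_degrees = FALSE)$isomorphic)
  expect_false(brute_force_isomorphic(wheel, prism))
})

test_that("matching a template graph against itself finds a role mapping", {
  g <- facet_adjacency(cephaloid_tetradecahedron())
  perm <- with_seed(1, sample(igraph::vcount(g)))
  g2 <- igraph::permute(g, perm)
  m <- graph_isomorphic(g, g2, respect_roles = TRUE)
  expect_true(m$isomorphic)
  ## role-respecting mapping preserves roles
  r1 <- setNames(igraph::V(g)$role, igraph::V(g)$name)
  r2 <- setNames(igraph::V(g2)$role, igraph::V(g2)$name)
  expect_identical(unname(r2[m$mapping]), unname(r1[names(m$mapping)]))

  dd <- facet_adjacency(cephaloid_dodecahedron())
  m2 <- graph_isomorphic(dd, g)
  expect_false(m2$isomorphic)
  expect_match(m2$diagnostic, "size mismatch")
})
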