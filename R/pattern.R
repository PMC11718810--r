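#' Labeled graph isomorphism with a witness mapping
#'
#' Tests whether two region-adjacency graphs are isomorphic, optionally
#' requiring node degrees and/or role labels to correspond. Backed by a
#' vertex-colored VF2 backtracking search; when the graphs match, one
#' witness mapping is returned.
#'
#' @param g1,g2 simple undirected `igraph` objects with a `name` vertex
#'   attribute (and optionally a `role` attribute).
#' @param respect_degrees if TRUE (default), matched nodes must have equal
#'   degree.
#' @param respect_roles if TRUE, matched nodes must carry the same `role`
#'   label; `"auto"` (default) respects roles only when both graphs carry a
#'   complete, non-missing `role` attribute.
#' @return a list with `isomorphic` (logical) and `mapping` (named character
#'   vector from `g1` names to `g2` names, or `NULL`), plus `diagnostic`
#'   (character, a first mismatched adjacency or count when not isomorphic).
#' @export
graph_isomorphic <- function(g1, g2, respect_degrees = TRUE,
                             respect_roles = "auto") {
  stopifnot(inherits(g1, "igraph"), inherits(g2, "igraph"))
  roles1 <- igraph::vertex_attr(g1, "role")
  roles2 <- igraph::vertex_attr(g2, "role")
  have_roles <- !is.null(roles1) && !is.null(roles2) &&
    !anyNA(roles1) && !anyNA(roles2)
  use_roles <- if (identical(respect_roles, "auto")) have_roles
               else isTRUE(respect_roles)
  if (use_roles && !have_roles)
    stop("respect_roles = TRUE but a graph lacks complete 'role' labels")

  if (igraph::vcount(g1) != igraph::vcount(g2) ||
      igraph::ecount(g1) != igraph::ecount(g2)) {
    return(list(isomorphic = FALSE, mapping = NULL,
                diagnostic = sprintf(
                  "size mismatch: %d nodes / %d edges vs %d nodes / %d edges",
                  igraph::vcount(g1), igraph::ecount(g1),
                  igraph::vcount(g2), igraph::ecount(g2))))
  }

  key1 <- key2 <- character(igraph::vcount(g1))
  if (respect_degrees) {
    key1 <- paste0(key1, "d", igraph::degree(g1))
    key2 <- paste0(key2, "d", igraph::degree(g2))
  }
  if (use_roles) {
    key1 <- paste0(key1, "r", roles1)
    key2 <- paste0(key2, "r", roles2)
  }
  lev <- sort(unique(c(key1, key2)))
  col1 <- match(key1, lev)
  col2 <- match(key2, lev)
  if (!identical(sort(col1), sort(col2))) {
    return(list(isomorphic = FALSE, mapping = NULL,
                diagnostic = "node degree/role multisets differ"))
  }

  maps <- igraph::isomorphisms(g1, g2, method = "vf2",
                               vertex.color1 = col1, vertex.color2 = col2)
  if (!length(maps)) {
    return(list(isomorphic = FALSE, mapping = NULL,
                diagnostic = first_adjacency_mismatch(g1, g2, use_roles)))
  }
  m <- as.integer(maps[[1L]])  # m[i]: g1 vertex matched to g2's vertex i
  mapping <- setNames(rep(NA_character_, length(m)), igraph::V(g1)$name)
  mapping[m] <- igraph::V(g2)$name
  list(isomorphic = TRUE, mapping = mapping, diagnostic = NULL)
}

## When both graphs have unique roles, report the first adjacency present in
## one graph (by role pair) but not the other.
first_adjacency_mismatch <- function(g1, g2, use_roles) {
  if (use_roles) {
    r1 <- igraph::vertex_attr(g1, "role")
    r2 <- igraph::vertex_attr(g2, "role")
    if (!anyDuplicated(r1) && !anyDuplicated(r2) && setequal(r1, r2)) {
      ep <- function(g, r) {
        e <- igraph::as_edgelist(g)
        nm <- setNames(r, igraph::V(g)$name)
        apply(cbind(nm[e[, 1]], nm[e[, 2]]), 1,
              function(x) paste(sort(x), collapse = " ~ "))
      }
      e1 <- ep(g1, r1); e2 <- ep(g2, r2)
      only1 <- setdiff(e1, e2); only2 <- setdiff(e2, e1)
      if (length(only1))
        return(sprintf("adjacency %s present only in first graph", only1[1L]))
      if (length(only2))
        return(sprintf("adjacency %s present only in second graph", only2[1L]))
    }
  }
  "no color-respecting isomorphism exists"
}

#' Elements visible in a dorsal projection
#'
#' In the dorsal view through the basal facet, every element of the
#' polyhedron is on display except the interior of the basal facet itself:
#' the basal vertices and edges form the perimeter of the projection. The
#' visible set therefore contains all F-1 non-basal facets, all V vertices
#' and all E edges — one fewer than the total element count.
#'
#' @param x a `polyhedral_complex`.
#' @param basal facet id of the occluded (ventral/basal) facet.
#' @return a list with `facets`, `vertices`, `edges` (character id vectors,
#'   edge ids from [edge_id()]), and `n` (their total).
#' @examples
#' visible_elements(cephaloid_tetradecahedron(), "basal")$n  # 63
#' @export
visible_elements <- function(x, basal) {
  stopifnot(inherits(x, "polyhedral_complex"))
  if (!basal %in% names(x$facets))
    stop(sprintf("unknown basal facet '%s'", basal))
  out <- list(
    facets = setdiff(names(x$facets), basal),
    vertices = x$vertices,
    edges = complex_edges(x)$edge
  )
  out$n <- length(out$facets) + length(out$vertices) + length(out$edges)
  out
}

#' Specimen observation set
#'
#' The subset of a template's elements identified on a specimen (e.g. from a
#' photograph of a hatchling head in dorsal view). All ids must exist in the
#' template; the basal facet is never part of a dorsal observation.
#'
#' @param template a `polyhedral_complex` the observation refers to.
#' @param facets,vertices character vectors of identified facet/vertex ids.
#' @param edges identified edges: either canonical edge ids or a list of
#'   length-2 endpoint vectors.
#' @param basal id of the occluded basal facet (default `"basal"` when that
#'   facet exists).
#' @param specimen free-text specimen identifier.
#' @param note free-text provenance note.
#' @return an object of class `observation_set`.
#' @export
observation_set <- function(template, facets = character(),
                            vertices = character(), edges = character(),
                            basal = if ("basal" %in% names(template$facets))
                              "basal" else NULL,
                            specimen = "", note = "") {
  stopifnot(inherits(template, "polyhedral_complex"))
  if (is.list(edges))
    edges <- vapply(edges, function(e) edge_id(e[1L], e[2L]), "")
  edges <- as.character(edges)
  facets <- as.character(facets); vertices <- as.character(vertices)
  all_edges <- complex_edges(template)$edge
  bad <- c(setdiff(facets, names(template$facets)),
           setdiff(vertices, template$vertices),
           setdiff(edges, all_edges))
  if (length(bad))
    stop(sprintf("observation refers to unknown element '%s'", bad[1L]))
  if (!is.null(basal) && basal %in% facets)
    stop("the basal facet cannot be visible in a dorsal observation")
  structure(list(facets = unique(facets), vertices = unique(vertices),
                 edges = unique(edges), basal = basal,
                 specimen = specimen, note = note),
            class = "observation_set")
}

#' Full dorsal observation of a template
#'
#' Convenience constructor: an observation containing every dorsally visible
#' element of a template.
#'
#' @inheritParams visible_elements
#' @param ... passed on to [observation_set()].
#' @return an `observation_set` scoring 1 against the template.
#' @export
full_observation <- function(x, basal, ...) {
  vis <- visible_elements(x, basal)
  observation_set(x, facets = vis$facets, vertices = vis$vertices,
                  edges = vis$edges, basal = basal, ...)
}

#' Identification success score
#'
#' The fraction of the dorsally visible template elements that were
#' identified on the specimen, with all element classes weighted equally:
#' |identified ∩ visible| / |visible|. The denominator is always the total
#' element count minus one (only the basal facet is occluded).
#'
#' @param template a `polyhedral_complex`.
#' @param basal id of the occluded basal facet.
#' @param obs an [observation_set()] referring to `template`.
#' @return an object of class `identification_score`: list with `score`,
#'   `identified`, `visible`, a per-class breakdown data frame, and the
#'   missing element ids per class.
#' @examples
#' tet <- cephaloid_tetradecahedron()
#' obs <- full_observation(tet, "basal")
#' identification_score(tet, "basal", obs)$score  # 1
#' @export
identification_score <- function(template, basal, obs) {
  stopifnot(inherits(obs, "observation_set"))
  vis <- visible_elements(template, basal)
  hit <- list(
    facets = intersect(obs$facets, vis$facets),
    vertices = intersect(obs$vertices, vis$vertices),
    edges = intersect(obs$edges, vis$edges)
  )
  miss <- list(
    facets = setdiff(vis$facets, obs$facets),
    vertices = setdiff(vis$vertices, obs$vertices),
    edges = setdiff(vis$edges, obs$edges)
  )
  n_vis <- c(facets = length(vis$facets), vertices = length(vis$vertices),
             edges = length(vis$edges))
  n_hit <- vapply(hit, length, 1L)
  breakdown <- data.frame(
    class = names(n_vis), visible = as.integer(n_vis),
    identified = as.integer(n_hit), row.names = NULL
  )
  structure(list(
    score = sum(n_hit) / sum(n_vis),
    identified = sum(n_hit), visible = sum(n_vis),
    breakdown = breakdown, missing = miss
  ), class = "identification_score")
}

#' @export
print.identification_score <- function(x, ...) {
  cat(sprintf("identification score: %d/%d = %.3f\n",
              x$identified, x$visible, x$score))
  for (i in seq_len(nrow(x$breakdown))) {
    b <- x$breakdown[i, ]
    cat(sprintf("  %-9s %d of %d", b$class, b$identified, b$visible))
    ms <- x$missing[[b$class]]
    if (length(ms)) cat("  (missing: ", paste(ms, collapse = ", "), ")",
                        sep = "")
    cat("\n")
  }
  invisible(x)
}
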