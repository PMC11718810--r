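#' T1 move specification
#'
#' Describes the edge-formation half of a foam T1 transition at a tetravalent
#' vertex: the vertex is replaced by a new edge shared by the two declared
#' gaining facets (which each acquire one edge and two new vertices in place
#' of the old one), while the other two facets at the vertex -- the separated
#' pair -- are pushed apart and keep their degree.
#'
#' @param vertex id of the target vertex (must have degree exactly 4).
#' @param gaining character vector of the two facet ids that acquire the new
#'   edge; they must be opposite at the vertex.
#' @param new_vertices optional character vector of length 2 naming the two
#'   new vertices; `new_vertices[1]` is kept by the separated facet that
#'   follows `gaining[1]` in the rotation around the vertex, `new_vertices[2]`
#'   by the other. Defaults to `<vertex>.1`, `<vertex>.2`.
#' @return an object of class `t1_move`.
#' @export
t1_move <- function(vertex, gaining, new_vertices = NULL) {
  stopifnot(length(vertex) == 1L, length(gaining) == 2L)
  structure(list(vertex = as.character(vertex),
                 gaining = as.character(gaining),
                 new_vertices = new_vertices),
            class = "t1_move")
}

#' Apply T1 edge formation
#'
#' Replaces a tetravalent vertex by a new edge between the two gaining
#' facets. Exact bookkeeping: the facet count is unchanged, the vertex count
#' increases by one and the edge count increases by one; each gaining facet's
#' degree grows by one; the separated facets keep their degree and afterwards
#' share no vertex inherited from the target.
#'
#' @param x a `polyhedral_complex`.
#' @param move a [t1_move()].
#' @return the rearranged, re-validated `polyhedral_complex` (coordinates,
#'   if any, are dropped: the operator is combinatorial).
#' @examples
#' d <- cephaloid_dodecahedron()
#' i <- t1_edge_formation(d, t1_move("o", c("frontal", "frontoparietal")))
#' census(i)  # {4:10, 5:2}, V = 15, E = 25
#' @export
t1_edge_formation <- function(x, move) {
  stopifnot(inherits(x, "polyhedral_complex"), inherits(move, "t1_move"))
  v <- move$vertex
  if (!v %in% x$vertices) stop(sprintf("unknown vertex '%s'", v))
  deg <- vertex_degrees(x)[[v]]
  if (deg != 4L)
    stop_cephaloid("cephaloid_t1_degree_error", sprintf(
      "T1 target vertex '%s' has degree %d (must be 4)", v, deg))
  ring <- facets_around_vertex(x, v)
  if (!all(move$gaining %in% ring))
    stop_cephaloid("cephaloid_t1_pair_error", sprintf(
      "gaining facets must be incident to vertex '%s'", v))
  i <- match(move$gaining[1L], ring)
  ring <- c(ring[i:4L], ring[seq_len(i - 1L)])  # rotate: gaining[1] first
  if (ring[3L] != move$gaining[2L])
    stop_cephaloid("cephaloid_t1_pair_error", sprintf(
      "gaining facets %s and %s are not opposite at vertex '%s'",
      move$gaining[1L], move$gaining[2L], v))
  g1 <- ring[1L]; A <- ring[2L]; g2 <- ring[3L]; B <- ring[4L]

  nv <- move$new_vertices
  if (is.null(nv)) nv <- paste0(v, c(".1", ".2"))
  if (any(nv %in% x$vertices) || nv[1L] == nv[2L])
    stop("new vertex names clash with existing vertices")
  va <- nv[1L]; vb <- nv[2L]

  facets <- x$facets
  sub_one <- function(cyc, repl) {
    i <- match(v, cyc)
    append(cyc[-i], repl, after = i - 1L)
  }
  facets[[A]] <- sub_one(facets[[A]], va)
  facets[[B]] <- sub_one(facets[[B]], vb)
  facets[[g1]] <- sub_one(facets[[g1]], c(vb, va))
  facets[[g2]] <- sub_one(facets[[g2]], c(va, vb))
  polyhedral_complex(facets, labels = x$labels[!is.na(x$labels)])
}

#' Facet split specification
#'
#' An edge-interior facet split: a chord is drawn between new vertices placed
#' in the interiors of two distinct boundary edges of the target facet,
#' dividing it into two offspring facets. The split adds exactly one facet,
#' two vertices and three edges, and each neighbouring facet across a chosen
#' edge gains one degree.
#'
#' @param facet id of the facet to split.
#' @param edges list of two edges of that facet, each either a length-2
#'   character vector of endpoints or a canonical edge id (`"u--v"`).
#' @param positions numeric length 2 in (0,1): split-point position along each
#'   edge. Combinatorially irrelevant (it would only affect an embedding);
#'   kept for interface completeness.
#' @param new_vertices optional names for the two split-point vertices
#'   (in the order of `edges`).
#' @param new_facets optional names for the two offspring facets:
#'   `new_facets[1]` is the offspring reached walking forward (in facet
#'   orientation) from the first split point to the second.
#' @param new_labels optional role labels for the two offspring facets, in
#'   the same order as `new_facets`; default derives them from the target's
#'   role as `<role>.1` and `<role>.2`.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(facet, edges, positions = c(0.5, 0.5),
                       new_vertices = NULL, new_facets = NULL,
                       new_labels = NULL) {
  stopifnot(length(facet) == 1L, length(edges) == 2L,
            all(positions > 0 & positions < 1))
  edges <- lapply(edges, function(e) {
    if (length(e) == 1L) e <- strsplit(e, "--", fixed = TRUE)[[1L]]
    sort(as.character(e))
  })
  if (identical(edges[[1L]], edges[[2L]]))
    stop_cephaloid("cephaloid_split_edge_error",
                   "the two split edges must be distinct")
  structure(list(facet = as.character(facet), edges = edges,
                 positions = positions, new_vertices = new_vertices,
                 new_facets = new_facets, new_labels = new_labels),
            class = "split_spec")
}

#' Apply an edge-interior facet split
#'
#' @param x a `polyhedral_complex`.
#' @param spec a [split_spec()].
#' @return the re-validated `polyhedral_complex` with one more facet, two more
#'   vertices and three more edges.
#' @examples
#' cb <- poly_cube()
#' sp <- split_spec("top", list(c("e", "f"), c("g", "h")))
#' census(facet_split(cb, sp))  # pentagonal-prism census {4:5, 5:2}
#' @export
facet_split <- function(x, spec) {
  stopifnot(inherits(x, "polyhedral_complex"), inherits(spec, "split_spec"))
  f <- spec$facet
  if (!f %in% names(x$facets)) stop(sprintf("unknown facet '%s'", f))
  cyc <- x$facets[[f]]
  d <- length(cyc)
  nxt <- c(cyc[-1L], cyc[1L])
  boundary <- edge_id(cyc, nxt)
  want <- vapply(spec$edges, function(e) edge_id(e[1L], e[2L]), "")
  pos <- match(want, boundary)
  if (anyNA(pos))
    stop_cephaloid("cephaloid_split_edge_error", sprintf(
      "edge %s is not on the boundary of facet '%s'", want[is.na(pos)][1L], f))

  nv <- spec$new_vertices
  if (is.null(nv)) {
    stem <- paste0(f, ".s")
    nv <- paste0(stem, 1:2)
  }
  if (any(nv %in% x$vertices) || nv[1L] == nv[2L])
    stop("new vertex names clash with existing vertices")
  nf <- spec$new_facets
  if (is.null(nf)) nf <- paste0(f, c(".1", ".2"))
  if (any(nf %in% names(x$facets)) || nf[1L] == nf[2L])
    stop("new facet names clash with existing facets")

  facets <- x$facets
  ## insert the split vertices into the neighbour facets (which gain degree 1)
  for (k in 1:2) {
    u <- cyc[pos[k]]; w <- nxt[pos[k]]
    neigh <- NULL
    for (g in names(facets)) {
      if (g == f) next
      gc <- facets[[g]]
      gn <- c(gc[-1L], gc[1L])
      hit <- which(gc == w & gn == u)  # opposite traversal w -> u
      if (length(hit)) { neigh <- g; break }
    }
    facets[[neigh]] <- append(facets[[neigh]], nv[k], after = hit)
  }

  ## walk the target cycle between the two split points
  seg_forward <- function(from_pos, to_pos) {
    idx <- from_pos + 1L
    out <- character(0)
    while (TRUE) {
      j <- ((idx - 1L) %% d) + 1L
      out <- c(out, cyc[j])
      if (j == to_pos) break
      idx <- idx + 1L
    }
    out
  }
  off1 <- c(nv[1L], seg_forward(pos[1L], pos[2L]), nv[2L])
  off2 <- c(nv[2L], seg_forward(pos[2L], pos[1L]), nv[1L])
  facets[[f]] <- NULL
  facets[[nf[1L]]] <- off1
  facets[[nf[2L]]] <- off2

  labels <- x$labels[!is.na(x$labels)]
  labels <- labels[names(labels) != f]
  role <- x$labels[[f]]
  nl <- spec$new_labels
  if (is.null(nl) && !is.na(role)) nl <- paste0(role, c(".1", ".2"))
  if (!is.null(nl)) labels <- c(labels, setNames(nl, nf))
  polyhedral_complex(facets, labels = labels)
}

#' Bilateral (mirror-image) facet splitting
#'
#' Applies two facet splits that are mirror images under a declared
#' left/right map, as in the supraocular split that turns the intermediate
#' dodecahedron into the cephaloid tetradecahedron. Bookkeeping: two new
#' facets, four new vertices, six new edges.
#'
#' @param x a `polyhedral_complex`.
#' @param left,right [split_spec()] objects; `right` must be the image of
#'   `left` under `mirror` (facet id and both edges), otherwise
#'   `cephaloid_mirror_error` is raised.
#' @param mirror a function mapping ids to their mirror images
#'   (default [mirror_lr()]).
#' @return the re-validated `polyhedral_complex`.
#' @examples
#' i <- intermediate_dodecahedron()
#' left <- split_spec("supraocular.L",
#'                    list(c("oc.L", "ot.L"), c("or.L", "nl.L")))
#' right <- split_spec("supraocular.R",
#'                     list(c("oc.R", "ot.R"), c("or.R", "nl.R")))
#' census(bilateral_split(i, left, right))  # {4:10, 5:3, 7:1}
#' @export
bilateral_split <- function(x, left, right, mirror = mirror_lr) {
  stopifnot(inherits(left, "split_spec"), inherits(right, "split_spec"))
  ok <- identical(mirror(left$facet), right$facet) &&
    all(mapply(function(a, b) setequal(mirror(a), b),
               left$edges, right$edges))
  if (!ok)
    stop_cephaloid("cephaloid_mirror_error",
                   "left and right split specs are not mirror images")
  facet_split(facet_split(x, left), right)
}

#' Fuse two adjacent regions of a region-adjacency graph
#'
#' Merges two adjacent regions into one; the merged region is adjacent to the
#' union of the neighbours of the pair (minus the pair itself) and its name
#' is the two names joined by `"+"`.
#'
#' @param g an `igraph` region-adjacency graph with a `name` vertex
#'   attribute.
#' @param pair character vector of two region names; they must be adjacent
#'   (`cephaloid_fusion_error` otherwise).
#' @return the fused `igraph`.
#' @export
region_fusion <- function(g, pair) {
  stopifnot(inherits(g, "igraph"), length(pair) == 2L)
  nm <- igraph::V(g)$name
  idx <- match(pair, nm)
  if (anyNA(idx)) stop(sprintf("unknown region '%s'", pair[is.na(idx)][1L]))
  if (!igraph::are_adjacent(g, idx[1L], idx[2L]))
    stop_cephaloid("cephaloid_fusion_error", sprintf(
      "regions %s and %s are not adjacent", pair[1L], pair[2L]))
  mapping <- seq_along(nm)
  mapping[idx[2L]] <- idx[1L]
  mapping <- match(mapping, sort(unique(mapping)))
  g2 <- igraph::contract(g, mapping, vertex.attr.comb = list(
    name = function(v) paste(v, collapse = "+"), "first"))
  igraph::simplify(g2, remove.multiple = TRUE, remove.loops = TRUE)
}
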