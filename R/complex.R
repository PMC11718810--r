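#' @importFrom stats setNames
NULL

stop_cephaloid <- function(subclass, message, ...) {
  cond <- structure(
    class = c(subclass, "cephaloid_validation_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' Canonical edge identifier
#'
#' Edges are unordered vertex pairs; their identifier is the two vertex ids
#' sorted and joined by `"--"` (which is therefore forbidden inside vertex
#' ids).
#'
#' @param u,v vertex ids (character, recycled pairwise).
#' @return character vector of edge ids.
#' @export
edge_id <- function(u, v) {
  swap <- u > v
  lo <- ifelse(swap, v, u)
  hi <- ifelse(swap, u, v)
  paste(lo, hi, sep = "--")
}

directed_edges <- function(facets) {
  out <- lapply(names(facets), function(f) {
    cyc <- facets[[f]]
    cbind(facet = f, from = cyc, to = c(cyc[-1], cyc[1]))
  })
  do.call(rbind, out)
}

canonical_rotation <- function(cyc) {
  i <- which(cyc == min(cyc))[1L]
  if (i == 1L) cyc else c(cyc[i:length(cyc)], cyc[seq_len(i - 1L)])
}

#' Build a validated polyhedral complex
#'
#' A polyhedral complex is a closed orientable sphere-like surface given
#' combinatorially: each facet is a cyclic sequence of vertex ids, all facets
#' oriented consistently (every edge is traversed once in each direction by
#' its two incident facets).
#'
#' Validation enforces, with a distinct condition class for each failure:
#' \itemize{
#'   \item every edge lies in exactly two facets
#'     (`cephaloid_nonmanifold_error`);
#'   \item the two traversals of every edge are opposite
#'     (`cephaloid_orientation_error`);
#'   \item every facet and every vertex has degree at least 3
#'     (`cephaloid_degree_error`);
#'   \item the Euler characteristic V - E + F equals 2
#'     (`cephaloid_euler_error`).
#' }
#'
#' @param facets list of character vectors, each a facet's cyclic vertex
#'   sequence. Names become facet ids (unnamed facets are named `F1`, `F2`,
#'   ...). Cycles are stored in a canonical rotation (lexicographically
#'   smallest vertex first) so equality of complexes is well defined.
#' @param labels optional named character vector mapping facet ids to role
#'   labels (e.g. `"frontal"`, `"basal"`).
#' @param coords optional numeric matrix of 3D vertex coordinates with row
#'   names matching vertex ids. All combinatorial computation ignores it.
#' @return an object of class `polyhedral_complex` with components
#'   `facets`, `vertices`, `labels`, `coords`.
#' @examples
#' cube <- polyhedral_complex(list(
#'   bottom = c("a", "b", "c", "d"), top = c("e", "h", "g", "f"),
#'   front  = c("a", "e", "f", "b"), right = c("b", "f", "g", "c"),
#'   back   = c("c", "g", "h", "d"), left  = c("d", "h", "e", "a")
#' ))
#' census(cube)
#' @export
polyhedral_complex <- function(facets, labels = NULL, coords = NULL) {
  if (!is.list(facets) || length(facets) < 4L)
    stop_cephaloid("cephaloid_degree_error",
                   "a closed surface needs at least 4 facets")
  if (is.null(names(facets)))
    names(facets) <- paste0("F", seq_along(facets))
  if (anyDuplicated(names(facets)))
    stop_cephaloid("cephaloid_nonmanifold_error", "duplicate facet ids")
  facets <- lapply(facets, as.character)
  if (any(vapply(facets, length, 1L) < 3L))
    stop_cephaloid("cephaloid_degree_error", "facet degree < 3")
  if (any(grepl("--", unlist(facets), fixed = TRUE)))
    stop_cephaloid("cephaloid_orientation_error",
                   "vertex ids must not contain '--' (reserved for edge ids)")
  if (any(vapply(facets, anyDuplicated, 1L) > 0L))
    stop_cephaloid("cephaloid_degree_error",
                   "facet visits a vertex more than once")
  facets <- lapply(facets, canonical_rotation)

  de <- directed_edges(facets)
  und <- edge_id(de[, "from"], de[, "to"])
  cnt <- table(und)
  if (any(cnt != 2L)) {
    bad <- names(cnt)[cnt != 2L][1L]
    stop_cephaloid("cephaloid_nonmanifold_error", sprintf(
      "edge %s lies in %d facet traversals (expected 2)", bad, cnt[[bad]]))
  }
  dir_key <- paste(de[, "from"], de[, "to"], sep = "\r")
  if (anyDuplicated(dir_key)) {
    bad <- de[duplicated(dir_key), , drop = FALSE][1L, ]
    stop_cephaloid("cephaloid_orientation_error", sprintf(
      "edge %s--%s traversed twice in the same direction (a facet is reversed)",
      bad[["from"]], bad[["to"]]))
  }

  vertices <- sort(unique(unlist(facets, use.names = FALSE)))
  V <- length(vertices)
  E <- length(cnt)
  F <- length(facets)
  vdeg <- table(de[, "from"])
  if (any(vdeg < 3L))
    stop_cephaloid("cephaloid_degree_error", sprintf(
      "vertex %s has degree %d (< 3)",
      names(vdeg)[vdeg < 3L][1L], min(vdeg)))
  if (V - E + F != 2L)
    stop_cephaloid("cephaloid_euler_error", sprintf(
      "Euler characteristic V - E + F = %d - %d + %d = %d (expected 2)",
      V, E, F, V - E + F))

  lab <- setNames(rep(NA_character_, F), names(facets))
  if (!is.null(labels)) {
    unknown <- setdiff(names(labels), names(facets))
    if (length(unknown))
      stop_cephaloid("cephaloid_nonmanifold_error", sprintf(
        "labels refer to unknown facet '%s'", unknown[1L]))
    lab[names(labels)] <- unname(labels)
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (is.null(rownames(coords)) || !all(vertices %in% rownames(coords)))
      stop("coords must have row names covering all vertex ids")
    coords <- coords[vertices, , drop = FALSE]
  }
  structure(
    list(facets = facets, vertices = vertices, labels = lab, coords = coords),
    class = "polyhedral_complex"
  )
}

#' @export
print.polyhedral_complex <- function(x, ...) {
  cs <- census(x)
  cat(sprintf("<polyhedral_complex> F=%d V=%d E=%d (total %d elements)\n",
              cs$F, cs$V, cs$E, cs$total))
  hist <- paste(sprintf("%s-gon:%d", names(cs$histogram), cs$histogram),
                collapse = ", ")
  cat("  facet degrees:", hist, "\n")
  roles <- x$labels[!is.na(x$labels)]
  if (length(roles))
    cat("  roles:", paste(sprintf("%s=%s", names(roles), roles),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.polyhedral_complex <- function(x, ...) {
  cs <- census(x)
  sprintf("polyhedral_complex(F=%d, V=%d, E=%d)", cs$F, cs$V, cs$E)
}

#' Edges of a complex
#'
#' @param x a `polyhedral_complex`.
#' @return a data.frame with columns `edge` (canonical id), `from`, `to`
#'   (endpoints, sorted), one row per undirected edge.
#' @export
complex_edges <- function(x) {
  stopifnot(inherits(x, "polyhedral_complex"))
  de <- directed_edges(x$facets)
  ids <- unique(edge_id(de[, "from"], de[, "to"]))
  parts <- strsplit(ids, "--", fixed = TRUE)
  data.frame(
    edge = ids,
    from = vapply(parts, `[`, "", 1L),
    to = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
}

#' Facet and vertex degrees
#'
#' @param x a `polyhedral_complex`.
#' @return named integer vector.
#' @export
facet_degrees <- function(x) {
  stopifnot(inherits(x, "polyhedral_complex"))
  vapply(x$facets, length, 1L)
}

#' @rdname facet_degrees
#' @export
vertex_degrees <- function(x) {
  stopifnot(inherits(x, "polyhedral_complex"))
  de <- directed_edges(x$facets)
  tab <- table(de[, "from"])
  setNames(as.integer(tab), names(tab))[x$vertices]
}

#' Element census of a polyhedral complex
#'
#' Counts facets by degree and reports V, E, F and the total element count
#' F + V + E (the "discrete elements" of the surface).
#'
#' @param x a `polyhedral_complex`.
#' @return an object of class `facet_census`: a list with `histogram`
#'   (facet-degree counts, names are degrees), `F`, `V`, `E`, `total`.
#' @export
census <- function(x) {
  stopifnot(inherits(x, "polyhedral_complex"))
  fd <- facet_degrees(x)
  hist <- table(fd)
  F <- length(x$facets)
  V <- length(x$vertices)
  E <- sum(fd) %/% 2L
  structure(
    list(histogram = setNames(as.integer(hist), names(hist)),
         F = F, V = V, E = E, total = F + V + E),
    class = "facet_census"
  )
}

#' @export
print.facet_census <- function(x, ...) {
  cat(sprintf("facet census: F=%d V=%d E=%d total=%d\n",
              x$F, x$V, x$E, x$total))
  cat(" ", paste(sprintf("{%s: %d}", names(x$histogram), x$histogram),
                 collapse = " "), "\n")
  invisible(x)
}

#' Facet-adjacency graph
#'
#' Nodes are facets (labelled with degree and role); one graph edge per shared
#' polyhedron edge. Templates are required to be simple here: a facet pair
#' sharing two or more polyhedron edges raises
#' `cephaloid_multiadjacency_error`.
#'
#' @param x a `polyhedral_complex`.
#' @return an `igraph` object with vertex attributes `name`, `degree`
#'   (facet degree in the polyhedron) and `role`.
#' @export
facet_adjacency <- function(x) {
  stopifnot(inherits(x, "polyhedral_complex"))
  de <- directed_edges(x$facets)
  eid <- edge_id(de[, "from"], de[, "to"])
  owner <- split(de[, "facet"], eid)
  pairs <- t(vapply(owner, sort, character(2)))
  pk <- paste(pairs[, 1], pairs[, 2], sep = "\r")
  if (anyDuplicated(pk)) {
    bad <- pairs[duplicated(pk), , drop = FALSE][1L, ]
    stop_cephaloid("cephaloid_multiadjacency_error", sprintf(
      "facets %s and %s share more than one edge", bad[1L], bad[2L]))
  }
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  ord <- igraph::V(g)$name
  g <- igraph::set_vertex_attr(g, "degree",
                               value = unname(facet_degrees(x)[ord]))
  igraph::set_vertex_attr(g, "role", value = unname(x$labels[ord]))
}

## Facets around a vertex in consistent rotational order, walking across
## shared edges via the opposite traversal of each outgoing edge.
facets_around_vertex <- function(x, v) {
  de <- directed_edges(x$facets)
  out <- de[de[, "from"] == v, , drop = FALSE]
  if (nrow(out) == 0L) stop(sprintf("unknown vertex '%s'", v))
  succ_facet <- setNames(out[, "facet"], out[, "to"])   # v -> s in facet
  succ_of <- setNames(out[, "to"], out[, "facet"])      # facet -> its s
  inn <- de[de[, "to"] == v, , drop = FALSE]
  facet_in <- setNames(inn[, "facet"], inn[, "from"])   # s -> facet with s->v
  start <- out[1L, "facet"]
  ring <- start
  repeat {
    nxt <- facet_in[[succ_of[[ring[length(ring)]]]]]
    if (nxt == start) break
    ring <- c(ring, nxt)
    if (length(ring) > nrow(out)) stop("vertex link is not a single cycle")
  }
  ring
}
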