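#' Cephaloid polyhedral templates
#'
#' Canonical combinatorial encodings of the three head polyhedra: the
#' twelve-quadrilateral cephaloid dodecahedron, the intermediate dodecahedron
#' in which the frontal and frontoparietal facets have become an edge-sharing
#' pentagon pair, and the cephaloid tetradecahedron with its dorsal
#' pentagon-heptagon pair (ten quadrilaterals, three pentagons, one heptagon;
#' 19 vertices, 31 edges, 64 elements in all).
#'
#' Vertex ids (dorsal view, rostral = up; `.L`/`.R` are the animal's own left
#' and right):
#' \describe{
#'   \item{a}{rostral apex of the basal kite (most anterior midline vertex,
#'     shared by the two temporal facets and the basal facet)}
#'   \item{n}{internasal vertex (rostral end of the prefrontal midline edge)}
#'   \item{f}{frontal apex (caudal end of the prefrontal midline edge)}
#'   \item{o}{interorbital vertex: the tetravalent vertex shared by the
#'     frontal and frontoparietal facets, target of the T1 move}
#'   \item{pn}{parietal notch (frontoparietal/caudal-pair junction)}
#'   \item{p}{caudal apex of the basal kite (the most caudal vertex)}
#'   \item{nl.L, nl.R}{nasolateral (tetravalent)}
#'   \item{or.L, or.R}{orbital-rostral}
#'   \item{oc.L, oc.R}{orbital-caudal (tetravalent)}
#'   \item{j.L, j.R}{jaw corners (lateral vertices of the basal kite)}
#' }
#' The T1 move replaces `o` by the transverse edge `ot.L--ot.R`; the bilateral
#' supraocular splits add `s1.L`/`s1.R` (on the frontoparietal-shared edges)
#' and `s2.L`/`s2.R` (on the prefrontal-shared edges).
#'
#' @return a `polyhedral_complex` with role labels equal to facet ids.
#' @seealso [t1_edge_formation()], [bilateral_split()], [census()]
#' @examples
#' census(cephaloid_tetradecahedron())  # {4:10, 5:3, 7:1}, 64 elements
#' @export
cephaloid_dodecahedron <- function() {
  facets <- list(
    rostral        = c("a", "nl.L", "n", "nl.R"),
    prefrontal.L   = c("n", "nl.L", "or.L", "f"),
    prefrontal.R   = c("n", "f", "or.R", "nl.R"),
    frontal        = c("f", "or.L", "o", "or.R"),
    supraocular.L  = c("oc.L", "o", "or.L", "nl.L"),
    supraocular.R  = c("oc.R", "nl.R", "or.R", "o"),
    frontoparietal = c("o", "oc.L", "pn", "oc.R"),
    temporal.L     = c("nl.L", "a", "j.L", "oc.L"),
    temporal.R     = c("a", "nl.R", "oc.R", "j.R"),
    caudal.L       = c("oc.L", "j.L", "p", "pn"),
    caudal.R       = c("oc.R", "pn", "p", "j.R"),
    basal          = c("j.L", "a", "j.R", "p")
  )
  polyhedral_complex(facets, labels = setNames(names(facets), names(facets)))
}

#' @rdname cephaloid_dodecahedron
#' @export
intermediate_dodecahedron <- function() {
  facets <- list(
    rostral        = c("a", "nl.L", "n", "nl.R"),
    prefrontal.L   = c("n", "nl.L", "or.L", "f"),
    prefrontal.R   = c("n", "f", "or.R", "nl.R"),
    frontal        = c("f", "or.L", "ot.L", "ot.R", "or.R"),
    supraocular.L  = c("oc.L", "ot.L", "or.L", "nl.L"),
    supraocular.R  = c("oc.R", "nl.R", "or.R", "ot.R"),
    frontoparietal = c("ot.L", "oc.L", "pn", "oc.R", "ot.R"),
    temporal.L     = c("nl.L", "a", "j.L", "oc.L"),
    temporal.R     = c("a", "nl.R", "oc.R", "j.R"),
    caudal.L       = c("oc.L", "j.L", "p", "pn"),
    caudal.R       = c("oc.R", "pn", "p", "j.R"),
    basal          = c("j.L", "a", "j.R", "p")
  )
  polyhedral_complex(facets, labels = setNames(names(facets), names(facets)))
}

#' @rdname cephaloid_dodecahedron
#' @export
cephaloid_tetradecahedron <- function() {
  facets <- list(
    rostral         = c("a", "nl.L", "n", "nl.R"),
    prefrontal.L    = c("n", "nl.L", "s2.L", "or.L", "f"),
    prefrontal.R    = c("n", "f", "or.R", "s2.R", "nl.R"),
    frontal         = c("f", "or.L", "ot.L", "ot.R", "or.R"),
    supraocular1.L  = c("s1.L", "ot.L", "or.L", "s2.L"),
    supraocular2.L  = c("oc.L", "s1.L", "s2.L", "nl.L"),
    supraocular1.R  = c("s2.R", "or.R", "ot.R", "s1.R"),
    supraocular2.R  = c("oc.R", "nl.R", "s2.R", "s1.R"),
    frontoparietal  = c("ot.L", "s1.L", "oc.L", "pn", "oc.R", "s1.R", "ot.R"),
    temporal.L      = c("nl.L", "a", "j.L", "oc.L"),
    temporal.R      = c("a", "nl.R", "oc.R", "j.R"),
    caudal.L        = c("oc.L", "j.L", "p", "pn"),
    caudal.R        = c("oc.R", "pn", "p", "j.R"),
    basal           = c("j.L", "a", "j.R", "p")
  )
  polyhedral_complex(facets, labels = setNames(names(facets), names(facets)))
}

#' Auxiliary solids
#'
#' Standard small polyhedra used for worked examples and as operator test
#' beds: the cube (facet splitting of one square into two congruent
#' quadrilaterals yields the combinatorics of the irregular pentagonal
#' prism), the regular tetrahedron, and the pentagonal prism itself.
#'
#' @return a `polyhedral_complex`.
#' @export
poly_cube <- function() {
  polyhedral_complex(list(
    bottom = c("a", "b", "c", "d"),
    top    = c("e", "h", "g", "f"),
    front  = c("a", "e", "f", "b"),
    right  = c("b", "f", "g", "c"),
    back   = c("c", "g", "h", "d"),
    left   = c("d", "h", "e", "a")
  ))
}

#' @rdname poly_cube
#' @export
poly_tetrahedron <- function() {
  polyhedral_complex(list(
    base = c("a", "c", "b"),
    s1   = c("a", "b", "d"),
    s2   = c("b", "c", "d"),
    s3   = c("c", "a", "d")
  ))
}

#' @rdname poly_cube
#' @export
poly_pentagonal_prism <- function() {
  bot <- paste0("b", 1:5)
  top <- paste0("t", 1:5)
  sides <- lapply(1:5, function(i) {
    j <- if (i == 5L) 1L else i + 1L
    c(bot[i], bot[j], top[j], top[i])
  })
  names(sides) <- paste0("side", 1:5)
  polyhedral_complex(c(
    list(bottom = rev(bot), top = top),
    sides
  ))
}

#' Canonical morphogenetic pathway moves
#'
#' The two-step pathway from the cephaloid dodecahedron to the cephaloid
#' tetradecahedron: (1) T1 edge formation at the interorbital tetravalent
#' vertex `o` with the frontal/frontoparietal facets as the gaining pair;
#' (2) bilateral splitting of the supraocular facets, with one split point on
#' each facet's frontoparietal-shared edge (turning that pentagon into the
#' heptagon) and the other on its prefrontal-shared edge. New element names
#' match the template constants, so applying the moves reproduces
#' [intermediate_dodecahedron()] and [cephaloid_tetradecahedron()] exactly.
#'
#' @return a list with components `t1` (a [t1_move()]), `left` and `right`
#'   ([split_spec()]s).
#' @examples
#' mv <- canonical_pathway()
#' x <- t1_edge_formation(cephaloid_dodecahedron(), mv$t1)
#' y <- bilateral_split(x, mv$left, mv$right)
#' census(y)$total  # 64
#' @export
canonical_pathway <- function() {
  list(
    t1 = t1_move("o", c("frontal", "frontoparietal"),
                 new_vertices = c("ot.R", "ot.L")),
    left = split_spec(
      "supraocular.L", list(c("oc.L", "ot.L"), c("or.L", "nl.L")),
      new_vertices = c("s1.L", "s2.L"),
      new_facets = c("supraocular1.L", "supraocular2.L"),
      new_labels = c("supraocular1.L", "supraocular2.L")),
    right = split_spec(
      "supraocular.R", list(c("oc.R", "ot.R"), c("or.R", "nl.R")),
      new_vertices = c("s1.R", "s2.R"),
      new_facets = c("supraocular2.R", "supraocular1.R"),
      new_labels = c("supraocular2.R", "supraocular1.R"))
  )
}

#' Left-right mirror map of the cephaloid templates
#'
#' The zygomorphy (single mirror plane) of every cephaloid template is the
#' involution swapping `.L` and `.R` suffixes on vertex and facet ids and
#' fixing midline ids.
#'
#' @param ids character vector of vertex or facet ids.
#' @return character vector of mirrored ids.
#' @export
mirror_lr <- function(ids) {
  out <- ids
  left <- grepl("\\.L$", ids)
  right <- grepl("\\.R$", ids)
  out[left] <- sub("\\.L$", ".R", ids[left])
  out[right] <- sub("\\.R$", ".L", ids[right])
  out
}

#' Template constraint checks
#'
#' Decidable structural predicates on a complex, used to validate the
#' cephaloid templates against their defining constraints: zygomorphy of the
#' facet-adjacency graph, the tetravalent vertex shared by the frontal and
#' frontoparietal facets, the pentagon-heptagon (or pentagon-pentagon)
#' edge-sharing pair, and the quadrilateral kite-shaped basal facet.
#'
#' @param x a `polyhedral_complex` with role labels.
#' @return `check_zygomorphy()` returns TRUE if the left/right relabelling
#'   `mirror_lr()` is an automorphism of the facet set (facet cycles map onto
#'   facet cycles, orientation reversed, roles respected).
#'   `shared_edge()` returns TRUE if the two named facets share at least one
#'   polyhedron edge. `shared_tetravalent_vertex()` returns the id of a
#'   degree-4 vertex common to both facets, or `NA` if none exists.
#' @export
check_zygomorphy <- function(x) {
  stopifnot(inherits(x, "polyhedral_complex"))
  tgt <- lapply(x$facets, function(cyc) canonical_rotation(rev(mirror_lr(cyc))))
  names(tgt) <- mirror_lr(names(x$facets))
  all(names(tgt) %in% names(x$facets)) &&
    all(mapply(identical, x$facets[names(tgt)], tgt))
}

#' @rdname check_zygomorphy
#' @param f1,f2 facet ids.
#' @export
shared_edge <- function(x, f1, f2) {
  stopifnot(inherits(x, "polyhedral_complex"))
  de <- directed_edges(x$facets)
  e1 <- edge_id(de[de[, "facet"] == f1, "from"], de[de[, "facet"] == f1, "to"])
  e2 <- edge_id(de[de[, "facet"] == f2, "from"], de[de[, "facet"] == f2, "to"])
  length(intersect(e1, e2)) > 0L
}

#' @rdname check_zygomorphy
#' @export
shared_tetravalent_vertex <- function(x, f1, f2) {
  stopifnot(inherits(x, "polyhedral_complex"))
  both <- intersect(x$facets[[f1]], x$facets[[f2]])
  deg <- vertex_degrees(x)
  hit <- both[deg[both] == 4L]
  if (length(hit)) hit[1L] else NA_character_
}

#' Facet id carrying a given role
#'
#' @param x a `polyhedral_complex`.
#' @param role role label to look up.
#' @return facet id (first match) or error if absent.
#' @export
facet_by_role <- function(x, role) {
  stopifnot(inherits(x, "polyhedral_complex"))
  hit <- names(x$labels)[!is.na(x$labels) & x$labels == role]
  if (!length(hit)) stop(sprintf("no facet has role '%s'", role))
  hit[1L]
}
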