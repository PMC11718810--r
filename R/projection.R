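#' Dorsal planar projection of a polyhedral complex
#'
#' Projects a sphere-like complex onto the plane through its basal facet:
#' the basal facet becomes the outer boundary of a planar straight-line
#' drawing (its vertices and edges form the perimeter and remain visible;
#' only the basal facet's interior is hidden), so every element except the
#' basal facet itself is on display — (F-1) + V + E elements in all.
#'
#' The embedding is computed barycentrically (Tutte): the basal cycle is
#' fixed to a convex polygon and every interior vertex is placed at the
#' average of its neighbours, which is crossing-free for the 3-connected
#' planar graphs of valid complexes.
#'
#' @param x a `polyhedral_complex`.
#' @param basal facet id to project through (occluded facet).
#' @return an object of class `dorsal_projection`: list with `coords`
#'   (V x 2 matrix of vertex positions), `visible` (list of facet, vertex
#'   and edge ids as from [visible_elements()]), `n_visible`, `basal`, and
#'   the complex `x`.
#' @examples
#' dorsal_projection(cephaloid_tetradecahedron(), "basal")$n_visible  # 63
#' @export
dorsal_projection <- function(x, basal) {
  stopifnot(inherits(x, "polyhedral_complex"))
  if (!basal %in% names(x$facets))
    stop(sprintf("unknown basal facet '%s'", basal))
  outer <- rev(x$facets[[basal]])   # reversed: seen from outside the page
  k <- length(outer)
  V <- x$vertices
  n <- length(V)
  ang <- pi / 2 + (seq_len(k) - 1L) * 2 * pi / k
  coords <- matrix(NA_real_, n, 2, dimnames = list(V, c("x", "y")))
  coords[outer, ] <- cbind(cos(ang), sin(ang))

  inner <- setdiff(V, outer)
  if (length(inner)) {
    ed <- complex_edges(x)
    A <- matrix(0, n, n, dimnames = list(V, V))
    A[cbind(ed$from, ed$to)] <- 1
    A[cbind(ed$to, ed$from)] <- 1
    deg <- rowSums(A)
    L <- diag(deg[inner], nrow = length(inner)) -
      A[inner, inner, drop = FALSE]
    rhs <- A[inner, outer, drop = FALSE] %*% coords[outer, , drop = FALSE]
    coords[inner, ] <- solve(L, rhs)
  }
  vis <- visible_elements(x, basal)
  structure(list(coords = coords, visible = vis, n_visible = vis$n,
                 basal = basal, complex = x),
            class = "dorsal_projection")
}

#' @export
print.dorsal_projection <- function(x, ...) {
  cat(sprintf(
    "<dorsal_projection> basal facet '%s' occluded; %d of %d elements visible\n",
    x$basal, x$n_visible, x$n_visible + 1L))
  invisible(x)
}

#' @describeIn dorsal_projection plot the projection: edges, vertices and
#'   facet labels (role when present, id otherwise).
#' @param labels draw facet labels (default TRUE).
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.dorsal_projection <- function(x, labels = TRUE, ...) {
  co <- x$coords
  graphics::plot(co, type = "n", asp = 1, axes = FALSE,
                 xlab = "", ylab = "", ...)
  ed <- complex_edges(x$complex)
  graphics::segments(co[ed$from, 1], co[ed$from, 2],
                     co[ed$to, 1], co[ed$to, 2], col = "grey30")
  graphics::points(co, pch = 19, cex = 0.6)
  if (labels) {
    for (f in names(x$complex$facets)) {
      if (f == x$basal) next
      ctr <- colMeans(co[x$complex$facets[[f]], , drop = FALSE])
      lab <- x$complex$labels[[f]]
      if (is.na(lab)) lab <- f
      graphics::text(ctr[1], ctr[2], lab, cex = 0.6, col = "darkred")
    }
  }
  invisible(x)
}
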