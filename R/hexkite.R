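#' Simple 2D polygon
#'
#' A planar polygon given by ordered vertex coordinates (abstract length
#' units). Construction checks simplicity (no two non-adjacent edges
#' intersect) and a minimum of three vertices.
#'
#' @param coords numeric matrix (n x 2) of vertex coordinates in boundary
#'   order.
#' @return an object of class `polygon2d` (the coordinate matrix with class
#'   attribute).
#' @export
polygon2d <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, nrow(coords) >= 3L, is.numeric(coords))
  n <- nrow(coords)
  seg <- function(i) rbind(coords[i, ], coords[if (i == n) 1L else i + 1L, ])
  intersects <- function(p1, p2, q1, q2) {
    d1 <- p2 - p1; d2 <- q2 - q1
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
    u <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  if (n > 3L) {
    for (i in seq_len(n - 2L)) {
      for (j in seq(i + 2L, n)) {
        if (i == 1L && j == n) next  # adjacent around the wrap
        si <- seg(i); sj <- seg(j)
        if (intersects(si[1, ], si[2, ], sj[1, ], sj[2, ]))
          stop("polygon is self-intersecting")
      }
    }
  }
  structure(coords, class = c("polygon2d", "matrix", "array"))
}

#' @rdname polygon2d
#' @param p a `polygon2d`.
#' @return `edge_lengths()`: numeric vector of edge lengths (edge i joins
#'   vertex i to vertex i+1); `perimeter()`: their sum.
#' @export
edge_lengths <- function(p) {
  stopifnot(inherits(p, "polygon2d"))
  nxt <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  sqrt(rowSums((nxt - unclass(p))^2))
}

#' @rdname polygon2d
#' @export
perimeter <- function(p) sum(edge_lengths(p))

#' Regular hexagon in the head orientation convention
#'
#' Six-around-one hexagonal packing gives a regular hexagonal perimeter; the
#' convention here places the anteroposterior axis on +y (rostral up) with
#' one vertex on the +y axis (rostral) and one on the -y axis (caudal) --
#' the caudal vertex is the one shared by the two immobilized caudal edges
#' of the stretching construction.
#'
#' @param edge_length positive edge length (equals the circumradius).
#' @return a `polygon2d` with 6 vertices in counter-clockwise order starting
#'   at the rostral vertex.
#' @export
regular_hexagon <- function(edge_length = 1) {
  if (!is.numeric(edge_length) || length(edge_length) != 1L ||
      edge_length <= 0)
    stop("edge_length must be a positive number")
  ang <- pi / 2 + (0:5) * pi / 3
  polygon2d(edge_length * cbind(cos(ang), sin(ang)))
}

#' Stretch a regular hexagon into a kite
#'
#' Models convergent extension on a hexagonal packing perimeter built from
#' six rigid strips: the two edges meeting at the caudal vertex are
#' immobilized; a rostral pull along the anteroposterior axis rotates each
#' remaining pair of strips into a straight line, so the quadrilateral
#' outcome is a kite whose two anterior edges are exactly twice the length of
#' either posterior (caudal) edge. The construction is closed form (the
#' endpoint, not the pulling trajectory): the rostral vertex is placed on the
#' symmetry axis at distance 2s from each immobilized lateral vertex, where s
#' is the strip length. Total perimeter is conserved (rigid strips).
#'
#' @param h a `polygon2d` that is a regular hexagon (within `tol`).
#' @param caudal_vertex index of the caudal vertex (the one shared by the two
#'   immobilized edges); default picks the vertex opposite the +y rostral
#'   direction in the hexagon's own frame.
#' @param tol relative tolerance for the regularity check.
#' @return a `polygon2d` kite with 4 vertices: rostral apex, then the two
#'   lateral (immobilized) vertices with the caudal vertex between them.
#' @examples
#' k <- stretch_to_kite(regular_hexagon(1))
#' sort(edge_lengths(k))  # 1 1 2 2
#' perimeter(k)           # 6
#' @export
stretch_to_kite <- function(h, caudal_vertex = NULL, tol = 1e-9) {
  stopifnot(inherits(h, "polygon2d"))
  if (nrow(h) != 6L) stop("input is not a hexagon")
  el <- edge_lengths(h)
  s <- mean(el)
  ctr <- colMeans(h)
  circ <- sqrt(rowSums(sweep(unclass(h), 2, ctr)^2))
  if (max(abs(el - s)) > tol * s || max(abs(circ - s)) > tol * s)
    stop("input is not a regular hexagon within tolerance")
  if (is.null(caudal_vertex)) {
    caudal_vertex <- which.min(unclass(h)[, 2])
  }
  n <- 6L
  C <- unclass(h)[caudal_vertex, ]
  Lprev <- unclass(h)[((caudal_vertex - 2L) %% n) + 1L, ]
  Lnext <- unclass(h)[(caudal_vertex %% n) + 1L, ]
  axis <- (ctr - C) / sqrt(sum((ctr - C)^2))
  ## rostral apex T = C + t*axis with |T - L| = 2s (two collinear strips)
  w <- Lnext - C
  b <- sum(w * axis)
  t <- b + sqrt(b^2 - sum(w * w) + 4 * s^2)
  Tv <- C + t * axis
  ## counter-clockwise: apex, lateral after caudal, caudal, lateral before
  polygon2d(rbind(Tv, Lnext, C, Lprev))
}

#' In-plane two-fold (reflection) symmetry axes of a polygon
#'
#' Finds every in-plane C2 axis by testing the candidate axes through the
#' centroid and each vertex or edge midpoint; an axis counts when reflecting
#' the polygon across it reproduces the polygon (up to cyclic relabelling,
#' orientation reversed). The count is invariant under scaling and rotation.
#'
#' @param p a `polygon2d`.
#' @param tol relative tolerance (default `1e-9`; the package's constructions
#'   are closed form).
#' @return a list with `count` (number of distinct axes) and `angles`
#'   (axis angles in radians, modulo pi).
#' @examples
#' c2_axes(regular_hexagon(1))$count                     # 6
#' c2_axes(stretch_to_kite(regular_hexagon(1)))$count    # 1
#' @export
c2_axes <- function(p, tol = 1e-9) {
  stopifnot(inherits(p, "polygon2d"))
  n <- nrow(p)
  ctr <- colMeans(p)
  X <- sweep(unclass(p), 2, ctr)
  scale <- max(sqrt(rowSums(X^2)))
  mids <- (X + rbind(X[-1, , drop = FALSE], X[1, , drop = FALSE])) / 2
  cand <- rbind(X, mids)
  keep <- sqrt(rowSums(cand^2)) > tol * scale
  ang <- atan2(cand[keep, 2], cand[keep, 1]) %% pi

  reflect <- function(theta) {
    co <- cos(2 * theta); si <- sin(2 * theta)
    X %*% matrix(c(co, si, si, -co), 2)
  }
  matches <- function(R) {
    ## reversed reflected polygon must equal the original up to rotation
    Rrev <- R[n:1, , drop = FALSE]
    for (k in seq_len(n)) {
      idx <- ((seq_len(n) + k - 2L) %% n) + 1L
      if (max(abs(Rrev[idx, ] - X)) <= tol * scale) return(TRUE)
    }
    FALSE
  }
  hits <- ang[vapply(ang, function(th) matches(reflect(th)), TRUE)]
  ## deduplicate angles modulo pi
  hits <- sort(hits)
  if (length(hits)) {
    d <- c(TRUE, diff(hits) > 1e-6)
    ## wrap-around duplicate (angle ~0 vs ~pi)
    if (length(hits) > 1L && (pi - (hits[length(hits)] - hits[1L])) < 1e-6)
      d[length(hits)] <- FALSE
    hits <- hits[d]
  }
  list(count = length(hits), angles = hits)
}
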