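#' Spheroid labels of the 1-6-6-1 head cluster
#'
#' The fourteen outer spheroids of the cluster are named for the cephalic
#' embryological regions they are taken to represent, the fifteenth is the
#' central (basicranial) spheroid. `.L`/`.R` are the animal's left/right.
#'
#' @format character vector of 15 labels.
#' @export
cluster_labels <- function() {
  c("frontonasal",                                    # top singleton
    "medial.nasal", "lateral.nasal.L", "optic.L",     # upper ring (rostral
    "mesencephalic", "optic.R", "lateral.nasal.R",    #  to caudal, L then R)
    "premandibular.L", "maxillomandibular.L", "metencephalic.L",
    "metencephalic.R", "maxillomandibular.R", "premandibular.R",
    "mandibular",                                     # bottom singleton
    "central")
}

## scute-facet role carried by each (possibly fused) surface region
region_role <- function(region_names) {
  base <- c(
    frontonasal = "frontal", medial.nasal = "rostral",
    lateral.nasal.L = "prefrontal.L", lateral.nasal.R = "prefrontal.R",
    optic.L = "supraocular.L", optic.R = "supraocular.R",
    mesencephalic = "frontoparietal",
    metencephalic.L = "caudal.L", metencephalic.R = "caudal.R",
    mandibular = "basal", central = "central"
  )
  vapply(region_names, function(nm) {
    parts <- strsplit(nm, "+", fixed = TRUE)[[1L]]
    if (length(parts) > 1L) {
      if ("premandibular.L" %in% parts) return("temporal.L")
      if ("premandibular.R" %in% parts) return("temporal.R")
      return(NA_character_)
    }
    if (nm %in% names(base)) base[[nm]] else NA_character_
  }, "")
}

#' Radius of an axis-aligned oblate spheroid along a direction
#'
#' @param u matrix of unit direction vectors (rows).
#' @param a equatorial semi-axis; `c` polar (z) semi-axis.
#' @return numeric vector of surface distances from the centre.
#' @keywords internal
spheroid_radius <- function(u, a, c) {
  1 / sqrt((u[, 1]^2 + u[, 2]^2) / a^2 + u[, 3]^2 / c^2)
}

#' Relative surface gaps between all spheroid pairs
#'
#' Gap along the centre-centre line against both spheroid surfaces (a
#' centre-line approximation of the ellipsoid-ellipsoid distance), divided
#' by the sum of the two surface radii: 0 means touching, negative overlap.
#'
#' @param cl a `spheroid_cluster`.
#' @return symmetric numeric matrix of relative gaps (diagonal `Inf`).
#' @export
cluster_gaps <- function(cl) {
  stopifnot(inherits(cl, "spheroid_cluster"))
  X <- cl$centers
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  G <- matrix(Inf, n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1L)) {
    j <- seq(i + 1L, n)
    u <- X[j, , drop = FALSE] - matrix(X[i, ], length(j), 3, byrow = TRUE)
    u <- u / D[i, j]
    rr <- 2 * spheroid_radius(u, cl$a, cl$c)
    G[i, j] <- G[j, i] <- D[i, j] / rr - 1
  }
  G
}

#' Build the 1-6-6-1 fifteen-spheroid cluster
#'
#' Constructs the densest-local-packing-style cluster in which fourteen
#' slightly oblate spheroids surround a central fifteenth: a top singleton,
#' two staggered six-rings and a bottom singleton (1-6-6-1 outer layering),
#' all with parallel polar (z) axes. Positions are seeded geometrically and
#' then relaxed by a deterministic position-based scheme (overlap resolution
#' between outer spheroids plus projection of every outer spheroid onto the
#' central-contact shell) until all fourteen outer spheroids touch the
#' central one within tolerance.
#'
#' @param aspect_ratio polar/equatorial semi-axis ratio c/a, in (0, 1];
#'   default 0.9 (slightly flattened spheres).
#' @param scale equatorial semi-axis a; default 1.5 (units of the putty
#'   model: 3.0 cm diameter, 2.7 cm height).
#' @param seed integer seed for the tiny symmetry-breaking jitter.
#' @param max_iter relaxation iteration cap.
#' @param contact_tol relative gap below which a pair counts as touching.
#' @return an object of class `spheroid_cluster`: list with `centers`
#'   (15 x 3 matrix, row names the labels), `a`, `c`, `labels`, `fusion`
#'   (named group assignment, initially each spheroid its own group).
#' @examples
#' cl <- build_1661_cluster()
#' sum(cluster_gaps(cl)["central", ] <= 0.02)  # 14 central contacts
#' @export
build_1661_cluster <- function(aspect_ratio = 0.9, scale = 1.5, seed = 0,
                               max_iter = 400, contact_tol = 0.02) {
  stopifnot(aspect_ratio > 0, aspect_ratio <= 1, scale > 0)
  a <- scale; cc <- aspect_ratio * scale
  labs <- cluster_labels()

  dirs <- matrix(0, 15, 3, dimnames = list(labs, c("x", "y", "z")))
  dirs["frontonasal", ] <- c(0, 0, 1)
  dirs["mandibular", ] <- c(0, 0, -1)
  th_u <- pi / 3; th_l <- pi - th_u
  up <- c("medial.nasal", "lateral.nasal.L", "optic.L",
          "mesencephalic", "optic.R", "lateral.nasal.R")
  lo <- c("premandibular.L", "maxillomandibular.L", "metencephalic.L",
          "metencephalic.R", "maxillomandibular.R", "premandibular.R")
  phi_u <- pi / 2 + (0:5) * pi / 3          # medial.nasal anterior (+y)
  phi_l <- pi / 2 + pi / 6 + (0:5) * pi / 3 # staggered
  dirs[up, ] <- cbind(sin(th_u) * cos(phi_u), sin(th_u) * sin(phi_u),
                      rep(cos(th_u), 6))
  dirs[lo, ] <- cbind(sin(th_l) * cos(phi_l), sin(th_l) * sin(phi_l),
                      rep(cos(th_l), 6))

  touch <- 2 * spheroid_radius(dirs, a, cc)
  X <- dirs * touch
  X["central", ] <- 0
  X <- X + with_seed(seed, matrix(stats::rnorm(45, sd = 1e-3 * a), 15, 3))
  X["central", ] <- 0

  cl <- structure(list(centers = X, a = a, c = cc, labels = labs,
                       fusion = setNames(labs, labs)),
                  class = "spheroid_cluster")
  cl <- relax_cluster(cl, max_iter = max_iter)
  g0 <- cluster_gaps(cl)["central", setdiff(labs, "central")]
  if (any(g0 > contact_tol))
    stop_cephaloid("cephaloid_convergence_error", sprintf(
      "relaxation left %d outer spheroids off the central contact (max gap %.3f)",
      sum(g0 > contact_tol), max(g0)))
  cl
}

## Deterministic position-based relaxation: batch overlap resolution between
## outer spheroids, then projection of each outer centre onto the
## central-contact shell. The central spheroid stays at the origin.
relax_cluster <- function(cl, max_iter = 400, w_overlap = 0.4,
                          w_central = 0.9, tol = 1e-4) {
  X <- cl$centers
  outer <- setdiff(rownames(X), "central")
  for (it in seq_len(max_iter)) {
    disp <- matrix(0, nrow(X), 3, dimnames = dimnames(X))
    G <- cluster_gaps(structure(list(centers = X, a = cl$a, c = cl$c),
                                class = "spheroid_cluster"))
    for (i in seq_along(outer)) {
      for (j in seq_along(outer)) {
        if (j <= i) next
        gi <- outer[i]; gj <- outer[j]
        if (G[gi, gj] < 0) {
          u <- X[gj, ] - X[gi, ]
          d <- sqrt(sum(u^2)); u <- u / d
          push <- -G[gi, gj] * d / (1 + G[gi, gj]) / 2  # absolute half-overlap
          disp[gi, ] <- disp[gi, ] - w_overlap * push * u
          disp[gj, ] <- disp[gj, ] + w_overlap * push * u
        }
      }
    }
    X <- X + disp
    ## project onto central-contact shell
    nrm <- sqrt(rowSums(X[outer, ]^2))
    u <- X[outer, ] / nrm
    tgt <- 2 * spheroid_radius(u, cl$a, cl$c)
    X[outer, ] <- X[outer, ] + (w_central * (tgt - nrm)) * u
    if (max(abs(disp)) < tol * cl$a && max(abs(tgt - nrm)) < tol * cl$a) break
  }
  cl$centers <- X
  cl
}

#' Contact graph of a spheroid cluster
#'
#' Nodes are the cluster's fusion groups (single spheroids unless fusions
#' have been applied), including the central spheroid; an edge joins two
#' groups whenever any member pair has relative surface gap at most `tol`.
#'
#' @param cl a `spheroid_cluster`.
#' @param tol relative surface-gap tolerance (default 0.02).
#' @return an `igraph` with vertex attributes `name` (group label, member
#'   labels joined by `+`) and `role` (scute-facet role, where known).
#' @export
contact_graph <- function(cl, tol = 0.02) {
  stopifnot(inherits(cl, "spheroid_cluster"))
  G <- cluster_gaps(cl)
  groups <- split(names(cl$fusion), cl$fusion)
  gname <- vapply(groups, function(m) paste(sort(m), collapse = "+"), "")
  ## keep the declared group order stable: central last
  k <- length(groups)
  adj <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      adj[i, j] <- min(G[groups[[i]], groups[[j]]]) <= tol
    }
  }
  el <- which(adj, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = unname(gname))
  if (nrow(el))
    g <- igraph::add_edges(g, t(cbind(el[, 1], el[, 2])))
  igraph::set_vertex_attr(g, "role", value = unname(region_role(gname)))
}
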