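#' Perturb a spheroid cluster
#'
#' Adds isotropic Gaussian noise to the spheroid centres (the central
#' spheroid stays at the origin), emulating imprecision in the hand-built
#' cluster. Labels, semi-axes and fusion groups are preserved; output is
#' deterministic given the seed.
#'
#' @param base a `spheroid_cluster`.
#' @param jitter relative positional noise (standard deviation as a
#'   fraction of the equatorial semi-axis a); must be >= 0.
#' @param seed integer seed.
#' @return a perturbed `spheroid_cluster`.
#' @export
perturbed_cluster <- function(base, jitter, seed = 0) {
  stopifnot(inherits(base, "spheroid_cluster"), jitter >= 0)
  n <- nrow(base$centers)
  noise <- with_seed(seed, matrix(stats::rnorm(3 * n, sd = jitter * base$a),
                                  n, 3))
  base$centers <- base$centers + noise
  base$centers["central", ] <- 0
  base
}

#' Element dropout model
#'
#' Independent per-element dropout probabilities by element class,
#' emulating elements that are "not readily apparent" on a specimen
#' photograph.
#'
#' @param facet,vertex,edge dropout probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return an object of class `dropout_model`.
#' @export
dropout_model <- function(facet = 0, vertex = 0, edge = 0, seed = 0) {
  p <- c(facet = facet, vertex = vertex, edge = edge)
  stopifnot(all(p >= 0), all(p <= 1))
  structure(list(p = p, seed = seed), class = "dropout_model")
}

#' Random specimen observation
#'
#' Draws a synthetic [observation_set()] from a template: every dorsally
#' visible element is retained independently with probability one minus its
#' class dropout rate.
#'
#' @param template a `polyhedral_complex`.
#' @param model a [dropout_model()].
#' @param basal id of the occluded basal facet.
#' @return an `observation_set`.
#' @examples
#' tet <- cephaloid_tetradecahedron()
#' obs <- random_observation(tet, dropout_model(edge = 1/31, seed = 1))
#' identification_score(tet, "basal", obs)$score
#' @export
random_observation <- function(template, model, basal = "basal") {
  stopifnot(inherits(template, "polyhedral_complex"),
            inherits(model, "dropout_model"))
  vis <- visible_elements(template, basal)
  keep <- with_seed(model$seed, list(
    facets = vis$facets[stats::runif(length(vis$facets)) >= model$p["facet"]],
    vertices = vis$vertices[
      stats::runif(length(vis$vertices)) >= model$p["vertex"]],
    edges = vis$edges[stats::runif(length(vis$edges)) >= model$p["edge"]]
  ))
  observation_set(template, facets = keep$facets, vertices = keep$vertices,
                  edges = keep$edges, basal = basal,
                  specimen = sprintf("synthetic-%d", model$seed),
                  note = "synthetic dropout observation")
}

#' Random sphere-like polyhedral complex
#'
#' Samples points uniformly on the unit sphere and returns the facet
#' structure of their convex hull as a validated `polyhedral_complex`
#' (all facets triangular for points in general position). Used as
#' negative-control and property-test input for the foam operators and the
#' isomorphism matcher.
#'
#' The hull is computed by the direct plane-side test (every triple of
#' points spanning a plane with all remaining points strictly on one side
#' is a hull facet), which is robust for the small point counts used here.
#'
#' @param n_points number of points (>= 4).
#' @param seed integer seed.
#' @param max_tries resampling attempts for (numerically) degenerate
#'   configurations before giving up.
#' @return a `polyhedral_complex` with vertices `P1..Pn` and triangular
#'   facets; vertex coordinates attached.
#' @examples
#' census(random_sphere_complex(4, seed = 1))$histogram  # {3: 4}
#' @export
random_sphere_complex <- function(n_points, seed = 0, max_tries = 10) {
  stopifnot(n_points >= 4)
  eps <- 1e-9
  for (try in seq_len(max_tries)) {
    P <- with_seed(seed + (try - 1L) * 7919L, {
      M <- matrix(stats::rnorm(3 * n_points), n_points, 3)
      M / sqrt(rowSums(M^2))
    })
    rownames(P) <- paste0("P", seq_len(n_points))
    tri <- utils::combn(n_points, 3)
    facets <- list()
    degenerate <- FALSE
    for (q in seq_len(ncol(tri))) {
      i <- tri[1, q]; j <- tri[2, q]; k <- tri[3, q]
      nrm <- c(
        (P[j, 2] - P[i, 2]) * (P[k, 3] - P[i, 3]) -
          (P[j, 3] - P[i, 3]) * (P[k, 2] - P[i, 2]),
        (P[j, 3] - P[i, 3]) * (P[k, 1] - P[i, 1]) -
          (P[j, 1] - P[i, 1]) * (P[k, 3] - P[i, 3]),
        (P[j, 1] - P[i, 1]) * (P[k, 2] - P[i, 2]) -
          (P[j, 2] - P[i, 2]) * (P[k, 1] - P[i, 1]))
      side <- drop(P %*% nrm) - sum(nrm * P[i, ])
      side <- side[-c(i, j, k)]
      if (any(abs(side) < eps)) { degenerate <- TRUE; break }
      if (all(side < 0)) {
        facets[[length(facets) + 1L]] <- rownames(P)[c(i, j, k)]
      } else if (all(side > 0)) {
        facets[[length(facets) + 1L]] <- rownames(P)[c(i, k, j)]
      }
    }
    if (degenerate) next
    names(facets) <- paste0("T", seq_along(facets))
    out <- tryCatch(polyhedral_complex(facets, coords = P),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop_cephaloid("cephaloid_degenerate_hull_error", sprintf(
    "no non-degenerate spherical point set found in %d tries", max_tries))
}
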