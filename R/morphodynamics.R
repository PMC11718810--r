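## Calibrated endpoint of the convergent-extension shaping, in head
## coordinates (x transverse, y anteroposterior with rostral positive,
## z dorsoventral with dorsal positive; units of the default cluster,
## a = 1.5). The configuration realises, with identical oblate spheroids,
## exactly the cephaloid-dodecahedron region adjacency: every facet-adjacent
## region pair rests in shallow surface contact while every pair that shares
## only a polyhedron vertex is separated by a clear margin. It was calibrated
## once, by constrained optimisation over mirror-symmetric configurations,
## and is part of the model definition (see the methods vignette).
ce_endpoint <- matrix(
  c(0, 0, -1.4636, -2.2066, 0, 2.2066, 1.4636, -2.4637,
    -2.5521, -1.4574, 1.4574, 2.5521, 2.4637, 0,
    0.3352, 3.687, 2.3396, -0.4984, -2.4309, -0.4984, 2.3396,
    2.9881, 0.1681, -2.4894, -2.4894, 0.1681, 2.9881, -0.3494,
    2.8781, -0.1789, 1.6582, 1.487, 1.308, 1.487, 1.6582,
    -1.2521, -1.0489, -0.9653, -0.9653, -1.0489, -1.2521, -2.1861),
  nrow = 14, ncol = 3,
  dimnames = list(c("frontonasal", "medial.nasal", "lateral.nasal.L",
                    "optic.L", "mesencephalic", "optic.R", "lateral.nasal.R",
                    "premandibular.L", "maxillomandibular.L",
                    "metencephalic.L", "metencephalic.R",
                    "maxillomandibular.R", "premandibular.R", "mandibular"),
                  c("x", "y", "z")))

## nominal anterior elongation and transverse dorsal narrowing realised by
## the full calibrated endpoint; protocol scalars are expressed relative to
## these
ce_nominal_stretch <- 1.36   # rostral extent 3.69 / 2.72
ce_nominal_pinch <- 0.38     # prefrontal |x| 2.36 -> 1.46

#' Strain protocol for the convergent-extension experiment
#'
#' Describes the in-silico analogue of stretching and pinching the putty
#' cluster: an anteroposterior stretch with dorsoventral flattening, and an
#' anterior-dorsal transverse narrowing (midline convergence). The two
#' scalars scale the longitudinal/vertical and transverse components of the
#' calibrated displacement program: `stretch = 1, pinch = 0` is the identity
#' protocol (no deformation, no fusion).
#'
#' @param stretch total anterior elongation factor (>= 1; default 1.36, the
#'   full calibrated program).
#' @param pinch anterior-dorsal transverse narrowing fraction in `[0, 1)`
#'   (default 0.38, the full program).
#' @param increments number of strain increments (>= 1).
#' @param relax_iter overlap-relaxation iterations per increment.
#' @param step relaxation step size in (0, 1]; scales all relaxation
#'   displacement weights.
#' @param seed integer seed (passed to the cluster builder when the
#'   pipeline constructs one; the deformation itself is deterministic).
#' @param fusions list of label pairs prescribed to fuse (the two
#'   anterolateral lower pairs by default). Fusions are executed only when
#'   the protocol applies strain and only once each pair is in contact.
#' @param new_contacts list of label pairs asserted to be newly in contact
#'   after deformation (default: the two lateral-nasal/prefrontal
#'   spheroids).
#' @param contact_tol relative surface-gap contact tolerance.
#' @param tear relative gap beyond which a strained adhesion bond tears.
#' @param bond relative gap below which a new adhesion bond forms.
#' @return an object of class `strain_protocol`.
#' @export
strain_protocol <- function(stretch = 1.36, pinch = 0.38,
                            increments = 20, relax_iter = 15, step = 0.3,
                            seed = 0,
                            fusions = list(
                              c("premandibular.L", "maxillomandibular.L"),
                              c("premandibular.R", "maxillomandibular.R")),
                            new_contacts = list(
                              c("lateral.nasal.L", "lateral.nasal.R")),
                            contact_tol = 0.02, tear = 0.025, bond = 0.005) {
  stopifnot(stretch >= 1, pinch >= 0, pinch < 1, increments >= 1,
            relax_iter >= 1, step > 0, step <= 1)
  structure(list(stretch = stretch, pinch = pinch, increments = increments,
                 relax_iter = relax_iter, step = step, seed = seed,
                 fusions = fusions, new_contacts = new_contacts,
                 contact_tol = contact_tol, tear = tear, bond = bond),
            class = "strain_protocol")
}

#' Deform the spheroid cluster by convergent extension
#'
#' The in-silico replacement for the manual putty experiment. The fourteen
#' outer spheroids are guided incrementally along the protocol's strain
#' program (anterior traction with dorsoventral flattening, scaled by
#' `stretch`; dorsal midline convergence, scaled by `pinch`) while a
#' position-based relaxation maintains the material behaviour: overlapping
#' spheroids push apart, adhesion bonds (initial contacts) hold neighbours
#' together until torn by tensile strain, torn interfaces do not re-fuse,
#' new bonds form on first touch, and the central spheroid acts as a
#' deformable incompressible core that supports the shell but can be
#' squashed. Prescribed fusions (the white and gray anterolateral
#' pairs) merge regions once in contact; the prescribed new contact between
#' the two prefrontal spheroids is asserted at the end.
#'
#' @param cl a `spheroid_cluster` with the standard labels (see
#'   [build_1661_cluster()]).
#' @param protocol a [strain_protocol()].
#' @return an object of class `ce_result`: list with `cluster` (deformed,
#'   fusion groups set), `graph` (region contact graph including the
#'   central node), `surface_graph` (central removed), `n_regions` (surface
#'   region count), `events` (bond tear/form log), `protocol`.
#' @examples
#' \donttest{
#' res <- convergent_extension(build_1661_cluster(), strain_protocol())
#' res$n_regions  # 12
#' }
#' @export
convergent_extension <- function(cl, protocol = strain_protocol()) {
  stopifnot(inherits(cl, "spheroid_cluster"),
            inherits(protocol, "strain_protocol"))
  if (!setequal(cl$labels, cluster_labels()))
    stop("cluster does not carry the standard 1-6-6-1 labels")
  p <- protocol
  X <- cl$centers
  outer <- setdiff(rownames(X), "central")
  a <- cl$a; cc <- cl$c

  m_s <- (p$stretch - 1) / (ce_nominal_stretch - 1)
  m_p <- p$pinch / ce_nominal_pinch
  identity_protocol <- m_s == 0 && m_p == 0

  D <- ce_endpoint[outer, ] * (a / 1.5) - X[outer, ]
  D[, "x"] <- D[, "x"] * m_p
  D[, "y"] <- D[, "y"] * m_s
  D[, "z"] <- D[, "z"] * m_s
  XT <- X[outer, ] + D

  ## the core deforms with the imposed strain
  core0 <- c(x = a, y = a, z = cc)
  coreT <- core0 + c(m_p * (0.9 * a - a), m_s * (1.33 * a - a),
                     m_s * (0.74 * cc - cc))

  gaps14 <- function(P) {
    n <- nrow(P)
    G <- matrix(Inf, n, n, dimnames = list(rownames(P), rownames(P)))
    D2 <- as.matrix(stats::dist(P))
    for (i in seq_len(n - 1L)) {
      j <- seq(i + 1L, n)
      u <- P[j, , drop = FALSE] - matrix(P[i, ], length(j), 3, byrow = TRUE)
      u <- u / D2[i, j]
      rr <- 2 * spheroid_radius(u, a, cc)
      G[i, j] <- G[j, i] <- D2[i, j] / rr - 1
    }
    G
  }

  nb <- length(outer)
  X0 <- X[outer, ]
  G <- gaps14(X[outer, ])
  bonded <- G <= p$contact_tol
  torn <- matrix(FALSE, nb, nb)
  events <- character()
  w_o <- p$step; w_b <- p$step; w_g <- 0.83 * p$step; w_c <- 1.67 * p$step

  for (k in seq_len(p$increments)) {
    t1 <- k / p$increments
    Xk <- X0 + D * t1
    core <- core0 + (coreT - core0) * t1
    for (r in seq_len(p$relax_iter)) {
      G <- gaps14(X[outer, ])
      disp <- matrix(0, nb, 3, dimnames = list(outer, NULL))
      for (i in seq_len(nb - 1L)) {
        for (j in seq(i + 1L, nb)) {
          g <- G[i, j]
          if (bonded[i, j]) {
            if (g > p$tear) {
              bonded[i, j] <- FALSE; torn[i, j] <- TRUE
              events <- c(events, sprintf("increment %02d: tear %s ~ %s",
                                          k, outer[i], outer[j]))
              next
            }
          } else if (!torn[i, j] && g <= p$bond) {
            bonded[i, j] <- TRUE
            events <- c(events, sprintf("increment %02d: bond %s ~ %s",
                                        k, outer[i], outer[j]))
          }
          w <- if (g < 0) w_o else if (bonded[i, j]) w_b else 0
          if (w == 0) next
          u <- X[outer[j], ] - X[outer[i], ]
          d <- sqrt(sum(u^2)); u <- u / d
          push <- -g * d / (1 + g) / 2 * w
          disp[i, ] <- disp[i, ] - push * u
          disp[j, ] <- disp[j, ] + push * u
        }
      }
      X[outer, ] <- X[outer, ] + disp + w_g * (Xk - X[outer, ])
      ## squashable core: supports the shell from inside, never pulls
      P <- X[outer, ]
      dvec <- sqrt(rowSums(P^2)); u <- P / dvec
      rcore <- 1 / sqrt(u[, 1]^2 / core["x"]^2 + u[, 2]^2 / core["y"]^2 +
                        u[, 3]^2 / core["z"]^2)
      rout <- spheroid_radius(u, a, cc)
      push <- pmin(dvec - (rcore + rout), 0)
      X[outer, ] <- X[outer, ] - (w_c * push) * u
    }
  }

  cl$centers <- X
  Gfin <- cluster_gaps(cl)

  if (!identity_protocol) {
    for (fp in p$fusions) {
      if (Gfin[fp[1], fp[2]] > p$contact_tol)
        stop_cephaloid("cephaloid_fusion_contact_error", sprintf(
          "prescribed fusion pair %s/%s never reached contact (gap %.3f)",
          fp[1], fp[2], Gfin[fp[1], fp[2]]))
      grp <- paste(sort(c(cl$fusion[fp[1]], cl$fusion[fp[2]])),
                   collapse = "+")
      cl$fusion[cl$fusion %in% cl$fusion[fp]] <- grp
    }
    for (ncp in p$new_contacts) {
      if (Gfin[ncp[1], ncp[2]] > p$contact_tol)
        stop_cephaloid("cephaloid_contact_error", sprintf(
          "prescribed new contact %s ~ %s absent after deformation (gap %.3f)",
          ncp[1], ncp[2], Gfin[ncp[1], ncp[2]]))
    }
  }

  graph <- contact_graph(cl, tol = p$contact_tol)
  surface <- igraph::delete_vertices(
    graph, which(igraph::V(graph)$name == "central"))
  structure(list(cluster = cl, graph = graph, surface_graph = surface,
                 n_regions = as.integer(igraph::vcount(surface)),
                 events = events, protocol = p),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf(
    "<ce_result> %d surface regions; %d region adjacencies; %d bond events\n",
    x$n_regions, igraph::ecount(x$surface_graph), length(x$events)))
  m <- match_to_dodecahedron(x)
  cat("  matches cephaloid dodecahedron facet graph:", m$isomorphic, "\n")
  invisible(x)
}

#' Match a deformed-cluster region graph to the cephaloid dodecahedron
#'
#' Role-respecting isomorphism test of a 12-region surface adjacency graph
#' against the facet-adjacency graph of [cephaloid_dodecahedron()]. The
#' roles force the anatomical correspondence, so a successful match sends
#' the mandibular region to the basal facet.
#'
#' @param x a `ce_result` or an `igraph` region graph (a `central` node, if
#'   present, is removed).
#' @return list with `isomorphic`, `mapping` (region name -> facet id) and
#'   `diagnostic` (first mismatched adjacency when not isomorphic).
#' @export
match_to_dodecahedron <- function(x) {
  g <- if (inherits(x, "ce_result")) x$surface_graph else x
  stopifnot(inherits(g, "igraph"))
  if ("central" %in% igraph::V(g)$name)
    g <- igraph::delete_vertices(g, which(igraph::V(g)$name == "central"))
  ref <- facet_adjacency(cephaloid_dodecahedron())
  graph_isomorphic(g, ref, respect_degrees = FALSE, respect_roles = "auto")
}
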