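## Mesh, graph and observation I/O. All formats are plain text: OFF and
## Wavefront OBJ for meshes (vertex ids are preserved in trailing comments;
## role labels only survive the JSON dialect), GraphML for region graphs
## (via igraph), and a documented JSON dialect for complexes and specimen
## observations.

#' Unit-sphere embedding of a complex
#'
#' Coordinates for a complex that has none: the dorsal projection through
#' an arbitrary facet is mapped to the sphere by inverse stereographic
#' projection. Purely cosmetic — used when exporting to OFF/OBJ.
#'
#' @param x a `polyhedral_complex`.
#' @return numeric matrix (V x 3) with vertex row names.
#' @export
sphere_embedding <- function(x) {
  stopifnot(inherits(x, "polyhedral_complex"))
  pr <- dorsal_projection(x, names(x$facets)[1L])
  co <- pr$coords * 1.5   # keep the outer face off the projection pole
  d2 <- rowSums(co^2)
  cbind(2 * co[, 1], 2 * co[, 2], d2 - 1) / (d2 + 1)
}

complex_coords <- function(x) {
  if (is.null(x$coords)) sphere_embedding(x) else x$coords[, 1:3, drop = FALSE]
}

#' Read and write polyhedral complexes
#'
#' `write_off()`/`read_off()` use the Object File Format; `write_obj()`/
#' `read_obj()` use Wavefront OBJ. Vertex ids are written as trailing `#`
#' comments so a round trip reproduces the identical complex (facet cycles
#' up to rotation); files from other tools get synthetic ids `P1..Pn`.
#' When the complex carries no coordinates a unit-sphere embedding is
#' written. `write_complex_json()`/`read_complex_json()` use the JSON
#' dialect `{"facets": {...}, "labels": {...}, "coords": {...}}` and
#' preserve labels and coordinates exactly.
#'
#' @param x a `polyhedral_complex`.
#' @param path file path.
#' @return the readers return a validated `polyhedral_complex`; the writers
#'   return `path` invisibly.
#' @export
write_off <- function(x, path) {
  stopifnot(inherits(x, "polyhedral_complex"))
  co <- complex_coords(x)
  cs <- census(x)
  ids <- x$vertices
  idx <- setNames(seq_along(ids) - 1L, ids)
  lines <- c(
    "OFF",
    sprintf("%d %d %d", cs$V, cs$F, cs$E),
    sprintf("%.10g %.10g %.10g # %s", co[ids, 1], co[ids, 2], co[ids, 3], ids),
    vapply(names(x$facets), function(f) {
      cyc <- x$facets[[f]]
      paste(c(length(cyc), idx[cyc]), collapse = " ")
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_off
#' @export
read_off <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  stopifnot(toupper(lines[1L]) == "OFF")
  counts <- as.integer(strsplit(lines[2L], "\\s+")[[1L]])
  nv <- counts[1L]; nf <- counts[2L]
  vlines <- lines[3:(2 + nv)]
  has_id <- grepl("#", vlines, fixed = TRUE)
  ids <- ifelse(has_id, trimws(sub(".*#", "", vlines)),
                paste0("P", seq_len(nv)))
  co <- t(vapply(sub("#.*", "", vlines), function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1L]][1:3]), numeric(3)))
  rownames(co) <- ids
  flines <- lines[(3 + nv):(2 + nv + nf)]
  facets <- lapply(flines, function(s) {
    w <- as.integer(strsplit(sub("#.*", "", s), "\\s+")[[1L]])
    ids[w[2:(1 + w[1L])] + 1L]
  })
  names(facets) <- paste0("F", seq_len(nf))
  polyhedral_complex(facets, coords = co)
}

#' @rdname write_off
#' @export
write_obj <- function(x, path) {
  stopifnot(inherits(x, "polyhedral_complex"))
  co <- complex_coords(x)
  ids <- x$vertices
  idx <- setNames(seq_along(ids), ids)
  lines <- c(
    sprintf("v %.10g %.10g %.10g # %s", co[ids, 1], co[ids, 2], co[ids, 3],
            ids),
    vapply(names(x$facets), function(f)
      paste(c("f", idx[x$facets[[f]]]), collapse = " "), "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_off
#' @export
read_obj <- function(path) {
  lines <- trimws(readLines(path))
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  nv <- length(vlines)
  has_id <- grepl("#", vlines, fixed = TRUE)
  ids <- ifelse(has_id, trimws(sub(".*#", "", vlines)),
                paste0("P", seq_len(nv)))
  co <- t(vapply(sub("#.*", "", vlines), function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1L]][2:4]), numeric(3)))
  rownames(co) <- ids
  facets <- lapply(flines, function(s) {
    w <- strsplit(sub("#.*", "", s), "\\s+")[[1L]][-1L]
    ids[as.integer(sub("/.*", "", w))]
  })
  names(facets) <- paste0("F", seq_along(facets))
  polyhedral_complex(facets, coords = co)
}

#' @rdname write_off
#' @export
write_complex_json <- function(x, path) {
  stopifnot(inherits(x, "polyhedral_complex"))
  obj <- list(facets = x$facets)
  labs <- x$labels[!is.na(x$labels)]
  if (length(labs)) obj$labels <- as.list(labs)
  if (!is.null(x$coords)) {
    obj$coords <- setNames(
      lapply(seq_len(nrow(x$coords)), function(i) unname(x$coords[i, ])),
      rownames(x$coords))
  }
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_off
#' @export
read_complex_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coords <- NULL
  if (!is.null(obj$coords)) {
    coords <- do.call(rbind, obj$coords)
    rownames(coords) <- names(obj$coords)
  }
  labels <- if (!is.null(obj$labels)) unlist(obj$labels) else NULL
  polyhedral_complex(as.list(obj$facets), labels = labels, coords = coords)
}

#' Read and write region-adjacency graphs as GraphML
#'
#' Thin wrappers over [igraph::write_graph()]/[igraph::read_graph()] that
#' keep the `name` and `role` vertex attributes.
#'
#' @param g an `igraph` region graph.
#' @param path file path.
#' @return the reader returns an `igraph`; the writer returns `path`
#'   invisibly.
#' @export
write_region_graphml <- function(g, path) {
  stopifnot(inherits(g, "igraph"))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_region_graphml
#' @export
read_region_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Read and write specimen observations as JSON
#'
#' Dialect: `{"template": name, "specimen": id, "facets": [...],
#' "vertices": [...], "edges": [[v1, v2], ...]}`.
#'
#' @param obs an [observation_set()].
#' @param path file path.
#' @param template_name name recorded in the file.
#' @param template the `polyhedral_complex` the observation refers to
#'   (needed to validate on read).
#' @return the reader returns an `observation_set` (plus a
#'   `template_name` attribute); the writer returns `path` invisibly.
#' @export
write_observation_json <- function(obs, path, template_name = "template") {
  stopifnot(inherits(obs, "observation_set"))
  edges <- lapply(strsplit(obs$edges, "--", fixed = TRUE), identity)
  jsonlite::write_json(
    list(template = template_name, specimen = obs$specimen,
         facets = obs$facets, vertices = obs$vertices, edges = edges,
         note = obs$note),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_observation_json
#' @export
read_observation_json <- function(path, template) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- obj$edges
  if (is.matrix(edges)) edges <- split(edges, seq_len(nrow(edges)))
  obs <- observation_set(template,
                         facets = unlist(obj$facets),
                         vertices = unlist(obj$vertices),
                         edges = as.list(edges),
                         specimen = obj$specimen %||% "",
                         note = obj$note %||% "")
  attr(obs, "template_name") <- obj$template
  obs
}
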