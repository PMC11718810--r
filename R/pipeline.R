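#' Pipeline configuration
#'
#' Parameters for the full morphogenesis pipeline: pack fifteen spheroids,
#' deform by convergent extension, match the surface pattern to the
#' cephaloid dodecahedron, apply the T1 edge formation and the bilateral
#' supraocular splits, and match/score the resulting tetradecahedron.
#'
#' @param aspect_ratio spheroid aspect ratio c/a (default 0.9).
#' @param scale equatorial semi-axis a (default 1.5).
#' @param seed integer seed for all stochastic stages.
#' @param stretch,pinch strain-protocol scalars (see [strain_protocol()]).
#' @param contact_tol relative contact tolerance.
#' @param increments,relax_iter,step relaxation controls.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(aspect_ratio = 0.9, scale = 1.5, seed = 0,
                            stretch = 1.36, pinch = 0.38,
                            contact_tol = 0.02, increments = 20,
                            relax_iter = 15, step = 0.3) {
  structure(list(aspect_ratio = aspect_ratio, scale = scale, seed = seed,
                 stretch = stretch, pinch = pinch,
                 contact_tol = contact_tol, increments = increments,
                 relax_iter = relax_iter, step = step),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file path; `.yaml`/`.yml` files require the `yaml` package.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, vals[names(vals) %in%
                                  names(formals(pipeline_config))])
}

#' Run the full morphogenesis pipeline
#'
#' Executes pack -> stretch -> match-to-dodecahedron -> T1 edge formation ->
#' bilateral supraocular split -> match-to-tetradecahedron -> dorsal
#' projection and identification scoring, and returns a machine-readable
#' report. Any failed stage assertion raises an error naming the stage.
#'
#' @param cfg a [pipeline_config()] (or path accepted by
#'   [read_pipeline_config()]).
#' @return an object of class `cephaloid_report`: a nested list with one
#'   entry per stage (censuses, isomorphism verdicts, scores) plus the
#'   configuration. Serialise with [write_report()].
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config())
#' rep$tetradecahedron$census$total  # 64
#' }
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  cl <- stage("pack", build_1661_cluster(
    aspect_ratio = cfg$aspect_ratio, scale = cfg$scale, seed = cfg$seed,
    contact_tol = cfg$contact_tol))
  central_contacts <- sum(
    cluster_gaps(cl)["central", setdiff(cl$labels, "central")] <=
      cfg$contact_tol)

  proto <- strain_protocol(stretch = cfg$stretch, pinch = cfg$pinch,
                           increments = cfg$increments,
                           relax_iter = cfg$relax_iter, step = cfg$step,
                           seed = cfg$seed, contact_tol = cfg$contact_tol)
  ce <- stage("stretch", convergent_extension(cl, proto))

  dmatch <- match_to_dodecahedron(ce)
  if (!dmatch$isomorphic)
    stop(sprintf(
      "pipeline stage 'match-dodecahedron' failed: %s", dmatch$diagnostic),
      call. = FALSE)

  dode <- cephaloid_dodecahedron()
  mv <- canonical_pathway()
  inter <- stage("t1", t1_edge_formation(dode, mv$t1))
  tetra <- stage("split", bilateral_split(inter, mv$left, mv$right))

  ref <- cephaloid_tetradecahedron()
  tmatch <- graph_isomorphic(facet_adjacency(tetra), facet_adjacency(ref),
                             respect_roles = TRUE)
  if (!tmatch$isomorphic)
    stop("pipeline stage 'match-tetradecahedron' failed", call. = FALSE)

  proj <- dorsal_projection(tetra, "basal")
  obs <- full_observation(tetra, "basal")
  score <- identification_score(tetra, "basal", obs)

  census_list <- function(x) {
    cs <- census(x)
    list(histogram = as.list(cs$histogram), F = cs$F, V = cs$V, E = cs$E,
         total = cs$total)
  }
  structure(list(
    schema = "cephaloid-report/1",
    config = unclass(cfg),
    pack = list(central_contacts = central_contacts,
                aspect_ratio = cfg$aspect_ratio),
    stretch = list(n_regions = ce$n_regions,
                   n_adjacencies = igraph::ecount(ce$surface_graph),
                   bond_events = length(ce$events)),
    dodecahedron = list(match = dmatch$isomorphic,
                        census = census_list(dode),
                        mandibular_maps_to =
                          unname(dmatch$mapping["mandibular"])),
    intermediate = list(census = census_list(inter)),
    tetradecahedron = list(match = tmatch$isomorphic,
                           census = census_list(tetra)),
    projection = list(visible = proj$n_visible,
                      total = census(tetra)$total,
                      full_observation_score = score$score)
  ), class = "cephaloid_report")
}

#' @export
print.cephaloid_report <- function(x, ...) {
  cat("<cephaloid_report>\n")
  cat(sprintf("  pack:    %d/14 central contacts\n",
              x$pack$central_contacts))
  cat(sprintf("  stretch: %d surface regions, dodecahedron match: %s\n",
              x$stretch$n_regions, x$dodecahedron$match))
  h <- x$tetradecahedron$census$histogram
  cat(sprintf("  pathway: tetradecahedron census {%s}, total %d, match: %s\n",
              paste(sprintf("%s:%d", names(h), unlist(h)), collapse = ", "),
              x$tetradecahedron$census$total, x$tetradecahedron$match))
  cat(sprintf("  dorsal projection: %d of %d elements visible\n",
              x$projection$visible, x$projection$total))
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' @param report a `cephaloid_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "cephaloid_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
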