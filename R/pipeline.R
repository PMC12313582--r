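#' Build pipeline node specifications
#'
#' `node_spec()` describes one node instance: a unique id, a registered node
#' type, parameter values and the upstream node(s) feeding it.
#' `pipeline()` assembles the ordered node graph; `chain_pipeline()` is a
#' shorthand that wires a list of node types into a linear chain (the shape
#' of all shipped presets).
#'
#' @param node_id Unique string id within the pipeline.
#' @param node_type Registered node-type label.
#' @param params Named list of parameter values (validated against the
#'   node's schema when the pipeline is validated/run).
#' @param upstream Character vector of upstream node ids (at most one; the
#'   engine executes single-upstream graphs).
#' @return `node_spec()`: a `node_spec` object; `pipeline()` /
#'   `chain_pipeline()`: a `pipeline_spec`.
#' @export
node_spec <- function(node_id, node_type, params = list(),
                      upstream = character(0)) {
  stopifnot(nzchar(node_id), nzchar(node_type))
  structure(list(node_id = node_id, node_type = node_type,
                 params = params, upstream = as.character(upstream)),
            class = "node_spec")
}

#' @rdname node_spec
#' @param nodes List of `node_spec`s.
#' @param name Pipeline name.
#' @param version Version tag carried in the serialization.
#' @export
pipeline <- function(nodes, name = "pipeline", version = "1") {
  stopifnot(all(vapply(nodes, inherits, logical(1), "node_spec")))
  p <- structure(list(name = name, version = version, nodes = nodes),
                 class = "pipeline_spec")
  validate_pipeline(p, check_types = FALSE)
  p
}

#' @rdname node_spec
#' @param types Character vector of node-type labels, in execution order.
#' @param params Named list: per-type parameter lists (names matching
#'   `types`).
#' @export
chain_pipeline <- function(types, params = list(), name = "pipeline",
                           version = "1") {
  ids <- make.unique(types, sep = "_")
  nodes <- lapply(seq_along(types), function(i)
    node_spec(ids[i], types[i],
              params = if (types[i] %in% names(params))
                params[[types[i]]] else list(),
              upstream = if (i > 1) ids[i - 1] else character(0)))
  pipeline(nodes, name = name, version = version)
}

#' Validate a pipeline graph
#'
#' Checks id uniqueness, acyclicity, that every upstream reference exists,
#' that each node has at most one upstream (the engine runs single-upstream
#' graphs) and exactly one node is a source, and — when `check_types` —
#' that every node type is registered and its parameters respect the
#' declared schema.
#'
#' @param p A `pipeline_spec`.
#' @param check_types Also validate node types and parameter ranges.
#' @return The topologically ordered node ids, invisibly.
#' @export
validate_pipeline <- function(p, check_types = TRUE) {
  stopifnot(inherits(p, "pipeline_spec"))
  ids <- vapply(p$nodes, `[[`, character(1), "node_id")
  if (anyDuplicated(ids))
    stop("duplicate node_id in pipeline", call. = FALSE)
  for (n in p$nodes) {
    if (length(n$upstream) > 1)
      stop(sprintf("node '%s' has %d upstream nodes; merges are not supported",
                   n$node_id, length(n$upstream)), call. = FALSE)
    if (length(n$upstream) && !n$upstream %in% ids)
      stop(sprintf("node '%s' references unknown upstream '%s'",
                   n$node_id, n$upstream), call. = FALSE)
  }
  sources <- ids[vapply(p$nodes, function(n) length(n$upstream) == 0,
                        logical(1))]
  if (length(p$nodes) && length(sources) != 1)
    stop(sprintf("pipeline must have exactly one source node (found %d)",
                 length(sources)), call. = FALSE)
  # topological order (Kahn)
  order <- character(0)
  placed <- character(0)
  remaining <- p$nodes
  while (length(remaining)) {
    ready <- vapply(remaining, function(n)
      length(n$upstream) == 0 || all(n$upstream %in% placed), logical(1))
    if (!any(ready))
      stop("pipeline graph contains a cycle", call. = FALSE)
    ready_ids <- vapply(remaining[ready], `[[`, character(1), "node_id")
    order <- c(order, ready_ids)
    placed <- c(placed, ready_ids)
    remaining <- remaining[!ready]
  }
  if (check_types) {
    for (n in p$nodes)
      validate_node_params(get_node(n$node_type), n$params)
  }
  invisible(order)
}

#' @export
print.pipeline_spec <- function(x, ...) {
  cat(sprintf("<pipeline '%s' (v%s): %d node(s)>\n", x$name, x$version,
              length(x$nodes)))
  for (n in x$nodes)
    cat(sprintf("  %s [%s]%s\n", n$node_id, n$node_type,
                if (length(n$params))
                  paste0(" {", paste(names(n$params),
                                     vapply(n$params, format, character(1)),
                                     sep = "=", collapse = ", "), "}")
                else ""))
  invisible(x)
}

#' Shipped preset pipelines
#'
#' The five predefined workflows: `"svs_1h"` (single-voxel 1H: adaptive
#' coil combination, frequency/phase alignment around NAA, eddy-current
#' correction, bad-average removal, averaging), `"fmrs"` (as svs_1h but
#' finishing with blocked averaging for rest/active designs), `"p31_svs"`
#' (full-range alignment, averaging, entropy-minimization phasing),
#' `"p31_csi"` (3D Hanning k-space filter plus 5 Hz Gaussian line
#' broadening) and `"mega"` (GABA-edited data handled as direct averaging,
#' with an optional trailing manual adjustment).
#'
#' @param name Preset name.
#' @return A `pipeline_spec`.
#' @export
preset_pipeline <- function(name = c("svs_1h", "fmrs", "p31_svs", "p31_csi",
                                     "mega")) {
  name <- match.arg(name)
  switch(name,
    svs_1h = chain_pipeline(
      c("coil_combination", "frequency_phase_alignment",
        "eddy_current_correction", "bad_average_removal", "averaging"),
      params = list(
        coil_combination = list(method = "adaptive"),
        frequency_phase_alignment = list(ppm_min = 1.6, ppm_max = 3.6)),
      name = "svs_1h"),
    fmrs = chain_pipeline(
      c("coil_combination", "frequency_phase_alignment",
        "eddy_current_correction", "blocked_averaging"),
      params = list(
        coil_combination = list(method = "adaptive"),
        frequency_phase_alignment = list(ppm_min = 1.6, ppm_max = 3.6),
        blocked_averaging = list(meas_per_block = 16, avgs_per_block = 1,
                                 n_block_types = 2)),
      name = "fmrs"),
    p31_svs = chain_pipeline(
      c("frequency_phase_alignment", "averaging", "entropy_phasing"),
      name = "p31_svs"),
    p31_csi = chain_pipeline(
      c("hanning_filter_3d", "apodization"),
      params = list(apodization = list(shape = "gaussian", width_hz = 5)),
      name = "p31_csi"),
    mega = chain_pipeline(
      c("coil_combination", "frequency_phase_alignment",
        "eddy_current_correction", "bad_average_removal", "averaging",
        "manual_adjustment"),
      params = list(
        coil_combination = list(method = "adaptive"),
        frequency_phase_alignment = list(ppm_min = 1.6, ppm_max = 3.6)),
      name = "mega"))
}

# --- .pipe serialization ---------------------------------------------------

sort_names_rec <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && length(x))
      x <- x[order(names(x))]
    lapply(x, sort_names_rec)
  } else x
}

#' Save and load pipelines as .pipe files
#'
#' The on-disk dialect is canonical JSON (schema-versioned, object keys
#' sorted, stable number formatting), so save -> load -> save is
#' byte-identical. Loading validates the file: unknown node types and
#' out-of-range parameter values are errors.
#'
#' @param p A `pipeline_spec`.
#' @param path Path of the `.pipe` file.
#' @return `save_pipe()`: `path`, invisibly; `load_pipe()`: a validated
#'   `pipeline_spec`.
#' @export
save_pipe <- function(p, path) {
  stopifnot(inherits(p, "pipeline_spec"))
  doc <- list(
    format = "mrspipe.pipe",
    schema_version = 1L,
    name = p$name,
    version = p$version,
    nodes = lapply(p$nodes, function(n) {
      entry <- list(node_id = n$node_id, node_type = n$node_type,
                    params = n$params, upstream = as.list(n$upstream))
      sort_names_rec(entry)
    }))
  doc <- sort_names_rec(doc)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = 2, null = "null")
  writeLines(as.character(json), path)
  invisible(path)
}

#' @rdname save_pipe
#' @export
load_pipe <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$format) || doc$format != "mrspipe.pipe")
    stop(sprintf("'%s' is not a .pipe file", path), call. = FALSE)
  nodes <- lapply(doc$nodes, function(n)
    node_spec(n$node_id, n$node_type,
              params = lapply(n$params, identity),
              upstream = unlist(n$upstream) %||% character(0)))
  p <- pipeline(nodes, name = doc$name %||% "pipeline",
                version = doc$version %||% "1")
  validate_pipeline(p, check_types = TRUE)
  p
}
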