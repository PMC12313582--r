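# Node registry: maps node-type labels to plugin_node objects. Built-in
# nodes are registered when the package loads; custom nodes come from
# load_custom_nodes().
.registry <- new.env(parent = emptyenv())

#' Define a processing node
#'
#' A node is the unit of the pipeline graph. The contract has five parts:
#' (1) identifying information (`label`, `author`, `description`);
#' (2) a parameter schema declaring every adjustable parameter with its
#' type, default and range; (3) a `process` hook,
#' `function(input, params, context)`, that transforms one data payload (a
#' [transient_set] or [csi_grid]) and may return a list of payloads to fan
#' out (as the averaging nodes do); (4) an optional `plot` hook,
#' `function(input, output, params)`, drawn onto the active device for step
#' diagnostics; (5) registration via [register_node()].
#'
#' The `context` passed to `process` is an environment carrying the shared
#' run state: `water` (the water-reference [transient_set], kept in step
#' with e.g. coil combination), `adjust_log` (path of the manual-adjustment
#' log) and `extras` (per-node diagnostic results).
#'
#' Parameter schema entries are lists with fields `type` (one of
#' `"numeric"`, `"integer"`, `"string"`, `"choice"`, `"logical"`),
#' `default`, and optionally `min`, `max` (numeric types) or `choices`.
#'
#' @param label Unique node-type name.
#' @param author,description Free-text metadata.
#' @param params Parameter schema (possibly empty list).
#' @param process The processing hook (required).
#' @param plot Optional plotting hook.
#' @param builtin Internal flag.
#' @return An object of class `plugin_node`.
#' @export
plugin_node <- function(label, author, description, params = list(),
                        process, plot = NULL, builtin = FALSE) {
  if (missing(label) || !nzchar(label))
    stop("node needs a non-empty label", call. = FALSE)
  if (missing(process) || !is.function(process))
    stop(sprintf("node '%s' lacks a process hook", label), call. = FALSE)
  if (missing(author) || missing(description))
    stop(sprintf("node '%s' lacks author/description metadata", label),
         call. = FALSE)
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$type) ||
        !p$type %in% c("numeric", "integer", "string", "choice", "logical"))
      stop(sprintf("node '%s': parameter '%s' has no valid type", label, nm),
           call. = FALSE)
    if (!"default" %in% names(p))
      stop(sprintf("node '%s': parameter '%s' has no default", label, nm),
           call. = FALSE)
  }
  structure(list(label = label, author = author, description = description,
                 params = params, process = process, plot = plot,
                 builtin = builtin),
            class = "plugin_node")
}

#' Register, list and retrieve pipeline nodes
#'
#' `register_node()` adds a [plugin_node()] to the node library, making it
#' constructible by name in pipelines; a duplicate label is rejected unless
#' `overwrite = TRUE`. `list_nodes()` returns the current library;
#' `get_node()` fetches one entry.
#'
#' @param node A [plugin_node()].
#' @param overwrite Replace an existing registration with the same label.
#' @return `register_node()`: the node's label, invisibly.
#' @export
register_node <- function(node, overwrite = FALSE) {
  stopifnot(inherits(node, "plugin_node"))
  if (!overwrite && !is.null(.registry[[node$label]]))
    stop(sprintf("a node labelled '%s' is already registered", node$label),
         call. = FALSE)
  assign(node$label, node, envir = .registry)
  invisible(node$label)
}

#' @rdname register_node
#' @export
list_nodes <- function() {
  labels <- sort(ls(.registry))
  data.frame(
    label = labels,
    author = vapply(labels, function(l) .registry[[l]]$author, character(1)),
    description = vapply(labels, function(l) .registry[[l]]$description,
                         character(1)),
    builtin = vapply(labels, function(l) isTRUE(.registry[[l]]$builtin),
                     logical(1)),
    row.names = NULL)
}

#' @rdname register_node
#' @param label Node-type label.
#' @export
get_node <- function(label) {
  node <- .registry[[label]]
  if (is.null(node))
    stop(sprintf("unknown node type '%s'", label), call. = FALSE)
  node
}

#' @rdname register_node
#' @export
unregister_node <- function(label) {
  if (!is.null(.registry[[label]])) rm(list = label, envir = .registry)
  invisible(label)
}

#' Load custom nodes from the designated plugin folder
#'
#' Sources every `.R` file in `dir`; each file defines and registers one or
#' more nodes by calling `register_node(plugin_node(...))`. Rescanning the
#' same folder re-registers its nodes (registrations from the folder may
#' overwrite earlier ones, so editing a plugin file and rescanning picks up
#' the change). Only this one designated directory is scanned; arbitrary
#' script paths are not imported.
#'
#' @param dir Plugin directory (default: the `mrspipe.node_dir` option).
#' @return Character vector of labels registered, invisibly.
#' @export
load_custom_nodes <- function(dir = getOption("mrspipe.node_dir")) {
  if (is.null(dir) || !dir.exists(dir)) return(invisible(character(0)))
  before <- ls(.registry)
  loader_env <- new.env(parent = asNamespace("mrspipe"))
  loader_env$register_node <- function(node, overwrite = TRUE)
    register_node(node, overwrite = overwrite)
  files <- sort(list.files(dir, pattern = "\\.R$", full.names = TRUE))
  for (f in files) sys.source(f, envir = loader_env)
  invisible(setdiff(ls(.registry), before))
}

#' Validate node parameters against the declared schema
#'
#' Unknown keys, type mismatches and out-of-range values are errors;
#' missing parameters are filled from the declared defaults.
#'
#' @param node A [plugin_node()] (or its label).
#' @param params Named list of parameter values.
#' @return The completed parameter list.
#' @export
validate_node_params <- function(node, params = list()) {
  if (is.character(node)) node <- get_node(node)
  unknown <- setdiff(names(params), names(node$params))
  if (length(unknown))
    stop(sprintf("node '%s' declares no parameter(s): %s", node$label,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  out <- list()
  for (nm in names(node$params)) {
    schema <- node$params[[nm]]
    val <- if (nm %in% names(params)) params[[nm]] else schema$default
    if (schema$type %in% c("numeric", "integer") && !is.null(val) &&
        !all(is.na(val))) {
      if (!is.numeric(val))
        stop(sprintf("node '%s': parameter '%s' must be numeric",
                     node$label, nm), call. = FALSE)
      if (schema$type == "integer" && any(val %% 1 != 0))
        stop(sprintf("node '%s': parameter '%s' must be integer",
                     node$label, nm), call. = FALSE)
      if (!is.null(schema$min) && any(val < schema$min))
        stop(sprintf("node '%s': parameter '%s' = %s below minimum %s",
                     node$label, nm, val, schema$min), call. = FALSE)
      if (!is.null(schema$max) && any(val > schema$max))
        stop(sprintf("node '%s': parameter '%s' = %s above maximum %s",
                     node$label, nm, val, schema$max), call. = FALSE)
    }
    if (schema$type == "choice" && !is.null(schema$choices) &&
        !val %in% schema$choices)
      stop(sprintf("node '%s': parameter '%s' must be one of %s",
                   node$label, nm, paste(schema$choices, collapse = ", ")),
           call. = FALSE)
    out[[nm]] <- val
  }
  out
}
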