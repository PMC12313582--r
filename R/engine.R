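#' Execute a processing pipeline
#'
#' Runs the node graph over the input payload (a [transient_set] or
#' [csi_grid]) in topological order. Inputs are never mutated; every node is
#' deterministic given its input and parameters, so step mode and full mode
#' produce identical final data — step mode only adds an inspection
#' callback after each node. Averaging nodes may fan one payload out into
#' several; downstream nodes then apply to each.
#'
#' When `output_dir` is given, a copy of the executed pipeline is always
#' written there as `pipeline.pipe`, a manual-adjustment log is kept next to
#' it, and a `parameters.csv` records the acquisition and pipeline
#' provenance. With `save_intermediate`, each node additionally writes a
#' step subfolder (`step01_<type>/ ...`) holding the processed data
#' (`.RAW` once single-transient, NIfTI-MRS always) plus a diagnostic plot
#' (PDF) and its numerical data (CSV).
#'
#' A failing node aborts the run with an error naming the node id (batch
#' mode instead records the failure and continues, see [run_batch()]).
#'
#' @param input The source payload.
#' @param pipeline A `pipeline_spec` (see [pipeline()], [preset_pipeline()],
#'   [load_pipe()]).
#' @param water_ref Optional water-reference [transient_set]; follows the
#'   data through coil combination and feeds eddy-current correction.
#' @param mode `"full"` or `"step"`.
#' @param output_dir Optional output directory (created if needed).
#' @param save_intermediate Write per-step artifacts.
#' @param step_callback `function(node_id, payloads)` called after each node
#'   in step mode.
#' @return A list with class `pipeline_run`: `result` (list of final
#'   payloads), `extras` (per-node diagnostics such as alignment shifts),
#'   `log` (character), `water` (the water reference after shared
#'   processing), `output_dir`, `steps` (data frame of executed nodes).
#' @export
run_pipeline <- function(input, pipeline, water_ref = NULL,
                         mode = c("full", "step"), output_dir = NULL,
                         save_intermediate = FALSE, step_callback = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(pipeline, "pipeline_spec"))
  order <- validate_pipeline(pipeline, check_types = TRUE)
  by_id <- stats::setNames(pipeline$nodes,
                           vapply(pipeline$nodes, `[[`, character(1),
                                  "node_id"))

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    save_pipe(pipeline, file.path(output_dir, "pipeline.pipe"))
  }

  context <- new.env(parent = emptyenv())
  context$water <- water_ref
  context$extras <- list()
  context$log <- character(0)
  context$adjust_log <- if (!is.null(output_dir))
    file.path(output_dir, "adjustments.log") else NULL

  payloads <- list(input)
  steps <- list()
  for (i in seq_along(order)) {
    nspec <- by_id[[order[i]]]
    node <- get_node(nspec$node_type)
    params <- validate_node_params(node, nspec$params)
    extras_before <- context$extras
    context$extras <- list()
    out <- tryCatch({
      res <- lapply(payloads, function(pl) {
        r <- node$process(pl, params, context)
        if (payload_is_ts(r) || payload_is_csi(r)) list(r) else r
      })
      unlist(res, recursive = FALSE)
    }, error = function(e)
      stop(sprintf("node '%s' (%s) failed: %s", nspec$node_id,
                   nspec$node_type, conditionMessage(e)), call. = FALSE))
    node_extras <- context$extras
    context$extras <- c(extras_before,
                        if (length(node_extras))
                          stats::setNames(list(node_extras), nspec$node_id))
    if (!is.null(output_dir) && save_intermediate)
      write_step_artifacts(out, node, params,
                           file.path(output_dir,
                                     sprintf("step%02d_%s", i,
                                             nspec$node_type)),
                           before = payloads)
    payloads <- out
    steps[[i]] <- data.frame(step = i, node_id = nspec$node_id,
                             node_type = nspec$node_type,
                             n_outputs = length(out))
    if (mode == "step" && !is.null(step_callback))
      step_callback(nspec$node_id, payloads)
  }

  if (!is.null(output_dir))
    write_parameter_csv(input, pipeline,
                        file.path(output_dir, "parameters.csv"))

  structure(list(result = payloads, extras = context$extras,
                 log = context$log, water = context$water,
                 output_dir = output_dir,
                 steps = if (length(steps)) do.call(rbind, steps)
                         else data.frame()),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run: %d step(s), %d final payload(s)>\n",
              nrow(x$steps), length(x$result)))
  if (length(x$log)) cat(paste0("  note: ", x$log, "\n"), sep = "")
  invisible(x)
}
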