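# Output-tree writers: per-step artifact folders, parameter provenance CSV,
# LCModel folder assembly and CSI voxel folders.

write_step_artifacts <- function(payloads, node, params, dir,
                                 before = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(payloads)) {
    pl <- payloads[[k]]
    tag <- if (length(payloads) > 1) sprintf("_%03d", k) else ""
    if (payload_is_ts(pl)) {
      write_nifti_mrs(pl, file.path(dir, paste0("data", tag, ".nii.gz")))
      if (n_transients(pl) == 1L && n_channels(pl) == 1L)
        write_lcmodel_raw(pl, file.path(dir, paste0("data", tag, ".RAW")))
      if (n_channels(pl) == 1L) {
        sp <- fid_to_spectrum(pl, 1L)
        utils::write.csv(
          data.frame(ppm = sp$ppm_axis, hz = sp$hz_axis,
                     real = Re(sp$values), imag = Im(sp$values),
                     magnitude = Mod(sp$values)),
          file.path(dir, paste0("spectrum", tag, ".csv")),
          row.names = FALSE)
      }
    }
  }
  # diagnostic plot of the first payload
  pdf_path <- file.path(dir, "plot.pdf")
  grDevices::pdf(pdf_path, width = 7, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  if (!is.null(node$plot)) {
    first_before <- if (length(before)) before[[1]] else NULL
    try(node$plot(first_before, payloads[[1]], params), silent = TRUE)
  } else if (payload_is_ts(payloads[[1]]) &&
             n_channels(payloads[[1]]) == 1L) {
    try(plot_ts_payload(NULL, payloads[[1]], params), silent = TRUE)
  } else {
    graphics::plot.new()
    graphics::title(main = node$label)
  }
  invisible(dir)
}

write_parameter_csv <- function(input, pipeline, path) {
  rows <- if (payload_is_ts(input)) {
    data.frame(
      parameter = c("nucleus", "f0_mhz", "dwell_time_s", "bandwidth_hz",
                    "n_points", "n_channels", "n_transients", "te_ms",
                    "tr_ms", "sequence", "pipeline", "pipeline_nodes"),
      value = c(input$nucleus, input$f0, input$dwell_time,
                1 / input$dwell_time, n_points(input), n_channels(input),
                n_transients(input),
                input$acq_meta$te_ms %||% NA,
                input$acq_meta$tr_ms %||% NA,
                input$acq_meta$sequence %||% NA,
                pipeline$name,
                paste(vapply(pipeline$nodes, `[[`, character(1),
                             "node_type"), collapse = "|")))
  } else if (payload_is_csi(input)) {
    ms <- csi_matrix_size(input)
    data.frame(
      parameter = c("nucleus", "f0_mhz", "dwell_time_s", "bandwidth_hz",
                    "n_points", "matrix_size", "fov_mm", "pipeline",
                    "pipeline_nodes"),
      value = c(input$nucleus, input$f0, input$dwell_time,
                1 / input$dwell_time, dim(input$data)[4],
                paste(ms, collapse = "x"),
                paste(input$fov_mm, collapse = "x"), pipeline$name,
                paste(vapply(pipeline$nodes, `[[`, character(1),
                             "node_type"), collapse = "|")))
  } else {
    data.frame(parameter = "pipeline", value = pipeline$name)
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Assemble the LCModel folder of a run
#'
#' Writes the processed data (`.RAW`), the filled control file and — via
#' [run_fitter()] when an LCModel binary is configured — the `.COORD`
#' result into `<dir>/LCModel/`. Without a configured fitter the RAW and
#' control files are left in place with a logged notice, so the folder can
#' be fitted elsewhere.
#'
#' @param ts The final single-transient [transient_set].
#' @param dir Run output directory.
#' @param control_template Control-file template (text, lines or path).
#' @param overrides Control-parameter overrides (see
#'   [generate_control_file()]), e.g. `water_conc` from
#'   [water_concentration()].
#' @param basis_path Optional basis-set path, passed through to the control
#'   file.
#' @param tag Optional file-name tag distinguishing several spectra.
#' @return A list with the written paths and, when fitting ran, the parsed
#'   [quant_result].
#' @export
write_lcmodel_inputs <- function(ts, dir, control_template = NULL,
                                 overrides = list(), basis_path = NULL,
                                 tag = "") {
  lcdir <- file.path(dir, "LCModel")
  dir.create(lcdir, recursive = TRUE, showWarnings = FALSE)
  stem <- if (nzchar(tag)) paste0("spectrum_", tag) else "spectrum"
  raw_path <- file.path(lcdir, paste0(stem, ".RAW"))
  write_lcmodel_raw(ts, raw_path)
  control_path <- NULL
  if (!is.null(control_template)) {
    ov <- overrides
    if (!is.null(basis_path)) ov$basis <- basis_path
    control_path <- file.path(lcdir, paste0(stem, ".control"))
    generate_control_file(control_template, ts = ts, overrides = ov,
                          path = control_path)
  }
  coord_path <- file.path(lcdir, paste0(stem, ".COORD"))
  quant <- if (!is.null(control_path))
    run_fitter(raw_path, control_path, basis_path, coord_path = coord_path)
  list(raw = raw_path, control = control_path,
       coord = if (!is.null(quant)) coord_path else NULL, quant = quant)
}

#' Write per-voxel CSI outputs
#'
#' Stores each voxel of an image-space CSI grid in a dedicated subfolder
#' named by its 3D spatial coordinates (0-based, underscore-separated:
#' `0_0_0`, `1_0_0`, ...), each holding the voxel FID as `.RAW` for
#' voxel-by-voxel fitting.
#'
#' @param csi A [csi_grid] in image space.
#' @param dir Target directory.
#' @param min_amplitude Voxels whose FID never exceeds this magnitude are
#'   skipped (empty corners of the field of view).
#' @return Data frame of written voxels (`vx`, `vy`, `vz` 0-based, `path`).
#' @export
write_csi_voxel_outputs <- function(csi, dir, min_amplitude = 0) {
  stopifnot(inherits(csi, "csi_grid"))
  if (csi$state != "image")
    stop("transform to image space before writing voxel outputs",
         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ms <- csi_matrix_size(csi)
  rows <- list()
  for (k in seq_len(ms[3])) for (j in seq_len(ms[2]))
    for (i in seq_len(ms[1])) {
      fid <- csi$data[i, j, k, ]
      if (max(Mod(fid)) <= min_amplitude) next
      vdir <- file.path(dir, sprintf("%d_%d_%d", i - 1L, j - 1L, k - 1L))
      dir.create(vdir, showWarnings = FALSE)
      ts <- transient_set(fid, csi$dwell_time, csi$f0,
                          nucleus = csi$nucleus, ref_ppm = csi$ref_ppm)
      path <- file.path(vdir, "voxel.RAW")
      write_lcmodel_raw(ts, path)
      rows[[length(rows) + 1L]] <-
        data.frame(vx = i - 1L, vy = j - 1L, vz = k - 1L, path = path)
    }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(vx = integer(0), vy = integer(0), vz = integer(0),
                  path = character(0))
}

#' Collect per-voxel quantification results into a grid table
#'
#' Scans a directory of CSI voxel folders (`<vx>_<vy>_<vz>/`) for `.COORD`
#' files and assembles the tidy quantification grid consumed by
#' [metabolite_map()].
#'
#' @param dir Directory holding voxel folders.
#' @return Data frame with columns `vx`, `vy`, `vz` (0-based), `metabolite`,
#'   `concentration`, `crlb_pct`, `ratio`.
#' @export
collect_csi_quant <- function(dir) {
  vox_dirs <- list.dirs(dir, recursive = FALSE)
  vox_dirs <- vox_dirs[grepl("^\\d+_\\d+_\\d+$", basename(vox_dirs))]
  rows <- list()
  for (vd in vox_dirs) {
    coords <- list.files(vd, pattern = "\\.COORD$", full.names = TRUE)
    if (!length(coords)) next
    idx <- as.integer(strsplit(basename(vd), "_")[[1]])
    qr <- parse_coord(coords[1])
    rec <- qr$records
    rec$vx <- idx[1]
    rec$vy <- idx[2]
    rec$vz <- idx[3]
    rows[[length(rows) + 1L]] <- rec
  }
  if (!length(rows))
    return(data.frame(vx = integer(0), vy = integer(0), vz = integer(0),
                      metabolite = character(0), concentration = numeric(0),
                      crlb_pct = numeric(0), ratio = numeric(0)))
  out <- do.call(rbind, rows)
  out[, c("vx", "vy", "vz", "metabolite", "concentration", "crlb_pct",
          "ratio")]
}
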