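#' Create a structured batch folder system
#'
#' Lays out the study tree used by batch processing:
#' ```
#' STUDY_NAME/
#'   STUDY_NAME.control        (placeholder, replace with your control file)
#'   STUDY_NAME.basis          (placeholder, replace with your basis set)
#'   PARTICIPANT_1/
#'     <FILENAME>_metabolite.nii.gz        (required, user-supplied)
#'     <FILENAME>_water_reference.nii.gz   (optional)
#'     tissue_segmentation_files/          (optional)
#'       WM_prob.nii  GM_prob.nii  CSF_prob.nii
#'   PARTICIPANT_2/ ...
#' ```
#' The control and basis files live at study level; the user drops the
#' per-participant data files into place afterwards.
#'
#' @param root Writable directory the study folder is created in.
#' @param study_name Study name (no path separators).
#' @param n_participants Number of participant folders (>= 1).
#' @return The study directory path, invisibly.
#' @export
make_batch_folder <- function(root, study_name, n_participants) {
  if (grepl("[/\\\\]", study_name))
    stop("`study_name` must not contain path separators", call. = FALSE)
  if (!is.numeric(n_participants) || n_participants < 1 ||
      n_participants %% 1 != 0)
    stop("`n_participants` must be a positive integer", call. = FALSE)
  study_dir <- file.path(root, study_name)
  if (dir.exists(study_dir) && length(list.files(study_dir)))
    stop(sprintf("target '%s' exists and is not empty", study_dir),
         call. = FALSE)
  dir.create(study_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines("placeholder - replace with your LCModel control file",
             file.path(study_dir, paste0(study_name, ".control")))
  writeLines("placeholder - replace with your LCModel basis set",
             file.path(study_dir, paste0(study_name, ".basis")))
  for (k in seq_len(n_participants)) {
    pdir <- file.path(study_dir, sprintf("PARTICIPANT_%d", k))
    dir.create(pdir)
    dir.create(file.path(pdir, "tissue_segmentation_files"))
  }
  invisible(study_dir)
}

batch_supported_ext <- function() c("nii", "nii.gz", "raw")

#' Validate a batch folder before running
#'
#' Checks that the study-level `.control` and `.basis` files are present,
#' and per participant that exactly the required files are in place: a
#' metabolite file (name containing `_metabolite`) in a supported format
#' (NIfTI-MRS `.nii`/`.nii.gz` or LCModel `.RAW`). Optional water-reference
#' and tissue-segmentation files are reported when found. Problems are
#' reported, not thrown: the report marks each participant runnable or not.
#'
#' @param root Study directory (as created by [make_batch_folder()]).
#' @return A `batch_report`: list with `study_ok`, `missing_study_files`,
#'   and a data frame `participants` with columns `participant`,
#'   `metabolite_file`, `format_ok`, `water_file`, `tissue_ok`, `runnable`,
#'   `messages`.
#' @export
validate_batch_folder <- function(root) {
  if (!dir.exists(root))
    stop(sprintf("batch folder '%s' does not exist", root), call. = FALSE)
  study <- basename(normalizePath(root))
  missing_study <- character(0)
  for (ext in c("control", "basis")) {
    if (!length(list.files(root, pattern = paste0("\\.", ext, "$"))))
      missing_study <- c(missing_study, paste0(".", ext))
  }
  pdirs <- sort(list.dirs(root, recursive = FALSE))
  pdirs <- pdirs[grepl("^PARTICIPANT_", basename(pdirs))]
  rows <- lapply(pdirs, function(pd) {
    msgs <- character(0)
    metab <- list.files(pd, pattern = "_metabolite")
    metab <- metab[!dir.exists(file.path(pd, metab))]
    water <- list.files(pd, pattern = "_water_reference")
    format_ok <- FALSE
    if (!length(metab)) {
      msgs <- c(msgs, "metabolite file missing")
    } else {
      ext <- tolower(sub("^[^.]*\\.", "", metab[1]))
      format_ok <- ext %in% batch_supported_ext()
      if (!format_ok)
        msgs <- c(msgs, sprintf("unsupported metabolite format '.%s'", ext))
    }
    tdir <- file.path(pd, "tissue_segmentation_files")
    tissue_ok <- dir.exists(tdir) &&
      all(file.exists(file.path(tdir, c("WM_prob.nii", "GM_prob.nii",
                                        "CSF_prob.nii"))))
    data.frame(
      participant = basename(pd),
      metabolite_file = if (length(metab)) metab[1] else NA_character_,
      format_ok = format_ok,
      water_file = if (length(water)) water[1] else NA_character_,
      tissue_ok = tissue_ok,
      runnable = length(metab) > 0 && format_ok,
      messages = paste(msgs, collapse = "; "))
  })
  participants <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant = character(0), metabolite_file = character(0),
               format_ok = logical(0), water_file = character(0),
               tissue_ok = logical(0), runnable = logical(0),
               messages = character(0))
  structure(list(study = study, study_ok = length(missing_study) == 0,
                 missing_study_files = missing_study,
                 participants = participants),
            class = "batch_report")
}

#' @export
print.batch_report <- function(x, ...) {
  cat(sprintf("<batch_report: study '%s'>\n", x$study))
  if (!x$study_ok)
    cat("  missing study files:",
        paste(x$missing_study_files, collapse = ", "), "\n")
  print(x$participants, row.names = FALSE)
  invisible(x)
}

#' Run a pipeline over every participant of a batch folder
#'
#' Applies the identical pipeline to each runnable participant, using the
#' water reference and tissue-segmentation files when present (water feeds
#' coil combination and eddy-current correction; tissue fractions set the
#' water concentration in the control file). Per-participant failures are
#' caught, recorded as one JSON line each in `<output>/errors.jsonl`
#' (fields `participant`, `node_id`, `message`), and the remaining
#' participants keep processing. Rerunning on the same inputs reproduces
#' identical outputs.
#'
#' @param root Study directory.
#' @param pipeline A `pipeline_spec`.
#' @param output_root Output directory (default `<root>/outputs`).
#' @param save_intermediate Write per-step artifacts for each participant.
#' @return A list with `results` (named per participant: `pipeline_run` or
#'   `NULL` on failure), `errors` (data frame), `report` (the validation
#'   report).
#' @export
run_batch <- function(root, pipeline, output_root = file.path(root, "outputs"),
                      save_intermediate = FALSE) {
  report <- validate_batch_folder(root)
  runnable <- report$participants[report$participants$runnable, ]
  if (nrow(runnable) == 0)
    stop("no runnable participant in the batch folder", call. = FALSE)
  dir.create(output_root, recursive = TRUE, showWarnings = FALSE)
  ledger_path <- file.path(output_root, "errors.jsonl")
  if (file.exists(ledger_path)) unlink(ledger_path)

  control_file <- list.files(root, pattern = "\\.control$",
                             full.names = TRUE)
  basis_file <- list.files(root, pattern = "\\.basis$", full.names = TRUE)

  results <- list()
  errors <- list()
  for (i in seq_len(nrow(runnable))) {
    pid <- runnable$participant[i]
    pdir <- file.path(root, pid)
    out_dir <- file.path(output_root, pid)
    res <- tryCatch({
      metab <- read_batch_input(file.path(pdir, runnable$metabolite_file[i]))
      water <- if (!is.na(runnable$water_file[i]))
        read_batch_input(file.path(pdir, runnable$water_file[i])) else NULL
      run <- run_pipeline(metab, pipeline, water_ref = water,
                          output_dir = out_dir,
                          save_intermediate = save_intermediate)
      # assemble LCModel inputs when control template is usable and the
      # final payloads are fit-ready
      if (length(control_file) == 1 &&
          !grepl("placeholder", readLines(control_file, n = 1))) {
        overrides <- list()
        if (runnable$tissue_ok[i]) {
          tf <- batch_tissue_fractions(pdir)
          if (!is.null(tf))
            overrides$water_conc <- water_concentration(tf)
        }
        for (k in seq_along(run$result)) {
          pl <- run$result[[k]]
          if (payload_is_ts(pl) && n_transients(pl) == 1L &&
              n_channels(pl) == 1L)
            write_lcmodel_inputs(
              pl, out_dir, control_template = control_file,
              overrides = overrides,
              basis_path = if (length(basis_file)) basis_file else NULL,
              tag = if (length(run$result) > 1) sprintf("%03d", k) else "")
        }
      }
      run
    }, error = function(e) {
      entry <- list(participant = pid, node_id = NA, message = conditionMessage(e))
      cat(as.character(jsonlite::toJSON(entry, auto_unbox = TRUE)), "\n",
          file = ledger_path, sep = "", append = TRUE)
      errors[[length(errors) + 1L]] <<- as.data.frame(entry,
                                                      stringsAsFactors = FALSE)
      NULL
    })
    results[[pid]] <- res
  }
  list(results = results,
       errors = if (length(errors)) do.call(rbind, errors) else
         data.frame(participant = character(0), node_id = character(0),
                    message = character(0)),
       report = report)
}

read_batch_input <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    return(read_nifti_mrs(path))
  stop(sprintf("unsupported input format for '%s'", basename(path)),
       call. = FALSE)
}

batch_tissue_fractions <- function(pdir) {
  tdir <- file.path(pdir, "tissue_segmentation_files")
  paths <- file.path(tdir, c("GM_prob.nii", "WM_prob.nii", "CSF_prob.nii"))
  if (!all(file.exists(paths))) return(NULL)
  vols <- lapply(paths, function(p) as.array(RNifti::readNifti(p)))
  d <- dim(vols[[1]])
  voxel_tissue_fractions(vols[[1]], vols[[2]], vols[[3]],
                         voxel_box = list(x = c(1, d[1]), y = c(1, d[2]),
                                          z = c(1, d[3])))
}
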