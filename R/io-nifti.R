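#' Read and write NIfTI-MRS files
#'
#' Serializes a [transient_set] as a NIfTI-1 file with complex time-domain
#' data laid out `[x, y, z, time, coil, dynamic]` (singleton spatial
#' dimensions for single-voxel data), the dwell time in `pixdim[4]`, and the
#' MRS metadata carried in the standard JSON header extension (ecode 44):
#' `SpectrometerFrequency` (MHz), `ResonantNucleus`, and the dimension tags
#' `dim_5 = "DIM_COIL"`, `dim_6 = "DIM_DYN"`. The round trip is lossless for
#' the data (complex128 on disk) and exact for the required metadata.
#'
#' Only time-domain storage is supported: files tagged as frequency-domain
#' are rejected. Vendor raw formats are out of scope; convert externally
#' (e.g. with spec2nii) and import the resulting NIfTI-MRS.
#'
#' @param ts A [transient_set].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `write_nifti_mrs()` returns `path` invisibly;
#'   `read_nifti_mrs()` returns a [transient_set].
#' @export
write_nifti_mrs <- function(ts, path) {
  validate_transient_set(ts)
  np <- n_points(ts)
  nc <- n_channels(ts)
  nt <- n_transients(ts)
  # [x, y, z, time, coil, dyn]
  arr <- array(0 + 0i, dim = c(1L, 1L, 1L, np, nc, nt))
  arr[1, 1, 1, , , ] <- aperm(ts$data, c(3, 2, 1))
  img <- RNifti::asNifti(arr)

  voxel <- ts$acq_meta$voxel_mm %||% c(1, 1, 1)
  # RNifti trims trailing singleton dimensions; match pixdim to what's left
  pd <- c(voxel, ts$dwell_time, 1, 1)[seq_along(dim(img))]
  RNifti::pixdim(img) <- pd

  hdr <- list(
    SpectrometerFrequency = ts$f0,
    ResonantNucleus = ts$nucleus,
    # dwell lives in pixdim[4] per the format; the float32 header rounds
    # it, so the exact double is carried here as well
    DwellTime = ts$dwell_time,
    SpectralDomain = "TIME",
    dim_5 = "DIM_COIL",
    dim_6 = "DIM_DYN",
    RefPpm = ts$ref_ppm,
    Role = ts$role)
  if (!is.null(ts$acq_meta$te_ms)) hdr$EchoTime <- ts$acq_meta$te_ms / 1000
  if (!is.null(ts$acq_meta$tr_ms))
    hdr$RepetitionTime <- ts$acq_meta$tr_ms / 1000
  if (!is.null(ts$acq_meta$sequence)) hdr$SequenceName <- ts$acq_meta$sequence
  json <- jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA)
  RNifti::extension(img, 44L) <- charToRaw(as.character(json))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_mrs
#' @export
read_nifti_mrs <- function(path) {
  img <- RNifti::readNifti(path)
  ext <- RNifti::extension(img, 44L, mode = "raw")
  if (is.null(ext))
    stop("not a NIfTI-MRS file: JSON header extension (ecode 44) is missing",
         call. = FALSE)
  if (is.list(ext)) ext <- ext[[1]]
  hdr <- jsonlite::fromJSON(rawToChar(ext))
  for (field in c("SpectrometerFrequency", "ResonantNucleus")) {
    if (is.null(hdr[[field]]))
      stop(sprintf("NIfTI-MRS header extension lacks required field '%s'",
                   field), call. = FALSE)
  }
  if (!is.null(hdr$SpectralDomain) &&
      toupper(hdr$SpectralDomain) != "TIME")
    stop("frequency-domain NIfTI-MRS data are not supported", call. = FALSE)

  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) < 4L)
    stop("NIfTI-MRS data must have a time dimension (dim 4)", call. = FALSE)
  d <- c(d, rep(1L, 6 - length(d)))
  dim(arr) <- d
  if (any(d[1:3] != 1L))
    stop("only single-voxel NIfTI-MRS layouts are supported here",
         call. = FALSE)
  data <- aperm(array(arr, dim = d[4:6]), c(3, 2, 1))  # [dyn, coil, time]

  dwell <- if (!is.null(hdr$DwellTime)) as.numeric(hdr$DwellTime)
           else as.numeric(RNifti::pixdim(img)[4])
  f0 <- as.numeric(hdr$SpectrometerFrequency)[1]
  nucleus <- as.character(hdr$ResonantNucleus)[1]
  acq <- list()
  if (!is.null(hdr$EchoTime)) acq$te_ms <- hdr$EchoTime * 1000
  if (!is.null(hdr$RepetitionTime)) acq$tr_ms <- hdr$RepetitionTime * 1000
  if (!is.null(hdr$SequenceName)) acq$sequence <- hdr$SequenceName
  transient_set(
    data, dwell_time = dwell, f0 = f0, nucleus = nucleus,
    ref_ppm = if (!is.null(hdr$RefPpm)) hdr$RefPpm else
      default_ref_ppm(nucleus),
    role = if (!is.null(hdr$Role)) hdr$Role else "metabolite",
    acq_meta = acq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
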