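#' CRLB-thresholded metabolite concentration map
#'
#' Extracts one 2D slice of per-voxel concentrations from a quantification
#' grid (see [collect_csi_quant()]), masking out unreliable voxels: a voxel
#' is shown only if the CRLB of the selected metabolite is strictly below
#' the threshold, and — when a reference metabolite is set — the
#' reference's CRLB passes the same test. With `as_ratio`, the map shows
#' the concentration ratio metabolite/reference instead of the absolute
#' concentration. Raising the threshold can only grow the mask.
#'
#' @param quant_grid Data frame with columns `vx`, `vy`, `vz` (0-based
#'   voxel indices), `metabolite`, `concentration`, `crlb_pct`.
#' @param metabolite Metabolite to map.
#' @param reference Optional reference metabolite (required for
#'   `as_ratio`).
#' @param crlb_threshold_pct CRLB threshold in percent (strict `<`).
#' @param orientation Slice orientation: `"axial"` (fixed `vz`),
#'   `"coronal"` (fixed `vy`) or `"sagittal"` (fixed `vx`).
#' @param slice_idx 0-based index of the slice along the fixed axis.
#' @param as_ratio Map the ratio to the reference instead of the
#'   concentration.
#' @return An object of class `metabolite_map`: `values` (matrix, `NA`
#'   outside the mask), `mask` (logical matrix), `orientation`,
#'   `slice_idx`, `metabolite`, `reference`, `scale_bounds`.
#' @export
metabolite_map <- function(quant_grid, metabolite, reference = NULL,
                           crlb_threshold_pct = 20,
                           orientation = c("axial", "coronal", "sagittal"),
                           slice_idx = 0, as_ratio = FALSE) {
  orientation <- match.arg(orientation)
  if (as_ratio && is.null(reference))
    stop("`as_ratio` requires a reference metabolite", call. = FALSE)
  if (!metabolite %in% quant_grid$metabolite)
    stop(sprintf("metabolite '%s' not present in the quantification grid",
                 metabolite), call. = FALSE)
  if (!is.null(reference) && !reference %in% quant_grid$metabolite)
    stop(sprintf("reference metabolite '%s' not present", reference),
         call. = FALSE)

  fixed <- switch(orientation, axial = "vz", coronal = "vy",
                  sagittal = "vx")
  inplane <- setdiff(c("vx", "vy", "vz"), fixed)
  sl <- quant_grid[quant_grid[[fixed]] == slice_idx, ]
  n1 <- max(quant_grid[[inplane[1]]]) + 1L
  n2 <- max(quant_grid[[inplane[2]]]) + 1L
  values <- matrix(NA_real_, n1, n2)
  mask <- matrix(FALSE, n1, n2)

  met <- sl[sl$metabolite == metabolite, ]
  ref <- if (!is.null(reference)) sl[sl$metabolite == reference, ]
  for (r in seq_len(nrow(met))) {
    i <- met[[inplane[1]]][r] + 1L
    j <- met[[inplane[2]]][r] + 1L
    ok <- met$crlb_pct[r] < crlb_threshold_pct
    ref_row <- NULL
    if (!is.null(ref)) {
      hit <- ref[[inplane[1]]] == met[[inplane[1]]][r] &
        ref[[inplane[2]]] == met[[inplane[2]]][r]
      ref_row <- ref[hit, ]
      ok <- ok && nrow(ref_row) > 0 &&
        ref_row$crlb_pct[1] < crlb_threshold_pct
    }
    if (ok) {
      mask[i, j] <- TRUE
      values[i, j] <- if (as_ratio)
        met$concentration[r] / ref_row$concentration[1]
      else met$concentration[r]
    }
  }
  structure(list(values = values, mask = mask, orientation = orientation,
                 slice_idx = slice_idx, metabolite = metabolite,
                 reference = reference,
                 scale_bounds = if (any(mask)) range(values[mask])
                                else c(NA_real_, NA_real_)),
            class = "metabolite_map")
}

#' @export
print.metabolite_map <- function(x, ...) {
  cat(sprintf(
    "<metabolite_map: %s%s, %s slice %d, %d x %d, %d voxel(s) shown>\n",
    x$metabolite,
    if (!is.null(x$reference)) paste0(" / ", x$reference) else "",
    x$orientation, x$slice_idx, nrow(x$values), ncol(x$values),
    sum(x$mask)))
  invisible(x)
}

#' Project a metabolite map onto an anatomical slice
#'
#' Bilinearly interpolates the (coarse) metabolite map to the resolution of
#' an anatomical image slice, excluding masked-out voxels from the
#' interpolation support (normalised convolution: contributions are
#' weighted by the mask, so unreliable voxels never leak into the map).
#' Interpolated values therefore stay within the range of the input map.
#' With no anatomical slice the raw concentration matrix is returned
#' unchanged, without any interpolation. An optional brain mask at
#' anatomical resolution blanks everything outside the brain.
#'
#' @param map A [metabolite_map()].
#' @param anat_slice Optional anatomical slice (matrix), at least as large
#'   as the map in both dimensions; only its dimensions are used.
#' @param brain_mask Optional logical matrix of the anatomical dimensions.
#' @return A `metabolite_map` at the anatomical resolution (or `map`
#'   itself when `anat_slice` is `NULL`).
#' @export
project_to_anatomy <- function(map, anat_slice = NULL, brain_mask = NULL) {
  stopifnot(inherits(map, "metabolite_map"))
  if (is.null(anat_slice)) return(map)
  out_dim <- dim(anat_slice)
  if (any(out_dim < dim(map$values)))
    stop("anatomical slice must be at least as large as the map",
         call. = FALSE)
  if (!is.null(brain_mask) && !identical(dim(brain_mask), out_dim))
    stop("brain mask dimensions must match the anatomical slice",
         call. = FALSE)

  vin <- map$values
  vin[!map$mask] <- 0
  win <- matrix(as.numeric(map$mask), nrow(map$mask), ncol(map$mask))
  nin <- dim(map$values)

  values <- matrix(NA_real_, out_dim[1], out_dim[2])
  mask <- matrix(FALSE, out_dim[1], out_dim[2])
  for (j in seq_len(out_dim[2])) {
    yc <- (j - 0.5) * nin[2] / out_dim[2] + 0.5
    j0 <- floor(yc)
    fy <- yc - j0
    j1 <- min(max(j0, 1L), nin[2])
    j2 <- min(j0 + 1L, nin[2])
    if (j0 < 1) { j1 <- j2 <- 1L; fy <- 0 }
    for (i in seq_len(out_dim[1])) {
      xc <- (i - 0.5) * nin[1] / out_dim[1] + 0.5
      i0 <- floor(xc)
      fx <- xc - i0
      i1 <- min(max(i0, 1L), nin[1])
      i2 <- min(i0 + 1L, nin[1])
      if (i0 < 1) { i1 <- i2 <- 1L; fx <- 0 }
      w <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy) *
        c(win[i1, j1], win[i2, j1], win[i1, j2], win[i2, j2])
      if (sum(w) > 0) {
        v <- c(vin[i1, j1], vin[i2, j1], vin[i1, j2], vin[i2, j2])
        val <- sum(w * v) / sum(w)
        if (is.null(brain_mask) || isTRUE(brain_mask[i, j])) {
          values[i, j] <- val
          mask[i, j] <- TRUE
        }
      }
    }
  }
  structure(list(values = values, mask = mask,
                 orientation = map$orientation, slice_idx = map$slice_idx,
                 metabolite = map$metabolite, reference = map$reference,
                 scale_bounds = if (any(mask)) range(values[mask])
                                else c(NA_real_, NA_real_)),
            class = "metabolite_map")
}

#' Export a metabolite map as CSV
#'
#' Long-format export (`row`, `col`, `value`, `masked`) for downstream
#' plotting or testing.
#'
#' @param map A [metabolite_map()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "metabolite_map"))
  idx <- expand.grid(row = seq_len(nrow(map$values)),
                     col = seq_len(ncol(map$values)))
  utils::write.csv(
    data.frame(row = idx$row, col = idx$col,
               value = map$values[cbind(idx$row, idx$col)],
               masked = !map$mask[cbind(idx$row, idx$col)]),
    path, row.names = FALSE)
  invisible(path)
}
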