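#' Tissue fractions within an MRS voxel
#'
#' Averages co-registered gray-matter, white-matter and CSF probability
#' volumes over the spatial extent of the MRS voxel, giving the voxel
#' composition used for water-concentration scaling. Fractions are
#' renormalised to sum to at most 1.
#'
#' @param gm_vol,wm_vol,csf_vol 3D probability arrays (values in `[0, 1]`,
#'   identical dimensions); RNifti images are accepted.
#' @param voxel_box The voxel extent in volume indices:
#'   `list(x = c(lo, hi), y = c(lo, hi), z = c(lo, hi))`, 1-based inclusive.
#' @return An object of class `tissue_fractions` with fields `f_gm`,
#'   `f_wm`, `f_csf`.
#' @export
voxel_tissue_fractions <- function(gm_vol, wm_vol, csf_vol, voxel_box) {
  gm <- as.array(gm_vol)
  wm <- as.array(wm_vol)
  csf <- as.array(csf_vol)
  if (!identical(dim(gm), dim(wm)) || !identical(dim(gm), dim(csf)))
    stop("tissue probability volumes differ in shape", call. = FALSE)
  d <- dim(gm)
  bx <- lapply(c("x", "y", "z"), function(a) voxel_box[[a]])
  for (a in 1:3) {
    if (is.null(bx[[a]]) || length(bx[[a]]) != 2)
      stop("`voxel_box` needs x, y, z ranges", call. = FALSE)
    if (bx[[a]][1] < 1 || bx[[a]][2] > d[a] || bx[[a]][1] > bx[[a]][2])
      stop("voxel extent lies outside the volume", call. = FALSE)
  }
  ix <- seq(bx[[1]][1], bx[[1]][2])
  iy <- seq(bx[[2]][1], bx[[2]][2])
  iz <- seq(bx[[3]][1], bx[[3]][2])
  f <- c(gm = mean(gm[ix, iy, iz]), wm = mean(wm[ix, iy, iz]),
         csf = mean(csf[ix, iy, iz]))
  tot <- sum(f)
  if (tot > 1) f <- f / tot
  structure(list(f_gm = unname(f["gm"]), f_wm = unname(f["wm"]),
                 f_csf = unname(f["csf"])),
            class = "tissue_fractions")
}

#' @export
print.tissue_fractions <- function(x, ...) {
  cat(sprintf("<tissue_fractions: GM %.3f, WM %.3f, CSF %.3f>\n",
              x$f_gm, x$f_wm, x$f_csf))
  invisible(x)
}

#' Voxel water concentration from tissue fractions
#'
#' Computes the water concentration passed to the fitter (`WCONC`) from the
#' voxel composition, using the conventional tissue water contents relative
#' to pure water (GM 0.78, WM 0.65, CSF 0.97; pure water 55510 mM):
#' \deqn{WCONC = 55510 \cdot
#'   \frac{0.78 f_{GM} + 0.65 f_{WM} + 0.97 f_{CSF}}
#'        {f_{GM} + f_{WM} + f_{CSF}} \; \mathrm{mM}.}
#' Relaxation attenuation corrections are deliberately not folded in; all
#' four constants can be overridden to apply site- or field-specific
#' values.
#'
#' @param tf A [voxel_tissue_fractions()] result (or a list with `f_gm`,
#'   `f_wm`, `f_csf`).
#' @param water_content Named vector of relative water contents
#'   (`gm`, `wm`, `csf`).
#' @param pure_water_mM Water concentration of pure water.
#' @return Water concentration in mM.
#' @export
water_concentration <- function(tf,
                                water_content = c(gm = 0.78, wm = 0.65,
                                                  csf = 0.97),
                                pure_water_mM = 55510) {
  f <- c(tf$f_gm, tf$f_wm, tf$f_csf)
  if (any(f < 0) || any(f > 1))
    stop("tissue fractions must lie in [0, 1]", call. = FALSE)
  tot <- sum(f)
  if (tot <= 0)
    stop("total tissue fraction is zero", call. = FALSE)
  pure_water_mM *
    sum(water_content[c("gm", "wm", "csf")] * f) / tot
}

#' Invoke the external spectral fitter
#'
#' Subprocess contract for LCModel (or a compatible stand-in): the
#' configured binary is run with the control file on its standard input and
#' is expected to produce the `.COORD` file, which is then parsed. Fitting
#' is optional infrastructure: when no binary is configured (option
#' `mrspipe.lcmodel`, falling back to `lcmodel` on the PATH), the run
#' degrades gracefully — a notice is emitted, the RAW/control files stay in
#' place for external fitting, and `NULL` is returned. A nonzero exit
#' status raises a warning and returns `NULL`.
#'
#' @param raw_path Path to the written `.RAW` data.
#' @param control_path Path to the filled control file.
#' @param basis_path Optional basis-set path (already referenced inside the
#'   control file; passed for provenance).
#' @param coord_path Where the `.COORD` output is expected.
#' @param fitter Path of the fitter binary; `""`/`NULL` means unconfigured.
#' @return A [quant_result], or `NULL` when fitting did not run.
#' @export
run_fitter <- function(raw_path, control_path, basis_path = NULL,
                       coord_path = sub("\\.[^.]*$", ".COORD", raw_path),
                       fitter = getOption("mrspipe.lcmodel",
                                          Sys.which("lcmodel"))) {
  if (is.null(fitter) || !nzchar(fitter)) {
    message("no LCModel binary configured; leaving RAW and control files ",
            "for external fitting")
    return(invisible(NULL))
  }
  status <- suppressWarnings(
    system2(fitter, stdin = control_path, stdout = FALSE, stderr = FALSE,
            env = c(paste0("MRSPIPE_RAW=", raw_path),
                    paste0("MRSPIPE_COORD=", coord_path))))
  if (!identical(status, 0L)) {
    warning(sprintf("fitter exited with status %s", status), call. = FALSE)
    return(invisible(NULL))
  }
  if (!file.exists(coord_path)) {
    warning("fitter produced no .COORD file", call. = FALSE)
    return(invisible(NULL))
  }
  parse_coord(coord_path)
}
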