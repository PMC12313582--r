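#' 3D Hanning filter for CSI k-space
#'
#' Multiplies the k-space grid by the separable window
#' \eqn{H(x) H(y) H(z)} with, along a dimension of size \eqn{w},
#' \deqn{H(j) = \tfrac12\left(1 + \cos\frac{2\pi (j - c)}{w - 1}\right),
#'   \quad c = \lfloor w/2 \rfloor,}
#' i.e. the symmetric Hanning taper anchored so the k-space centre sample
#' gets weight exactly 1 (integer-centre alignment for even sizes). All
#' weights lie in \eqn{[0, 1]}. Filtering suppresses Gibbs ringing at the
#' cost of a broader spatial point-spread function (see [csi_psf()]).
#'
#' @param csi A [csi_grid] in k-space state.
#' @param window_size Length-3 window dimensions; must equal the matrix
#'   size.
#' @return The filtered [csi_grid], still in k-space.
#' @export
hanning_filter_3d <- function(csi, window_size = csi_matrix_size(csi)) {
  stopifnot(inherits(csi, "csi_grid"))
  if (csi$state != "kspace")
    stop("Hanning filtering applies in k-space; call csi_to_kspace() first",
         call. = FALSE)
  ms <- csi_matrix_size(csi)
  if (!identical(as.integer(window_size), as.integer(ms)))
    stop(sprintf("window size (%s) must equal the matrix size (%s)",
                 paste(window_size, collapse = "x"),
                 paste(ms, collapse = "x")), call. = FALSE)
  w1 <- hanning_weights(ms[1])
  w2 <- hanning_weights(ms[2])
  w3 <- hanning_weights(ms[3])
  W <- outer(outer(w1, w2), w3)
  for (tt in seq_len(dim(csi$data)[4]))
    csi$data[, , , tt] <- array(csi$data[, , , tt, drop = FALSE],
                                dim = ms) * W
  csi
}

# Symmetric Hanning taper, centre weight 1 at index floor(w/2)+1 (1-based).
hanning_weights <- function(w) {
  if (w == 1L) return(1)
  j <- seq_len(w) - 1
  c0 <- floor(w / 2)
  0.5 * (1 + cos(2 * pi * (j - c0) / (w - 1)))
}

#' Spatial point-spread function of a CSI grid
#'
#' The image of a uniformly filled k-space (the response to a point source
#' under the given k-space weighting). `psf_fwhm()` measures the full width
#' at half maximum of the PSF magnitude along one axis through its peak, in
#' voxel units with linear interpolation; Hanning weighting broadens it.
#'
#' @param matrix_size Length-3 grid dimensions.
#' @param weights Optional k-space weighting array (e.g. the Hanning
#'   window); `NULL` for the unfiltered grid.
#' @return `csi_psf()`: numeric array of PSF magnitude (peak at the centre
#'   voxel). `psf_fwhm()`: FWHM in voxels.
#' @export
csi_psf <- function(matrix_size, weights = NULL) {
  k <- array(1 + 0i, dim = matrix_size)
  if (!is.null(weights)) {
    stopifnot(identical(dim(weights), as.integer(matrix_size)) ||
                identical(dim(weights), matrix_size))
    k <- k * weights
  }
  img <- stats::fft(fftshift3(k, inverse = TRUE), inverse = TRUE) /
    prod(matrix_size)
  fftshift3(Mod(img))
}

#' @rdname csi_psf
#' @param psf A PSF array from `csi_psf()`.
#' @param axis Which axis to measure along (1, 2 or 3).
#' @export
psf_fwhm <- function(psf, axis = 1L) {
  ctr <- floor(dim(psf) / 2) + 1
  profile <- switch(axis,
                    psf[, ctr[2], ctr[3]],
                    psf[ctr[1], , ctr[3]],
                    psf[ctr[1], ctr[2], ])
  peak <- which.max(profile)
  half <- profile[peak] / 2
  cross <- function(step) {
    i <- peak
    repeat {
      j <- i + step
      if (j < 1L || j > length(profile)) return(abs(j - peak) - 0.5)
      if (profile[j] <= half) break
      i <- j
    }
    frac <- (profile[i] - half) / (profile[i] - profile[j])
    abs(i - peak) + frac
  }
  cross(-1L) + cross(+1L)
}

#' Construct the separable 3D Hanning window array
#'
#' @param matrix_size Length-3 dimensions.
#' @return Numeric array of weights in `[0, 1]` with centre weight 1.
#' @export
hanning_window_3d <- function(matrix_size) {
  outer(outer(hanning_weights(matrix_size[1]),
              hanning_weights(matrix_size[2])),
        hanning_weights(matrix_size[3]))
}
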