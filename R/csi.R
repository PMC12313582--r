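#' 3D chemical-shift imaging grid
#'
#' A spatial grid of FIDs with an explicit k-space / image-space state flag.
#' CSI data are filtered in k-space (see [hanning_filter_3d()]) and
#' spatially Fourier-transformed to image space before per-voxel fitting.
#'
#' @param data Complex array `[nx, ny, nz, n_points]`.
#' @param state Either `"image"` or `"kspace"`.
#' @param dwell_time,f0,nucleus,ref_ppm Spectral metadata as in
#'   [transient_set()].
#' @param fov_mm Field of view, length 3, millimetres.
#' @return An object of class `csi_grid`.
#' @export
csi_grid <- function(data, state = c("image", "kspace"), dwell_time, f0,
                     nucleus = "31P", ref_ppm = default_ref_ppm(nucleus),
                     fov_mm = c(200, 200, 80)) {
  state <- match.arg(state)
  if (length(dim(data)) != 4L)
    stop("`data` must be a [nx, ny, nz, n_points] array", call. = FALSE)
  storage.mode(data) <- "complex"
  stopifnot(dwell_time > 0, f0 > 0, length(fov_mm) == 3L)
  structure(list(data = data, state = state, dwell_time = dwell_time,
                 f0 = f0, nucleus = nucleus, ref_ppm = ref_ppm,
                 fov_mm = fov_mm),
            class = "csi_grid")
}

#' @export
print.csi_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<csi_grid: %d x %d x %d voxels x %d points, %s space>\n",
              d[1], d[2], d[3], d[4], x$state))
  invisible(x)
}

csi_matrix_size <- function(csi) dim(csi$data)[1:3]

# --- spatial DFT -----------------------------------------------------------
# k-space layout is fftshifted: the k-space centre sits at index
# floor(n/2) + 1 along each dimension, which is also where the Hanning
# window is anchored.

shift_perm <- function(n, inverse = FALSE) {
  s <- floor(n / 2)
  if (inverse) ((seq_len(n) - 1 - s) %% n) + 1
  else ((seq_len(n) - 1 + s) %% n) + 1
}

fftshift3 <- function(arr, inverse = FALSE) {
  d <- dim(arr)
  arr[shift_perm(d[1], inverse), shift_perm(d[2], inverse),
      shift_perm(d[3], inverse), drop = FALSE]
}

#' Transform a CSI grid between image space and k-space
#'
#' `csi_to_kspace()` applies a centred forward spatial DFT to each time
#' point; `csi_to_image()` is its exact inverse. Both are no-ops when the
#' grid is already in the requested state.
#'
#' @param csi A [csi_grid].
#' @return A [csi_grid] in the requested state.
#' @export
csi_to_kspace <- function(csi) {
  stopifnot(inherits(csi, "csi_grid"))
  if (csi$state == "kspace") return(csi)
  d <- dim(csi$data)
  out <- csi$data
  for (tt in seq_len(d[4]))
    out[, , , tt] <- fftshift3(stats::fft(
      array(csi$data[, , , tt, drop = FALSE], dim = d[1:3])))
  csi$data <- out
  csi$state <- "kspace"
  csi
}

#' @rdname csi_to_kspace
#' @export
csi_to_image <- function(csi) {
  stopifnot(inherits(csi, "csi_grid"))
  if (csi$state == "image") return(csi)
  d <- dim(csi$data)
  out <- csi$data
  for (tt in seq_len(d[4])) {
    k <- fftshift3(array(csi$data[, , , tt, drop = FALSE], dim = d[1:3]),
                   inverse = TRUE)
    out[, , , tt] <- stats::fft(k, inverse = TRUE) / prod(d[1:3])
  }
  csi$data <- out
  csi$state <- "image"
  csi
}

#' Centred ellipsoid amplitude map
#'
#' A simple brain-like support: 1 inside the ellipsoid spanning
#' `semi_frac` of each half-dimension, 0 outside (corner voxels are zero).
#'
#' @param matrix_size Integer length-3 grid dimensions.
#' @param semi_frac Semi-axes as a fraction of each half-dimension.
#' @return A numeric `[nx, ny, nz]` array of 0/1.
#' @export
ellipsoid_amplitude_map <- function(matrix_size, semi_frac = 0.8) {
  n <- matrix_size
  ctr <- (n + 1) / 2
  semi <- pmax(semi_frac * n / 2, 0.5)
  arr <- array(0, dim = n)
  for (k in seq_len(n[3])) for (j in seq_len(n[2])) for (i in seq_len(n[1])) {
    r2 <- ((i - ctr[1]) / semi[1])^2 + ((j - ctr[2]) / semi[2])^2 +
      ((k - ctr[3]) / semi[3])^2
    if (r2 <= 1) arr[i, j, k] <- 1
  }
  arr
}

#' Synthesize a 3D CSI acquisition
#'
#' Builds an image-space grid of FIDs whose per-voxel amplitude follows
#' `amplitude_map` (default: a centred ellipsoid "brain"), each voxel holding
#' the resonances of `cfg` plus voxel-independent complex noise. Defaults
#' emulate a 31P CSI-FID acquisition: a 16 x 16 x 8 matrix over a
#' 200 x 200 x 80 mm field of view, 6 kHz bandwidth, 1024 points.
#'
#' @inheritParams simulate_transients
#' @param matrix_size Integer length-3 spatial matrix.
#' @param fov_mm Field of view in mm (length 3).
#' @param amplitude_map Numeric `[nx, ny, nz]` array of per-voxel amplitude
#'   multipliers; `NULL` for the default ellipsoid.
#' @param to_kspace If `TRUE`, return the grid forward-transformed to
#'   k-space.
#' @return A [csi_grid].
#' @export
simulate_csi <- function(cfg, matrix_size = c(16L, 16L, 8L),
                         fov_mm = c(200, 200, 80),
                         amplitude_map = NULL,
                         n_points = 1024L, dwell_time = 1 / 6000,
                         f0 = 120.7, nucleus = "31P",
                         ref_ppm = default_ref_ppm(nucleus),
                         to_kspace = FALSE) {
  stopifnot(inherits(cfg, "sim_config"), all(matrix_size >= 1))
  if (is.null(amplitude_map))
    amplitude_map <- ellipsoid_amplitude_map(matrix_size)
  if (!identical(dim(amplitude_map), as.integer(matrix_size)))
    stop("`amplitude_map` dimensions must equal `matrix_size`",
         call. = FALSE)
  tvec <- (seq_len(n_points) - 1) * dwell_time
  base <- peak_fid(cfg$peaks, tvec, f0, ref_ppm) * eddy_phase_term(cfg, tvec)
  nvox <- prod(matrix_size)
  data <- array(0 + 0i, dim = c(matrix_size, n_points))
  flat_amp <- as.vector(amplitude_map)
  for (v in seq_len(nvox)) {
    idx <- arrayInd(v, matrix_size)
    data[idx[1], idx[2], idx[3], ] <- flat_amp[v] * base
  }
  if (cfg$noise_sigma > 0) {
    noise <- with_seed(substream_seed(cfg$seed, "csi"),
                       complex_noise(length(data), cfg$noise_sigma))
    data <- data + array(noise, dim = dim(data))
  }
  grid <- csi_grid(data, state = "image", dwell_time = dwell_time, f0 = f0,
                   nucleus = nucleus, ref_ppm = ref_ppm, fov_mm = fov_mm)
  if (to_kspace) csi_to_kspace(grid) else grid
}

#' Extract one voxel of a CSI grid as a transient set
#'
#' @param csi A [csi_grid] in image space.
#' @param i,j,k Voxel indices (1-based).
#' @return A single-transient [transient_set].
#' @export
csi_voxel_fid <- function(csi, i, j, k) {
  stopifnot(inherits(csi, "csi_grid"))
  if (csi$state != "image")
    stop("transform to image space before extracting voxel FIDs",
         call. = FALSE)
  transient_set(csi$data[i, j, k, ], csi$dwell_time, csi$f0,
                nucleus = csi$nucleus, ref_ppm = csi$ref_ppm)
}
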