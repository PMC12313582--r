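#' Frequency and chemical-shift axes for a spectrum
#'
#' Builds the Hz and ppm axes used throughout the package. The underlying
#' frequency grid is the centred DFT grid
#' \eqn{(k - n/2) / (n \cdot dwell)} for \eqn{k = 0, \dots, n-1}, reversed so
#' that the ppm axis decreases with index, i.e. the conventional NMR display
#' with chemical shift decreasing left to right. The carrier (0 Hz offset)
#' maps to `ref_ppm`:
#' \deqn{ppm[i] = hz[i] / f_0 + ref_{ppm}}
#' with `f0` the transmitter frequency in MHz, so Hz offsets divide directly
#' into ppm.
#'
#' @param n_points Number of spectral points (at least 2).
#' @param dwell_time Dwell time in seconds per point.
#' @param f0 Transmitter frequency in MHz.
#' @param ref_ppm Chemical shift at the carrier frequency (defaults: 4.7 for
#'   water-referenced 1H, 0 for X-nuclei; see [default_ref_ppm()]).
#' @return A list with components `hz` and `ppm`, both length `n_points` and
#'   strictly decreasing.
#' @export
#' @examples
#' ax <- build_axes(4096, 1 / 4000, 297.2, 4.7)
#' diff(range(ax$hz)) # spectral span just under the 4 kHz bandwidth
build_axes <- function(n_points, dwell_time, f0, ref_ppm = 4.7) {
  if (length(n_points) != 1L || n_points < 2L || n_points %% 1 != 0)
    stop("`n_points` must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(dwell_time) || dwell_time <= 0)
    stop("`dwell_time` must be positive", call. = FALSE)
  if (!is.numeric(f0) || f0 <= 0)
    stop("`f0` must be positive (MHz)", call. = FALSE)
  k <- seq_len(n_points) - 1
  hz <- rev((k - floor(n_points / 2)) / (n_points * dwell_time))
  list(hz = hz, ppm = hz / f0 + ref_ppm)
}

#' Default carrier chemical shift for a nucleus
#'
#' 1H acquisitions place the carrier on water (4.7 ppm); X-nuclei axes are
#' referenced to 0 ppm at the carrier.
#'
#' @param nucleus Nucleus label, e.g. `"1H"`, `"31P"`, `"13C"`, `"2H"`.
#' @return Carrier position in ppm.
#' @export
default_ref_ppm <- function(nucleus) {
  if (identical(nucleus, "1H")) 4.7 else 0
}

#' Convert between ppm values and spectral indices
#'
#' `ppm_to_index()` returns the index of the axis point nearest to `ppm`;
#' `index_to_ppm()` is its inverse on the grid. Both accept a [spectrum]
#' object or a raw ppm axis vector.
#'
#' @param x A `spectrum` or a numeric ppm axis (strictly decreasing).
#' @param ppm Chemical shift value(s) in ppm.
#' @param index Spectral index (1-based).
#' @return An integer index (or ppm value) vector.
#' @export
ppm_to_index <- function(x, ppm) {
  axis <- if (inherits(x, "spectrum")) x$ppm_axis else x
  vapply(ppm, function(p) which.min(abs(axis - p)), integer(1))
}

#' @rdname ppm_to_index
#' @export
index_to_ppm <- function(x, index) {
  axis <- if (inherits(x, "spectrum")) x$ppm_axis else x
  axis[index]
}

#' Indices of the spectral points inside a ppm window
#'
#' @param x A `spectrum` or ppm axis vector.
#' @param ppm_range Numeric length-2 window (order irrelevant).
#' @return Integer indices, in axis order.
#' @export
ppm_window <- function(x, ppm_range) {
  axis <- if (inherits(x, "spectrum")) x$ppm_axis else x
  lo <- min(ppm_range)
  hi <- max(ppm_range)
  idx <- which(axis >= lo & axis <= hi)
  if (length(idx) == 0L)
    stop(sprintf("ppm window [%g, %g] contains no spectral points", lo, hi),
         call. = FALSE)
  idx
}
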