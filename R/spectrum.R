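#' Frequency-domain view of a transient
#'
#' `fid_to_spectrum()` applies a centre-shifted discrete Fourier transform to
#' one FID of a [transient_set] and attaches the axes from [build_axes()], so
#' a resonance at frequency offset \eqn{f} Hz lands at `hz_axis == f` (up to
#' grid resolution). `spectrum_to_fid()` inverts it to numerical precision.
#' The forward transform is the plain (non-unitary) DFT; Parseval's relation
#' then reads \eqn{\sum |X_k|^2 = n \sum |x_j|^2}.
#'
#' @param ts A single-channel [transient_set].
#' @param transient Which transient to transform (1-based).
#' @return `fid_to_spectrum()`: an object of class `spectrum` with fields
#'   `values` (complex), `hz_axis`, `ppm_axis` (both strictly decreasing),
#'   plus the metadata needed to invert (`f0`, `ref_ppm`, `dwell_time`,
#'   `nucleus`). `spectrum_to_fid()`: a complex vector.
#' @export
fid_to_spectrum <- function(ts, transient = 1L) {
  validate_transient_set(ts)
  if (n_channels(ts) > 1L)
    stop("multi-channel data: combine coils before computing spectra",
         call. = FALSE)
  if (transient < 1L || transient > n_transients(ts))
    stop("transient index out of range", call. = FALSE)
  fid <- get_fid(ts, transient)
  values <- fid_to_spec_values(fid)
  ax <- build_axes(length(fid), ts$dwell_time, ts$f0, ts$ref_ppm)
  new_spectrum(values, ax$hz, ax$ppm, f0 = ts$f0, ref_ppm = ts$ref_ppm,
               dwell_time = ts$dwell_time, nucleus = ts$nucleus)
}

#' @rdname fid_to_spectrum
#' @param spec A `spectrum`.
#' @export
spectrum_to_fid <- function(spec) {
  stopifnot(inherits(spec, "spectrum"))
  spec_values_to_fid(spec$values)
}

new_spectrum <- function(values, hz, ppm, f0, ref_ppm, dwell_time, nucleus) {
  stopifnot(length(values) == length(hz), length(hz) == length(ppm))
  structure(list(values = values, hz_axis = hz, ppm_axis = ppm, f0 = f0,
                 ref_ppm = ref_ppm, dwell_time = dwell_time,
                 nucleus = nucleus),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %d points, %.4g to %.4g ppm (f0 %.4g MHz)>\n",
              length(x$values), x$ppm_axis[1],
              x$ppm_axis[length(x$ppm_axis)], x$f0))
  invisible(x)
}

# --- DFT plumbing ----------------------------------------------------------
# Spectral values are stored on the *descending* ppm axis, i.e. the
# fftshifted DFT reversed. Both helpers below are exact inverses for any n.

fftshift <- function(x) {
  n <- length(x)
  s <- floor(n / 2)
  x[((seq_len(n) - 1 + s) %% n) + 1]
}

ifftshift <- function(x) {
  n <- length(x)
  s <- floor(n / 2)
  x[((seq_len(n) - 1 - s) %% n) + 1]
}

fid_to_spec_values <- function(fid) {
  rev(fftshift(stats::fft(fid)))
}

spec_values_to_fid <- function(values) {
  stats::fft(ifftshift(rev(values)), inverse = TRUE) / length(values)
}

#' Spectral quality metrics container
#'
#' Holds the SNR of the metabolite spectrum and the water linewidth (full
#' width at half maximum), as produced by [quality_metrics()]. The two FWHM
#' fields are consistent: `fwhm_hz == fwhm_ppm * f0`.
#'
#' @param snr Signal-to-noise ratio (dimensionless, >= 0).
#' @param fwhm_hz Water linewidth in Hz.
#' @param f0 Transmitter frequency in MHz used to express the width in ppm.
#' @return An object of class `quality_metrics`.
#' @export
new_quality_metrics <- function(snr, fwhm_hz, f0) {
  stopifnot(snr >= 0, fwhm_hz >= 0, f0 > 0)
  structure(list(snr = snr, fwhm_hz = fwhm_hz, fwhm_ppm = fwhm_hz / f0),
            class = "quality_metrics")
}

#' @export
print.quality_metrics <- function(x, ...) {
  cat(sprintf("<quality_metrics: SNR %.1f, water FWHM %.3g Hz (%.4g ppm)>\n",
              x$snr, x$fwhm_hz, x$fwhm_ppm))
  invisible(x)
}
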