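#' Apodize FIDs with a Lorentzian or Gaussian envelope
#'
#' Multiplies every FID by \eqn{e^{-\pi w t}} (Lorentzian) or
#' \eqn{e^{-(\pi w t)^2 / (4 \ln 2)}} (Gaussian) with `width_hz` \eqn{= w},
#' so the spectral FWHM of a matching lineshape grows by exactly `width_hz`
#' (Lorentzian widths add under convolution; a Gaussian envelope on a flat
#' FID gives a Gaussian line of FWHM `width_hz`). Trades linewidth for SNR.
#'
#' @param ts A [transient_set].
#' @param shape `"lorentzian"` or `"gaussian"`.
#' @param width_hz Line-broadening in Hz (>= 0; 0 is the identity).
#' @return The apodized [transient_set].
#' @export
apodize <- function(ts, shape = c("lorentzian", "gaussian"), width_hz) {
  shape <- match.arg(shape)
  validate_transient_set(ts)
  if (!is.numeric(width_hz) || length(width_hz) != 1L || width_hz < 0)
    stop("`width_hz` must be a single non-negative number", call. = FALSE)
  if (width_hz == 0) return(ts)
  tvec <- time_axis(ts)
  env <- switch(shape,
                lorentzian = exp(-pi * width_hz * tvec),
                gaussian = exp(-(pi * width_hz * tvec)^2 / (4 * log(2))))
  for (t in seq_len(n_transients(ts)))
    for (ch in seq_len(n_channels(ts)))
      ts$data[t, ch, ] <- ts$data[t, ch, ] * env
  ts
}

#' Zero-fill FIDs to refine the spectral grid
#'
#' Appends zeros so each FID grows to `factor` times its length. The
#' spectrum of the padded FID is the trigonometric interpolation of the
#' original: evaluated on the original frequency grid it reproduces the
#' original spectrum exactly. Axes are rebuilt for the new length.
#'
#' @param ts A [transient_set].
#' @param factor Integer >= 1 (1 is the identity).
#' @return The zero-filled [transient_set].
#' @export
zero_fill <- function(ts, factor = 2L) {
  validate_transient_set(ts)
  if (!is.numeric(factor) || length(factor) != 1L || factor %% 1 != 0 ||
      factor < 1)
    stop("`factor` must be a single integer >= 1", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(ts)
  d <- dim(ts$data)
  out <- array(0 + 0i, dim = c(d[1], d[2], d[3] * factor))
  out[, , seq_len(d[3])] <- ts$data
  set_data(ts, out)
}

#' Average all transients into one
#'
#' Arithmetic mean over the transient axis. With pure noise of per-transient
#' spectral RMS \eqn{\sigma}, averaging \eqn{N} transients leaves RMS
#' \eqn{\sigma/\sqrt N}.
#'
#' @param ts A [transient_set] (>= 1 transient).
#' @return A [transient_set] with a single transient.
#' @export
average_all <- function(ts) {
  validate_transient_set(ts)
  if (n_transients(ts) == 1L) return(ts)
  d <- dim(ts$data)
  out <- array(0 + 0i, dim = c(1L, d[2], d[3]))
  out[1L, , ] <- apply(ts$data, c(2, 3), mean)
  set_data(ts, out)
}
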