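#' A set of complex time-domain MRS transients
#'
#' The canonical in-memory container that every processing node consumes and
#' produces: complex free induction decays (FIDs) indexed
#' `[transient, channel, point]` together with the acquisition metadata that
#' fixes the frequency axes. Data stay in the time domain between nodes;
#' [fid_to_spectrum()] provides the frequency-domain view on demand.
#'
#' @param data Complex array `[transient, channel, point]`. A plain vector is
#'   treated as one transient of one channel; a matrix as
#'   `[transient, point]` with one channel.
#' @param dwell_time Dwell time in seconds per point (> 0).
#' @param f0 Transmitter frequency in MHz (> 0).
#' @param nucleus Nucleus label: `"1H"`, `"31P"`, `"13C"` or `"2H"`.
#' @param ref_ppm Chemical shift at the carrier; defaults per nucleus via
#'   [default_ref_ppm()].
#' @param role Either `"metabolite"` or `"water_reference"`.
#' @param acq_meta Free-form acquisition metadata list; recognised fields are
#'   `te_ms`, `tr_ms`, `sequence`, `voxel_mm` (length 3), and the block tags
#'   `block_type` / `block_index` attached by [blocked_average()].
#' @return An object of class `transient_set`.
#' @export
transient_set <- function(data, dwell_time, f0, nucleus = "1H",
                          ref_ppm = default_ref_ppm(nucleus),
                          role = c("metabolite", "water_reference"),
                          acq_meta = list()) {
  role <- match.arg(role)
  if (is.null(dim(data))) {
    data <- array(data, dim = c(1L, 1L, length(data)))
  } else if (length(dim(data)) == 2L) {
    data <- array(data, dim = c(nrow(data), 1L, ncol(data)))
  }
  if (length(dim(data)) != 3L)
    stop("`data` must be a [transient, channel, point] array", call. = FALSE)
  storage.mode(data) <- "complex"
  ts <- structure(
    list(data = data, dwell_time = dwell_time, f0 = f0, nucleus = nucleus,
         ref_ppm = ref_ppm, role = role, acq_meta = acq_meta),
    class = "transient_set")
  validate_transient_set(ts)
  ts
}

validate_transient_set <- function(ts) {
  stopifnot(inherits(ts, "transient_set"))
  if (n_points(ts) < 2L)
    stop("a transient needs at least 2 points", call. = FALSE)
  if (!is.numeric(ts$dwell_time) || length(ts$dwell_time) != 1L ||
      ts$dwell_time <= 0)
    stop("`dwell_time` must be a single positive number", call. = FALSE)
  if (!is.numeric(ts$f0) || length(ts$f0) != 1L || ts$f0 <= 0)
    stop("`f0` must be a single positive number (MHz)", call. = FALSE)
  if (!ts$role %in% c("metabolite", "water_reference"))
    stop("`role` must be 'metabolite' or 'water_reference'", call. = FALSE)
  invisible(ts)
}

#' Dimensions of a transient set
#'
#' @param ts A [transient_set].
#' @return An integer scalar.
#' @export
n_transients <- function(ts) dim(ts$data)[1L]

#' @rdname n_transients
#' @export
n_channels <- function(ts) dim(ts$data)[2L]

#' @rdname n_transients
#' @export
n_points <- function(ts) dim(ts$data)[3L]

#' Sampling times of the FID
#'
#' @param ts A [transient_set].
#' @return Numeric vector of times in seconds, starting at 0.
#' @export
time_axis <- function(ts) (seq_len(n_points(ts)) - 1) * ts$dwell_time

# Replace the data array, keeping metadata (internal).
set_data <- function(ts, data) {
  if (is.null(dim(data)))
    data <- array(data, dim = c(1L, 1L, length(data)))
  if (length(dim(data)) == 2L)
    data <- array(data, dim = c(nrow(data), 1L, ncol(data)))
  ts$data <- data
  ts
}

# Extract one FID as a complex vector (internal).
get_fid <- function(ts, transient = 1L, channel = 1L) {
  ts$data[transient, channel, ]
}

#' Subset transients of a set
#'
#' @param ts A [transient_set].
#' @param i Transient indices to keep (1-based, order preserved).
#' @return A `transient_set` with the selected transients.
#' @export
subset_transients <- function(ts, i) {
  ts$data <- ts$data[i, , , drop = FALSE]
  ts
}

#' @export
print.transient_set <- function(x, ...) {
  cat(sprintf(
    "<transient_set: %d transient(s) x %d channel(s) x %d points>\n",
    n_transients(x), n_channels(x), n_points(x)))
  cat(sprintf("  nucleus %s, f0 %.4g MHz, dwell %.4g s (bandwidth %.4g Hz)\n",
              x$nucleus, x$f0, x$dwell_time, 1 / x$dwell_time))
  cat(sprintf("  role: %s, carrier at %.3g ppm\n", x$role, x$ref_ppm))
  invisible(x)
}

#' Per-transient frequency and phase corrections
#'
#' Container returned by [align_frequency_phase()]: the frequency (Hz) and
#' zero-order phase (degrees) applied to each transient.
#'
#' @param freq_shifts_hz Numeric vector, one entry per transient.
#' @param phase_shifts_deg Numeric vector, same length.
#' @param converged Logical vector, same length.
#' @return An object of class `alignment_result`.
#' @export
alignment_result <- function(freq_shifts_hz, phase_shifts_deg,
                             converged = rep(TRUE, length(freq_shifts_hz))) {
  stopifnot(length(freq_shifts_hz) == length(phase_shifts_deg),
            all(is.finite(freq_shifts_hz)), all(is.finite(phase_shifts_deg)))
  structure(list(freq_shifts_hz = freq_shifts_hz,
                 phase_shifts_deg = phase_shifts_deg,
                 converged = converged),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result: %d transient(s)>\n",
              length(x$freq_shifts_hz)))
  cat(sprintf("  freq shifts  [Hz]: %s\n",
              paste(sprintf("%.2f", utils::head(x$freq_shifts_hz, 8)),
                    collapse = " ")))
  cat(sprintf("  phase shifts [deg]: %s\n",
              paste(sprintf("%.1f", utils::head(x$phase_shifts_deg, 8)),
                    collapse = " ")))
  invisible(x)
}
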