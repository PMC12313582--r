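#' Generative description of a synthetic MRS acquisition
#'
#' A `sim_config` fixes everything needed to synthesize a multi-transient,
#' multi-channel acquisition deterministically: the resonances, the receive
#' chain, and the corruptions (noise, frequency drift, phase jitter,
#' eddy-current phase, motion-like outliers, functional block designs).
#' The same config and seed always reproduce the same bytes. The global seed
#' is expanded into independent per-purpose substreams (noise, jitter,
#' water-reference noise, CSI noise), so switching one corruption on or off
#' does not perturb the draws of the others.
#'
#' Lineshapes: a peak with Lorentzian width \eqn{\Delta\nu_L} and Gaussian
#' width \eqn{\Delta\nu_G} (both FWHM, Hz) decays as
#' \deqn{g(t) = e^{-\pi \Delta\nu_L t} \; e^{-(\pi \Delta\nu_G t)^2 / (4\ln 2)}}
#' so the spectral FWHM of each component equals the configured value —
#' quality-metric and apodization tests rely on this calibration.
#'
#' The defaults emulate a short-TE 7 T 1H brain acquisition: 32 transients,
#' 4 kHz bandwidth at 4096 points, NAA/Cr/Cho-like resonances.
#'
#' @param peaks Data frame with columns `ppm`, `amplitude`,
#'   `lorentz_fwhm_hz`, `gauss_fwhm_hz`, `phase_deg` (one row per resonance;
#'   amplitudes must be non-negative).
#' @param n_transients,n_channels Acquisition geometry.
#' @param channel_sensitivities Complex vector, one entry per channel.
#' @param noise_sigma Standard deviation of the complex noise added to every
#'   sample (applied independently to real and imaginary parts); >= 0.
#' @param freq_drift_hz_per_transient Linear frequency drift across the
#'   acquisition, in Hz per transient.
#' @param phase_jitter_deg_sd Per-transient zero-order phase jitter SD.
#' @param eddy_amp_rad,eddy_decay_s Eddy-current phase transient
#'   \eqn{\phi(t) = A e^{-t/\tau}} applied multiplicatively as
#'   \eqn{e^{i\phi(t)}}.
#' @param outlier_indices 1-based transient indices corrupted as
#'   motion-like outliers (amplitude times `outlier_gain` plus a large phase
#'   excursion `outlier_phase_deg`).
#' @param outlier_gain,outlier_phase_deg Outlier corruption parameters.
#' @param block_design `NULL`, or `list(block_len =, multipliers =)` where
#'   `multipliers` is an `n_blocks x n_peaks` matrix of per-block amplitude
#'   multipliers (functional MRS block designs).
#' @param seed Integer seed; same config + seed give bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(peaks = default_1h_peaks(),
                       n_transients = 32L,
                       n_channels = 1L,
                       channel_sensitivities = rep(1 + 0i, n_channels),
                       noise_sigma = 0,
                       freq_drift_hz_per_transient = 0,
                       phase_jitter_deg_sd = 0,
                       eddy_amp_rad = 0,
                       eddy_decay_s = 0.1,
                       outlier_indices = integer(0),
                       outlier_gain = 20,
                       outlier_phase_deg = 120,
                       block_design = NULL,
                       seed = 1L) {
  peaks <- as.data.frame(peaks)
  needed <- c("ppm", "amplitude", "lorentz_fwhm_hz", "gauss_fwhm_hz",
              "phase_deg")
  missing_cols <- setdiff(needed, names(peaks))
  if (length(missing_cols))
    stop("`peaks` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  stopifnot(all(peaks$amplitude >= 0), noise_sigma >= 0,
            n_transients >= 1, n_channels >= 1,
            length(channel_sensitivities) == n_channels)
  if (length(outlier_indices) &&
      (any(outlier_indices < 1) || any(outlier_indices > n_transients)))
    stop("`outlier_indices` must lie in 1..n_transients", call. = FALSE)
  if (!is.null(block_design)) {
    stopifnot(is.list(block_design),
              !is.null(block_design$block_len),
              !is.null(block_design$multipliers))
    block_design$multipliers <- as.matrix(block_design$multipliers)
    if (ncol(block_design$multipliers) != nrow(peaks))
      stop("block_design$multipliers needs one column per peak",
           call. = FALSE)
  }
  structure(list(peaks = peaks, n_transients = as.integer(n_transients),
                 n_channels = as.integer(n_channels),
                 channel_sensitivities = as.complex(channel_sensitivities),
                 noise_sigma = noise_sigma,
                 freq_drift_hz_per_transient = freq_drift_hz_per_transient,
                 phase_jitter_deg_sd = phase_jitter_deg_sd,
                 eddy_amp_rad = eddy_amp_rad, eddy_decay_s = eddy_decay_s,
                 outlier_indices = as.integer(outlier_indices),
                 outlier_gain = outlier_gain,
                 outlier_phase_deg = outlier_phase_deg,
                 block_design = block_design, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default resonances of the synthetic 1H brain spectrum
#'
#' NAA at 2.02 ppm (the alignment anchor), creatine and choline analogues.
#'
#' @return A peaks data frame suitable for [sim_config()].
#' @export
default_1h_peaks <- function() {
  data.frame(
    ppm = c(2.02, 3.03, 3.22),
    amplitude = c(1.0, 0.8, 0.6),
    lorentz_fwhm_hz = c(5, 5, 5),
    gauss_fwhm_hz = c(0, 0, 0),
    phase_deg = c(0, 0, 0))
}

#' Default resonances of the synthetic 31P spectrum
#'
#' PCr at 0 ppm with ATP- and Pi-like companions, for X-nucleus pipelines.
#'
#' @return A peaks data frame suitable for [sim_config()].
#' @export
default_31p_peaks <- function() {
  data.frame(
    ppm = c(0, 4.9, -7.5, -16.1, 6.7),
    amplitude = c(1.0, 0.35, 0.45, 0.4, 0.3),
    lorentz_fwhm_hz = c(8, 10, 12, 14, 10),
    gauss_fwhm_hz = c(0, 0, 0, 0, 0),
    phase_deg = c(0, 0, 0, 0, 0))
}

# --- seeded substreams -----------------------------------------------------

substream_seed <- function(seed, purpose) {
  offsets <- c(noise = 101L, jitter = 211L, water = 401L, csi = 503L)
  as.integer((as.numeric(seed) * 48271 + offsets[[purpose]]) %% 2147483629)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

complex_noise <- function(n, sigma) {
  complex(real = stats::rnorm(n, sd = sigma),
          imaginary = stats::rnorm(n, sd = sigma))
}

# Noiseless sum-of-resonances FID at given per-peak amplitudes/extra shift.
peak_fid <- function(peaks, tvec, f0, ref_ppm, amp_mult = 1,
                     extra_freq_hz = 0, extra_phase_rad = 0) {
  fid <- complex(length(tvec))
  amp_mult <- rep_len(amp_mult, nrow(peaks))
  for (p in seq_len(nrow(peaks))) {
    f_hz <- (peaks$ppm[p] - ref_ppm) * f0 + extra_freq_hz
    decay <- exp(-pi * peaks$lorentz_fwhm_hz[p] * tvec) *
      exp(-(pi * peaks$gauss_fwhm_hz[p] * tvec)^2 / (4 * log(2)))
    fid <- fid + peaks$amplitude[p] * amp_mult[p] * decay *
      exp(1i * (2 * pi * f_hz * tvec +
                  (peaks$phase_deg[p]) * pi / 180 + extra_phase_rad))
  }
  fid
}

eddy_phase_term <- function(cfg, tvec) {
  if (cfg$eddy_amp_rad == 0) return(rep(1 + 0i, length(tvec)))
  exp(1i * cfg$eddy_amp_rad * exp(-tvec / cfg$eddy_decay_s))
}

#' Synthesize a multi-transient, multi-channel acquisition
#'
#' Generates the FIDs described by a [sim_config()]: per transient and
#' channel,
#' \deqn{s_{t,c}(n) = w_c \left[\sum_p A_p m_{b(t),p}\, g_p(t_n)\,
#'   e^{i(2\pi (f_p + t\,\delta f) t_n + \phi_p + \eta_t)}\right]
#'   e^{i\,\phi_{eddy}(t_n)} + \epsilon_{t,c}(n)}
#' with \eqn{w_c} the channel sensitivities, \eqn{\delta f} the drift,
#' \eqn{\eta_t} the phase jitter, \eqn{m_{b,p}} the block-design amplitude
#' multipliers, and \eqn{\epsilon} complex Gaussian noise. Outlier transients
#' are scaled by `outlier_gain` and rotated by `outlier_phase_deg` before the
#' channel sensitivities apply.
#'
#' @param cfg A [sim_config()].
#' @param n_points Samples per FID.
#' @param dwell_time Dwell time in seconds (default 1/4000 s: 4 kHz
#'   bandwidth).
#' @param f0 Transmitter frequency in MHz (default 297.2, 1H at 7 T).
#' @param nucleus Nucleus label.
#' @param ref_ppm Carrier chemical shift.
#' @return A [transient_set] with role `"metabolite"`.
#' @export
simulate_transients <- function(cfg, n_points = 4096L,
                                dwell_time = 1 / 4000, f0 = 297.2,
                                nucleus = "1H",
                                ref_ppm = default_ref_ppm(nucleus)) {
  stopifnot(inherits(cfg, "sim_config"))
  tvec <- (seq_len(n_points) - 1) * dwell_time
  nt <- cfg$n_transients
  nc <- cfg$n_channels

  jitter <- if (cfg$phase_jitter_deg_sd > 0)
    with_seed(substream_seed(cfg$seed, "jitter"),
              stats::rnorm(nt, sd = cfg$phase_jitter_deg_sd * pi / 180))
  else rep(0, nt)

  mult_for_transient <- function(t) {
    bd <- cfg$block_design
    if (is.null(bd)) return(rep(1, nrow(cfg$peaks)))
    b <- (t - 1) %/% bd$block_len + 1
    if (b > nrow(bd$multipliers))
      stop("block_design$multipliers has too few rows for n_transients",
           call. = FALSE)
    bd$multipliers[b, ]
  }

  eddy <- eddy_phase_term(cfg, tvec)
  data <- array(0 + 0i, dim = c(nt, nc, n_points))
  for (t in seq_len(nt)) {
    base <- peak_fid(cfg$peaks, tvec, f0, ref_ppm,
                     amp_mult = mult_for_transient(t),
                     extra_freq_hz = cfg$freq_drift_hz_per_transient * (t - 1),
                     extra_phase_rad = jitter[t]) * eddy
    if (t %in% cfg$outlier_indices)
      base <- base * cfg$outlier_gain *
        exp(1i * cfg$outlier_phase_deg * pi / 180)
    for (ch in seq_len(nc))
      data[t, ch, ] <- cfg$channel_sensitivities[ch] * base
  }
  if (cfg$noise_sigma > 0) {
    noise <- with_seed(substream_seed(cfg$seed, "noise"),
                       complex_noise(nt * nc * n_points, cfg$noise_sigma))
    data <- data + array(noise, dim = dim(data))
  }
  transient_set(data, dwell_time, f0, nucleus = nucleus, ref_ppm = ref_ppm,
                role = "metabolite",
                acq_meta = list(sequence = "synthetic", seed = cfg$seed))
}

#' Synthesize an unsuppressed water reference acquisition
#'
#' A single dominant resonance at the carrier, sharing the eddy-current term
#' and channel sensitivities with a paired metabolite set from the same
#' config (so Klose eddy-current correction cancels exactly in the noiseless
#' case). Drift, jitter and outliers do not apply; noise uses its own
#' substream of the config seed.
#'
#' @inheritParams simulate_transients
#' @param amplitude Water peak amplitude.
#' @param lorentz_fwhm_hz Water linewidth (Lorentzian FWHM, Hz).
#' @param n_transients Number of water transients (defaults to the config's).
#' @return A [transient_set] with role `"water_reference"`.
#' @export
simulate_water_reference <- function(cfg, n_points = 4096L,
                                     dwell_time = 1 / 4000, f0 = 297.2,
                                     nucleus = "1H",
                                     ref_ppm = default_ref_ppm(nucleus),
                                     amplitude = 100,
                                     lorentz_fwhm_hz = 10,
                                     n_transients = cfg$n_transients) {
  stopifnot(inherits(cfg, "sim_config"))
  tvec <- (seq_len(n_points) - 1) * dwell_time
  peaks <- data.frame(ppm = ref_ppm, amplitude = amplitude,
                      lorentz_fwhm_hz = lorentz_fwhm_hz, gauss_fwhm_hz = 0,
                      phase_deg = 0)
  base <- peak_fid(peaks, tvec, f0, ref_ppm) * eddy_phase_term(cfg, tvec)
  nc <- cfg$n_channels
  data <- array(0 + 0i, dim = c(n_transients, nc, n_points))
  for (t in seq_len(n_transients))
    for (ch in seq_len(nc))
      data[t, ch, ] <- cfg$channel_sensitivities[ch] * base
  if (cfg$noise_sigma > 0) {
    noise <- with_seed(substream_seed(cfg$seed, "water"),
                       complex_noise(length(data), cfg$noise_sigma))
    data <- data + array(noise, dim = dim(data))
  }
  transient_set(data, dwell_time, f0, nucleus = nucleus, ref_ppm = ref_ppm,
                role = "water_reference",
                acq_meta = list(sequence = "synthetic", seed = cfg$seed))
}
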