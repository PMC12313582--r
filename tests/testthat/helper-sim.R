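# Shared fixtures and independent oracles for the test suite. All data are
# generated in code; no files are shipped.

single_peak_cfg <- function(ppm = 2.02, amplitude = 1, lw = 5, n_transients = 1,
                            ...) {
  sim_config(peaks = data.frame(ppm = ppm, amplitude = amplitude,
                                lorentz_fwhm_hz = lw, gauss_fwhm_hz = 0,
                                phase_deg = 0),
             n_transients = n_transients, ...)
}

# Small, fast 1H acquisition (1 kHz-resolution grid keeps ffts cheap).
quick_1h <- function(cfg, n_points = 1024L) {
  simulate_transients(cfg, n_points = n_points, dwell_time = 1 / 4000,
                      f0 = 297.2)
}

quick_31p_spectrum <- function(n_points = 1024L, noise_sigma = 0,
                               seed = 1L) {
  cfg <- sim_config(peaks = default_31p_peaks(), n_transients = 1L,
                    noise_sigma = noise_sigma, seed = seed)
  fid_to_spectrum(simulate_transients(cfg, n_points = n_points,
                                      dwell_time = 1 / 6000, f0 = 120.7,
                                      nucleus = "31P"))
}

# Build a transient set from explicit per-transient (df Hz, dphi deg)
# modulations of a template FID.
shifted_copies <- function(template_ts, df_hz, dphi_deg) {
  stopifnot(length(df_hz) == length(dphi_deg))
  tvec <- (seq_len(n_points(template_ts)) - 1) * template_ts$dwell_time
  fid <- template_ts$data[1, 1, ]
  dat <- array(0 + 0i, dim = c(length(df_hz), 1L, length(fid)))
  for (t in seq_along(df_hz))
    dat[t, 1, ] <- fid * exp(1i * (2 * pi * df_hz[t] * tvec +
                                     dphi_deg[t] * pi / 180))
  transient_set(dat, template_ts$dwell_time, template_ts$f0,
                nucleus = template_ts$nucleus,
                ref_ppm = template_ts$ref_ppm)
}

# --- alignment oracle: exhaustive grid search over the same registration
# objective (window residual to the pointwise median spectrum), 0.05 Hz x
# 0.5 degree resolution. Per trial frequency all phases are scored in
# closed form from the cross term, which keeps the full grid cheap.
align_grid_oracle <- function(ts, ppm_range,
                              df_grid = seq(-8, 8, by = 0.05),
                              dphi_grid_deg = seq(-180, 179.5, by = 0.5)) {
  np <- n_points(ts)
  nt <- n_transients(ts)
  tvec <- (seq_len(np) - 1) * ts$dwell_time
  spec_of <- function(fid) rev(fft_shift_vec(stats::fft(fid)))
  S <- vapply(seq_len(nt), function(t) spec_of(ts$data[t, 1, ]),
              complex(np))
  med <- complex(real = apply(Re(S), 1, stats::median),
                 imaginary = apply(Im(S), 1, stats::median))
  ax <- build_axes(np, ts$dwell_time, ts$f0, ts$ref_ppm)
  win <- which(ax$ppm >= min(ppm_range) & ax$ppm <= max(ppm_range))
  med_w <- med[win]
  med_e <- sum(Mod(med_w)^2)
  phi_rad <- dphi_grid_deg * pi / 180
  out <- matrix(0, nt, 2)
  for (t in seq_len(nt)) {
    fid <- ts$data[t, 1, ]
    best <- c(Inf, 0, 0)
    for (df in df_grid) {
      s <- spec_of(fid * exp(1i * 2 * pi * df * tvec))[win]
      cross <- sum(s * Conj(med_w))
      base <- sum(Mod(s)^2) + med_e
      vals <- base - 2 * Re(exp(1i * phi_rad) * cross)
      k <- which.min(vals)
      if (vals[k] < best[1]) best <- c(vals[k], df, dphi_grid_deg[k])
    }
    out[t, ] <- best[2:3]
  }
  list(freq_shifts_hz = out[, 1], phase_shifts_deg = out[, 2])
}

fft_shift_vec <- function(x) {
  n <- length(x)
  s <- floor(n / 2)
  x[((seq_len(n) - 1 + s) %% n) + 1]
}

# --- entropy-phasing oracle: plain 2-D grid search over the same
# objective (derivative entropy + negativity penalty).
entropy_grid_oracle <- function(spec, phi0_grid = seq(-60, 60, by = 1),
                                phi1_grid = seq(-5, 5, by = 0.5),
                                gamma = 1000, pivot_ppm = spec$ref_ppm) {
  s0 <- spec$values / max(Mod(spec$values))
  dppm <- spec$ppm_axis - pivot_ppm
  score <- function(p0, p1) {
    re <- Re(s0 * exp(1i * (p0 + p1 * dppm) * pi / 180))
    d <- abs(diff(re))
    tot <- sum(d)
    ent <- if (tot == 0) 0 else {
      h <- d / tot
      h <- h[h > 0]
      -sum(h * log(h))
    }
    ent + gamma * sum(pmin(re, 0)^2)
  }
  best <- c(Inf, 0, 0)
  for (p0 in phi0_grid) for (p1 in phi1_grid) {
    v <- score(p0, p1)
    if (v < best[1]) best <- c(v, p0, p1)
  }
  list(phi0_deg = best[2], phi1_deg_per_ppm = best[3], value = best[1])
}

# Minimal valid LCModel control template.
control_template <- function() {
  c(" $LCMODL",
    " TITLE='synthetic acquisition'",
    " KEY=123456789",
    " WCONC=35880",
    " DOECC=F",
    " $END")
}

# A quant_result fixture with curves, used for COORD round trips and the
# stubbed fitter.
coord_fixture <- function(ny = 64) {
  set.seed(421)
  quant_result(
    data.frame(metabolite = c("NAA", "Cr+PCr", "Cho"),
               concentration = c(8.215, 6.12, 1.43),
               crlb_pct = c(5, 6, 12),
               ratio = c(1.342, 1.0, 0.234)),
    snr = 45, fwhm_ppm = 0.042, reference = "Cr+PCr",
    curves = list(ppm = seq(4.2, 0.5, length.out = ny),
                  data = round(stats::rnorm(ny), 4),
                  fit = round(stats::rnorm(ny), 4),
                  baseline = round(stats::rnorm(ny), 4)))
}

# Shell-script fitter stub that consumes the control file on stdin and
# copies a prepared COORD fixture into place.
make_stub_fitter <- function(coord_source) {
  stub <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "cat > /dev/null",
               sprintf("cp %s \"$MRSPIPE_COORD\"", shQuote(coord_source))),
             stub)
  Sys.chmod(stub, "0755")
  stub
}

# Tidy quantification grid covering a nx x ny x nz CSI volume.
synthetic_quant_grid <- function(nx = 4, ny = 4, nz = 2,
                                 crlb_fun = function(vx, vy, vz) 10) {
  g <- expand.grid(vx = seq_len(nx) - 1L, vy = seq_len(ny) - 1L,
                   vz = seq_len(nz) - 1L)
  rbind(
    data.frame(g, metabolite = "NAD+", concentration = 0.3 + 0.01 * g$vx,
               crlb_pct = mapply(crlb_fun, g$vx, g$vy, g$vz), ratio = 0.1),
    data.frame(g, metabolite = "PCr", concentration = 4,
               crlb_pct = 5, ratio = 1))
}
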