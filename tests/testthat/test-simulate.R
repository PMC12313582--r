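test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_transients = 4, n_channels = 2,
                    channel_sensitivities = c(1, 2i), noise_sigma = 0.01,
                    phase_jitter_deg_sd = 5, outlier_indices = 2,
                    seed = 123)
  a <- simulate_transients(cfg, n_points = 256)
  b <- simulate_transients(cfg, n_points = 256)
  expect_identical(a, b)
  w1 <- simulate_water_reference(cfg, n_points = 256)
  w2 <- simulate_water_reference(cfg, n_points = 256)
  expect_identical(w1, w2)
})

test_that("a single noiseless peak lands at its configured chemical shift", {
  ts <- quick_1h(single_peak_cfg())
  sp <- fid_to_spectrum(ts)
  peak_ppm <- sp$ppm_axis[which.max(Mod(sp$values))]
  bin_ppm <- (4000 / n_points(ts)) / ts$f0
  expect_lt(abs(peak_ppm - 2.02), bin_ppm + 1e-9)
})

test_that("frequency drift accumulates linearly across transients", {
  cfg <- single_peak_cfg(n_transients = 11,
                         freq_drift_hz_per_transient = 1)
  ts <- quick_1h(cfg, n_points = 4096L)
  peak_hz <- vapply(c(1L, 11L), function(t) {
    sp <- fid_to_spectrum(ts, t)
    sp$hz_axis[which.max(Mod(sp$values))]
  }, numeric(1))
  bin_hz <- 4000 / 4096
  expect_lt(abs((peak_hz[2] - peak_hz[1]) - 10), bin_hz + 1e-9)
})

test_that("channel sensitivities scale the FIDs linearly", {
  cfg <- single_peak_cfg(n_transients = 2)
  cfg2 <- sim_config(peaks = cfg$peaks, n_transients = 2, n_channels = 2,
                     channel_sensitivities = c(1, 2))
  ts <- quick_1h(cfg2, n_points = 256)
  expect_equal(ts$data[1, 2, ], 2 * ts$data[1, 1, ])
})

test_that("water reference shares the eddy term and obeys the closed form", {
  cfg <- sim_config(n_transients = 2, n_channels = 2,
                    channel_sensitivities = c(1, 0.5i),
                    eddy_amp_rad = 0.8, eddy_decay_s = 0.1)
  m <- simulate_transients(cfg, n_points = 256)
  w <- simulate_water_reference(cfg, n_points = 256, amplitude = 100)
  # identical eddy phase per time point (visible on single-resonance water
  # as the phase after removing the carrier is the eddy transient itself)
  tvec <- (0:255) / 4000
  eddy <- 0.8 * exp(-tvec / 0.1)
  expect_equal(Arg(w$data[1, 1, ] / (100 * exp(-pi * 10 * tvec))), eddy,
               tolerance = 1e-10)
  # first-point magnitude: A |sens_c| per channel, A * sum|sens| overall
  expect_equal(Mod(w$data[1, 1, 1]), 100, tolerance = 1e-10)
  expect_equal(sum(Mod(w$data[1, , 1])), 100 * (1 + 0.5),
               tolerance = 1e-10)
  expect_identical(w$role, "water_reference")
  expect_identical(m$role, "metabolite")
})

test_that("spectral noise level matches the configured sigma", {
  # pure noise: spectral real-part RMS is sigma * sqrt(n)
  cfg <- sim_config(peaks = default_1h_peaks()[0, ], n_transients = 1,
                    noise_sigma = 0.05, seed = 31)
  ts <- simulate_transients(cfg, n_points = 4096L)
  sp <- fid_to_spectrum(ts)
  win <- ppm_window(sp$ppm_axis, c(0.2, 3.0))
  rms <- sqrt(mean(Re(sp$values[win])^2))
  expect_equal(rms, 0.05 * sqrt(4096), tolerance = 0.05)
})

test_that("block-design amplitude multipliers are recoverable", {
  mult <- matrix(c(1, 1, 1,
                   1.5, 1, 1,
                   1, 1, 1,
                   1.5, 1, 1), ncol = 3, byrow = TRUE)
  cfg <- sim_config(n_transients = 32, noise_sigma = 0.001, seed = 9,
                    block_design = list(block_len = 8, multipliers = mult))
  ts <- quick_1h(cfg, n_points = 2048L)
  res <- blocked_average(ts, meas_per_block = 8, avgs_per_block = 1,
                         n_block_types = 2)
  naa_area <- vapply(res$outputs, function(o) {
    sp <- fid_to_spectrum(o)
    sum(Mod(sp$values[ppm_window(sp$ppm_axis, c(1.9, 2.15))]))
  }, numeric(1))
  ratio <- naa_area[2] / naa_area[1]
  expect_equal(ratio, 1.5, tolerance = 0.05)
})

test_that("config validation catches inconsistent inputs", {
  expect_error(sim_config(peaks = data.frame(ppm = 1)), "lacks column")
  expect_error(sim_config(n_channels = 2,
                          channel_sensitivities = c(1 + 0i)))
  expect_error(sim_config(outlier_indices = 40, n_transients = 32),
               "outlier_indices")
  bad_mult <- list(block_len = 8, multipliers = matrix(1, 2, 2))
  expect_error(sim_config(block_design = bad_mult), "per peak")
})

test_that("CSI simulation honours the amplitude map and spatial DFT", {
  cfg <- single_peak_cfg(ppm = 0)
  cfg$peaks$lorentz_fwhm_hz <- 8
  # uniform map: all voxel FIDs identical
  u <- simulate_csi(cfg, matrix_size = c(4, 4, 2), n_points = 64,
                    amplitude_map = array(1, c(4, 4, 2)))
  expect_equal(u$data[1, 1, 1, ], u$data[3, 4, 2, ])
  # ellipsoid: corner voxels empty
  e <- simulate_csi(cfg, matrix_size = c(8, 8, 4), n_points = 64)
  expect_equal(max(Mod(e$data[1, 1, 1, ])), 0)
  expect_gt(max(Mod(e$data[5, 5, 2, ])), 0)
  # k-space -> image round trip is the identity
  k <- csi_to_kspace(e)
  back <- csi_to_image(k)
  expect_lt(max(Mod(back$data - e$data)) / max(Mod(e$data)), 1e-8)
  expect_error(simulate_csi(cfg, matrix_size = c(4, 4, 2),
                            amplitude_map = array(1, c(2, 2, 2))),
               "dimensions")
})
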