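test_that("single-channel input passes through with unit weight", {
  ts <- quick_1h(single_peak_cfg(n_transients = 2), n_points = 256)
  for (m in c("adaptive", "snr2", "svd")) {
    res <- coil_combine(ts, m)
    expect_identical(res$ts$data, ts$data)
    expect_equal(res$weights, complex(real = 1))
  }
})

test_that("svd combination of two identical noiseless channels gives sqrt(2) gain", {
  cfg <- sim_config(peaks = single_peak_cfg()$peaks, n_transients = 2,
                    n_channels = 2, channel_sensitivities = c(1, 1))
  ts <- quick_1h(cfg, n_points = 256)
  w <- simulate_water_reference(cfg, n_points = 256)
  res <- coil_combine(ts, "svd", water_ref = w)
  expect_equal(res$ts$data[1, 1, ], sqrt(2) * ts$data[1, 1, ],
               tolerance = 1e-10)
  expect_equal(n_channels(res$ts), 1L)
})

test_that("snr2 combination reaches the matched-filter SNR optimum", {
  sens <- c(1, 2, 2, 1) * exp(1i * c(0.2, -0.7, 1.3, 2.4))
  sigma <- 0.04
  cfg <- sim_config(
    peaks = data.frame(ppm = 2.02, amplitude = 10, lorentz_fwhm_hz = 5,
                       gauss_fwhm_hz = 0, phase_deg = 0),
    n_transients = 8, n_channels = 4, channel_sensitivities = sens,
    noise_sigma = sigma, seed = 17)
  ts <- quick_1h(cfg, n_points = 2048L)
  w <- simulate_water_reference(cfg, n_points = 2048L)
  res <- coil_combine(ts, "snr2", water_ref = w)

  # oracle: direct matched-filter combination with the known sensitivities
  oracle_w <- Conj(sens) / sqrt(sum(Mod(sens)^2))
  oracle <- apply_coil_weights(ts, oracle_w)
  snr_of <- function(x) {
    sp <- fid_to_spectrum(average_all(x))
    win <- ppm_window(sp$ppm_axis, c(1.8, 2.2))
    noi <- ppm_window(sp$ppm_axis, c(0.2, 0.5))
    max(Mod(sp$values[win])) / sqrt(mean(Re(sp$values[noi])^2))
  }
  expect_equal(snr_of(res$ts), snr_of(oracle), tolerance = 0.03)
})

test_that("dead channels get zero weight with a warning", {
  cfg <- sim_config(peaks = single_peak_cfg()$peaks, n_transients = 2,
                    n_channels = 3, channel_sensitivities = c(1, 0, 1))
  ts <- quick_1h(cfg, n_points = 256)
  w <- simulate_water_reference(cfg, n_points = 256)
  expect_warning(res <- coil_combine(ts, "svd", water_ref = w),
                 "no signal")
  expect_equal(res$weights[2], 0 + 0i)
})

test_that("combined water-reference first point is rotated real-positive", {
  cfg <- sim_config(peaks = single_peak_cfg()$peaks, n_transients = 2,
                    n_channels = 2,
                    channel_sensitivities = c(1i, -1))
  ts <- quick_1h(cfg, n_points = 256)
  w <- simulate_water_reference(cfg, n_points = 256)
  for (m in c("adaptive", "snr2", "svd")) {
    res <- coil_combine(ts, m, water_ref = w)
    wc <- apply_coil_weights(w, res$weights)
    expect_gt(Re(wc$data[1, 1, 1]), 0)
    expect_lt(abs(Arg(wc$data[1, 1, 1])), 1e-8)
  }
})

test_that("water reference with mismatched channel count is rejected", {
  cfg <- sim_config(n_transients = 2, n_channels = 2,
                    channel_sensitivities = c(1, 1))
  ts <- quick_1h(cfg, n_points = 128)
  w <- simulate_water_reference(sim_config(n_transients = 2),
                                n_points = 128)
  expect_error(coil_combine(ts, "svd", water_ref = w), "channel count")
})
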