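test_that("axis construction follows the centred, descending convention", {
  ax <- build_axes(4, 0.25, 1, 0)
  expect_equal(ax$hz, c(1, 0, -1, -2))
  expect_equal(ax$ppm, ax$hz / 1 + 0)

  # a 4 kHz bandwidth spans 4000 Hz across the grid
  ax2 <- build_axes(4096, 1 / 4000, 297.2, 4.7)
  expect_equal(diff(range(ax2$hz)), 4000 * (4095 / 4096))
  expect_equal(ax2$hz[1] - ax2$hz[2], 4000 / 4096)
  expect_true(all(diff(ax2$ppm) < 0))
  expect_equal(ax2$ppm, ax2$hz / 297.2 + 4.7)

  expect_error(build_axes(1, 0.25, 1), "n_points")
  expect_error(build_axes(16, -1, 1), "dwell")
  expect_error(build_axes(16, 0.25, 0), "f0")
})

test_that("ppm/index conversions round-trip on the grid", {
  ax <- build_axes(256, 1 / 4000, 297.2, 4.7)
  ks <- c(1L, 2L, 128L, 200L, 256L)
  expect_identical(ppm_to_index(ax$ppm, index_to_ppm(ax$ppm, ks)), ks)
})

test_that("transient_set validates its invariants", {
  expect_error(transient_set(complex(1), 1e-4, 297.2), "2 points")
  expect_error(transient_set(complex(8), 0, 297.2), "dwell_time")
  expect_error(transient_set(complex(8), 1e-4, -1), "f0")
  ts <- transient_set(matrix(0i, 3, 16), 1e-4, 297.2)
  expect_equal(c(n_transients(ts), n_channels(ts), n_points(ts)),
               c(3L, 1L, 16L))
})

test_that("FID/spectrum transforms invert each other and place peaks", {
  n <- 1024
  dw <- 1 / 4000
  # impulse at t = 0 has flat magnitude
  ts <- transient_set(c(1, rep(0, n - 1)) + 0i, dw, 297.2)
  sp <- fid_to_spectrum(ts)
  expect_equal(Mod(sp$values), rep(1, n))

  # complex exponential at +50 Hz lands at the argmax bin of the full grid
  fid <- exp(2i * pi * 50 * (0:(n - 1)) * dw)
  sp2 <- fid_to_spectrum(transient_set(fid, dw, 297.2))
  oracle_bin <- which.max(Mod(sp2$values))
  expect_lt(abs(sp2$hz_axis[oracle_bin] - 50), 4000 / n + 1e-9)

  # round trip to numerical precision
  set.seed(7)
  fid3 <- complex(real = rnorm(n), imaginary = rnorm(n))
  ts3 <- transient_set(fid3, dw, 297.2)
  back <- spectrum_to_fid(fid_to_spectrum(ts3))
  expect_lt(max(Mod(back - fid3)) / max(Mod(fid3)), 1e-10)

  expect_error(fid_to_spectrum(transient_set(array(0i, c(1, 2, 8)),
                                             dw, 297.2)),
               "combine")
  expect_error(fid_to_spectrum(ts3, transient = 2), "out of range")
})

test_that("Parseval's relation holds for the forward transform", {
  set.seed(11)
  for (n in c(64, 255, 1024)) {
    fid <- complex(real = rnorm(n), imaginary = rnorm(n))
    sp <- fid_to_spectrum(transient_set(fid, 1 / 4000, 297.2))
    expect_lt(abs(sum(Mod(fid)^2) - sum(Mod(sp$values)^2) / n) /
                sum(Mod(fid)^2), 1e-8)
  }
})

test_that("a Hz shift moves the ppm location by df/f0 for any nucleus", {
  n <- 2048
  for (f0 in c(49.9, 120.7, 297.2)) {
    dw <- 1 / 4000
    tvec <- (0:(n - 1)) * dw
    df <- 120
    decay <- exp(-pi * 8 * tvec)
    sp0 <- fid_to_spectrum(transient_set(decay, dw, f0, nucleus = "31P"))
    sp1 <- fid_to_spectrum(transient_set(
      decay * exp(2i * pi * df * tvec), dw, f0, nucleus = "31P"))
    p0 <- sp0$ppm_axis[which.max(Mod(sp0$values))]
    p1 <- sp1$ppm_axis[which.max(Mod(sp1$values))]
    bin_ppm <- (4000 / n) / f0
    expect_lt(abs((p1 - p0) - df / f0), bin_ppm + 1e-9)
  }
})

test_that("alignment_result and quality_metrics enforce their invariants", {
  expect_error(alignment_result(c(1, NaN), c(0, 0)))
  ar <- alignment_result(c(1, -2), c(30, -10))
  expect_length(ar$freq_shifts_hz, 2)
  qm <- new_quality_metrics(50, 9.5, 297.2)
  expect_equal(qm$fwhm_hz, qm$fwhm_ppm * 297.2)
  expect_error(new_quality_metrics(-1, 9.5, 297.2))
})
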