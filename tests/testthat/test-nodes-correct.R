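test_that("eddy-current correction is exact algebra on shared phase", {
  # water with identically zero phase leaves the data untouched
  ts <- quick_1h(single_peak_cfg(n_transients = 2), n_points = 512)
  tvec <- (0:511) / 4000
  w_real <- transient_set(100 * exp(-pi * 10 * tvec) + 0i, 1 / 4000, 297.2,
                          role = "water_reference")
  expect_equal(eddy_current_correct(ts, w_real)$data, ts$data)

  # metabolite identical to water: correction leaves |w|, real non-negative
  w_dist <- w_real
  w_dist$data[1, 1, ] <- w_real$data[1, 1, ] *
    exp(1i * 0.8 * exp(-tvec / 0.1))
  self <- eddy_current_correct(w_dist, w_dist)
  expect_lt(max(abs(Im(self$data))), 1e-10)
  expect_true(all(Re(self$data) >= -1e-12))

  # injected eddy phase cancels to numerical precision
  cfg_e <- sim_config(peaks = single_peak_cfg()$peaks, n_transients = 3,
                      eddy_amp_rad = 0.8, eddy_decay_s = 0.1)
  cfg_0 <- sim_config(peaks = single_peak_cfg()$peaks, n_transients = 3)
  m_dist <- quick_1h(cfg_e, n_points = 512)
  w_ref <- simulate_water_reference(cfg_e, n_points = 512)
  clean <- quick_1h(cfg_0, n_points = 512)
  corr <- eddy_current_correct(m_dist, w_ref)
  expect_lt(max(Mod(corr$data - clean$data)) / max(Mod(clean$data)), 1e-8)
})

test_that("water samples below machine precision hold the last valid phase", {
  tvec <- (0:255) / 4000
  w <- transient_set(exp(1i * 0.5 * exp(-tvec / 0.05)) + 0i, 1 / 4000,
                     297.2, role = "water_reference")
  w$data[1, 1, 200:256] <- 0 + 0i
  ts <- quick_1h(single_peak_cfg(), n_points = 256)
  expect_silent(out <- eddy_current_correct(ts, w))
  # the held phase equals the phase at the last valid point
  held <- Arg(exp(1i * 0.5 * exp(-tvec[199] / 0.05)))
  expect_equal(Arg(out$data[1, 1, 256] / ts$data[1, 1, 256]), -held,
               tolerance = 1e-10)
})

test_that("outlier rejection removes exactly the planted artifact", {
  cfg <- sim_config(n_transients = 32, noise_sigma = 0.002,
                    outlier_indices = 17, outlier_gain = 20, seed = 41)
  ts <- quick_1h(cfg, n_points = 512)
  res <- remove_bad_averages(ts, k_sd = 3)
  expect_identical(res$removed_indices, 17L)
  expect_identical(res$kept_indices, setdiff(1:32, 17L))
  # oracle: direct score computation
  mean_fid <- apply(ts$data[, 1, , drop = FALSE], 3, mean)
  scores <- vapply(1:32, function(t)
    sqrt(mean(Mod(ts$data[t, 1, ] - mean_fid)^2)), numeric(1))
  expect_equal(res$scores, scores)
  expect_identical(which(scores > mean(scores) + 3 * sd(scores)), 17L)
  # kept transients keep their order and content
  expect_identical(res$ts$data, ts$data[-17, , , drop = FALSE])
})

test_that("outlier rejection degenerate cases", {
  ts <- quick_1h(single_peak_cfg(n_transients = 5), n_points = 128)
  # identical transients: zero-variance scores, none removed
  res <- remove_bad_averages(ts)
  expect_length(res$removed_indices, 0)
  # unreachable threshold removes nothing
  cfg <- sim_config(n_transients = 8, noise_sigma = 0.05, seed = 4)
  res2 <- remove_bad_averages(quick_1h(cfg, n_points = 128), k_sd = 1e6)
  expect_length(res2$removed_indices, 0)
  expect_error(remove_bad_averages(
    quick_1h(single_peak_cfg(n_transients = 2), n_points = 128)),
    "at least 3")
})
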