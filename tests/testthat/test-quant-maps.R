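test_that("voxel tissue fractions average the probability maps", {
  d <- c(16, 16, 8)
  box <- list(x = c(5, 8), y = c(5, 8), z = c(3, 5))
  # uniform volumes pass through
  tf <- voxel_tissue_fractions(array(0.6, d), array(0.3, d),
                               array(0.1, d), box)
  expect_equal(c(tf$f_gm, tf$f_wm, tf$f_csf), c(0.6, 0.3, 0.1))
  # all-CSF voxel
  tf2 <- voxel_tissue_fractions(array(0, d), array(0, d), array(1, d), box)
  expect_equal(c(tf2$f_gm, tf2$f_wm, tf2$f_csf), c(0, 0, 1))
  # half-GM/half-WM split voxel (oracle: voxel average over the box)
  gm <- array(0, d); gm[1:8, , ] <- 1
  wm <- array(0, d); wm[9:16, , ] <- 1
  tf3 <- voxel_tissue_fractions(gm, wm, array(0, d),
                                list(x = c(5, 12), y = c(5, 8),
                                     z = c(3, 5)))
  expect_equal(c(tf3$f_gm, tf3$f_wm, tf3$f_csf), c(0.5, 0.5, 0))
  expect_error(voxel_tissue_fractions(gm, wm, array(0, c(4, 4, 4)), box),
               "shape")
  expect_error(voxel_tissue_fractions(gm, wm, array(0, d),
                                      list(x = c(0, 4), y = c(1, 2),
                                           z = c(1, 2))),
               "outside")
})

test_that("water concentration follows the tissue-water convention", {
  tf <- function(g, w, c) list(f_gm = g, f_wm = w, f_csf = c)
  expect_equal(water_concentration(tf(0, 0, 1)), 55510 * 0.97)
  expect_equal(water_concentration(tf(0, 0, 1)), 53844.7)
  expect_equal(water_concentration(tf(1, 0, 0)), 55510 * 0.78)
  expect_equal(water_concentration(tf(1, 0, 0)), 43297.8)
  # equal fractions give the mean of the pure-tissue values
  expect_equal(water_concentration(tf(1 / 3, 1 / 3, 1 / 3)),
               mean(55510 * c(0.78, 0.65, 0.97)))
  expect_error(water_concentration(tf(0, 0, 0)), "zero")
  # linearity and bounds over random simplex fractions
  set.seed(2)
  for (i in 1:20) {
    f <- as.numeric(stats::runif(3))
    f <- f / sum(f)
    w <- water_concentration(tf(f[1], f[2], f[3]))
    expect_gte(w, 55510 * 0.65)
    expect_lte(w, 55510 * 0.97)
  }
  # constants are overridable
  expect_equal(water_concentration(tf(1, 0, 0),
                                   water_content = c(gm = 0.8, wm = 0.65,
                                                     csf = 0.97)),
               55510 * 0.8)
})

test_that("the fitter contract degrades gracefully and accepts a stub", {
  ts <- average_all(simulate_transients(sim_config(n_transients = 2),
                                        n_points = 128))
  td <- tempfile("fit")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  raw <- file.path(td, "s.RAW")
  write_lcmodel_raw(ts, raw)
  ctl <- file.path(td, "s.control")
  writeLines(generate_control_file(control_template(), ts = ts), ctl)

  # no binary configured: notice, NULL, files left in place
  expect_message(out <- run_fitter(raw, ctl, fitter = ""), "external")
  expect_null(out)
  expect_true(file.exists(raw) && file.exists(ctl))

  # stub fitter emits the fixture COORD; parsed result matches it
  qr <- coord_fixture()
  fx <- file.path(td, "fixture.COORD")
  write_coord(qr, fx)
  stub <- make_stub_fitter(fx)
  got <- run_fitter(raw, ctl, fitter = stub)
  expect_identical(got$records$metabolite, qr$records$metabolite)
  expect_equal(got$records$crlb_pct, qr$records$crlb_pct)

  # failing stub raises a warning and returns NULL
  bad <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "cat > /dev/null", "exit 3"), bad)
  Sys.chmod(bad, "0755")
  expect_warning(out2 <- run_fitter(raw, ctl, fitter = bad), "status")
  expect_null(out2)
})

test_that("per-voxel CSI fitting yields one COORD per voxel folder", {
  cfg <- single_peak_cfg(ppm = 0)
  csi <- simulate_csi(cfg, matrix_size = c(2, 2, 1), n_points = 32,
                      amplitude_map = array(1, c(2, 2, 1)))
  dir <- tempfile("vox")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  vout <- write_csi_voxel_outputs(csi, dir)
  qr <- coord_fixture()
  qr$records$metabolite <- c("NAD+", "PCr", "Pi")
  fx <- file.path(dir, "fixture.COORD")
  write_coord(qr, fx)
  stub <- make_stub_fitter(fx)
  ctl <- file.path(dir, "v.control")
  writeLines(control_template(), ctl)
  for (p in vout$path)
    run_fitter(p, ctl, fitter = stub)
  grid <- collect_csi_quant(dir)
  expect_equal(sort(unique(paste(grid$vx, grid$vy, grid$vz))),
               sort(c("0 0 0", "1 0 0", "0 1 0", "1 1 0")))
  expect_equal(nrow(grid), 4 * 3)
})

test_that("metabolite maps apply the strict double CRLB threshold", {
  qg <- synthetic_quant_grid(
    nx = 4, ny = 4, nz = 2,
    crlb_fun = function(vx, vy, vz) if (vx < 2) 10 else 25)
  m <- metabolite_map(qg, "NAD+", reference = "PCr",
                      crlb_threshold_pct = 20, slice_idx = 0)
  expect_equal(dim(m$values), c(4L, 4L))
  expect_true(all(m$mask[1:2, ]))
  expect_false(any(m$mask[3:4, ]))
  expect_true(all(is.na(m$values[!m$mask])))

  # the reference CRLB masks a voxel even when the metabolite passes
  qg2 <- synthetic_quant_grid(nx = 2, ny = 2, nz = 1)
  qg2$crlb_pct[qg2$metabolite == "PCr"] <- 25
  m2 <- metabolite_map(qg2, "NAD+", reference = "PCr",
                       crlb_threshold_pct = 20, slice_idx = 0)
  expect_false(any(m2$mask))
  # without a reference the metabolite CRLB alone decides
  m3 <- metabolite_map(qg2, "NAD+", crlb_threshold_pct = 20,
                       slice_idx = 0)
  expect_true(all(m3$mask))

  # the threshold is strict: CRLB == threshold is excluded
  qg3 <- synthetic_quant_grid(nx = 2, ny = 2, nz = 1,
                              crlb_fun = function(...) 20)
  m4 <- metabolite_map(qg3, "NAD+", crlb_threshold_pct = 20,
                       slice_idx = 0)
  expect_false(any(m4$mask))

  expect_error(metabolite_map(qg, "Unobtainium"), "not present")
  expect_error(metabolite_map(qg, "NAD+", as_ratio = TRUE), "reference")
})

test_that("raising the CRLB threshold never shrinks the mask", {
  set.seed(14)
  qg <- synthetic_quant_grid(nx = 6, ny = 6, nz = 1,
                             crlb_fun = function(...) runif(1, 2, 40))
  prev <- matrix(FALSE, 6, 6)
  for (thr in c(5, 10, 20, 30, 50)) {
    m <- metabolite_map(qg, "NAD+", reference = "PCr",
                        crlb_threshold_pct = thr, slice_idx = 0)
    expect_true(all(prev[m$mask == FALSE] == FALSE))
    expect_true(all(m$mask[prev]))
    prev <- m$mask
  }
})

test_that("ratio maps of a metabolite to itself are identically one", {
  qg <- synthetic_quant_grid(nx = 3, ny = 3, nz = 1)
  m <- metabolite_map(qg, "NAD+", reference = "NAD+", as_ratio = TRUE,
                      crlb_threshold_pct = 20, slice_idx = 0)
  expect_true(all(m$values[m$mask] == 1))
})

test_that("anatomical projection interpolates within bounds or passes through", {
  qg <- synthetic_quant_grid(nx = 4, ny = 4, nz = 1,
                             crlb_fun = function(vx, vy, vz)
                               if (vx == 0 && vy == 0) 30 else 5)
  m <- metabolite_map(qg, "NAD+", crlb_threshold_pct = 20, slice_idx = 0)
  # no anatomy: unchanged
  expect_identical(project_to_anatomy(m), m)
  # constant map stays constant after interpolation
  qgc <- synthetic_quant_grid(nx = 4, ny = 4, nz = 1)
  qgc$concentration[qgc$metabolite == "NAD+"] <- 2.5
  mc <- metabolite_map(qgc, "NAD+", crlb_threshold_pct = 20,
                       slice_idx = 0)
  pc <- project_to_anatomy(mc, matrix(0, 64, 64))
  expect_equal(unique(stats::na.omit(as.vector(pc$values))), 2.5)
  # 4x4 -> 64x64: shape, bounds, and masked voxels never leak in
  p <- project_to_anatomy(m, matrix(0, 64, 64))
  expect_equal(dim(p$values), c(64L, 64L))
  expect_gte(min(p$values, na.rm = TRUE), min(m$values, na.rm = TRUE))
  expect_lte(max(p$values, na.rm = TRUE), max(m$values, na.rm = TRUE))
  expect_error(project_to_anatomy(m, matrix(0, 2, 2)), "at least")
  expect_error(project_to_anatomy(m, matrix(0, 64, 64),
                                  brain_mask = matrix(TRUE, 8, 8)),
               "dimensions")
})
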