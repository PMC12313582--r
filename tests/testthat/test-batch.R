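test_that("batch folder creation matches the documented tree", {
  root <- tempfile("batch")
  dir.create(root)
  on.exit(unlink(root, recursive = TRUE), add = TRUE)
  sd <- make_batch_folder(root, "MYSTUDY", 2)
  expect_true(file.exists(file.path(sd, "MYSTUDY.control")))
  expect_true(file.exists(file.path(sd, "MYSTUDY.basis")))
  expect_true(dir.exists(file.path(sd, "PARTICIPANT_1",
                                   "tissue_segmentation_files")))
  expect_true(dir.exists(file.path(sd, "PARTICIPANT_2")))
  expect_error(make_batch_folder(root, "MYSTUDY", 2), "not empty")
  expect_error(make_batch_folder(root, "A/B", 2), "separators")
  expect_error(make_batch_folder(root, "OK", 0), "positive integer")
})

fill_participant <- function(sd, k, seed = k, corrupt = FALSE,
                             water = TRUE) {
  cfg <- sim_config(n_transients = 8, n_channels = 2,
                    channel_sensitivities = c(1, 1), noise_sigma = 0.003,
                    seed = seed)
  pdir <- file.path(sd, sprintf("PARTICIPANT_%d", k))
  mf <- file.path(pdir, "scan_metabolite.nii.gz")
  if (corrupt) writeLines("garbage", mf)
  else write_nifti_mrs(simulate_transients(cfg, n_points = 256), mf)
  if (water)
    write_nifti_mrs(simulate_water_reference(cfg, n_points = 256),
                    file.path(pdir, "scan_water_reference.nii.gz"))
  invisible(pdir)
}

test_that("batch validation flags missing and misformatted files", {
  root <- tempfile("batch")
  dir.create(root)
  on.exit(unlink(root, recursive = TRUE), add = TRUE)
  sd <- make_batch_folder(root, "S", 3)
  fill_participant(sd, 1)
  fill_participant(sd, 2)
  # participant 3: wrong extension
  writeLines("x", file.path(sd, "PARTICIPANT_3", "scan_metabolite.sdat"))
  rep <- validate_batch_folder(sd)
  expect_true(rep$study_ok)
  expect_true(all(rep$participants$runnable[1:2]))
  expect_false(rep$participants$runnable[3])
  expect_match(rep$participants$messages[3], "unsupported")

  # remove a metabolite file: that participant is flagged, others pass
  unlink(file.path(sd, "PARTICIPANT_1", "scan_metabolite.nii.gz"))
  rep2 <- validate_batch_folder(sd)
  expect_false(rep2$participants$runnable[1])
  expect_match(rep2$participants$messages[1], "missing")
  expect_true(rep2$participants$runnable[2])
})

test_that("batch runs isolate failures and reproduce single runs", {
  root <- tempfile("batch")
  dir.create(root)
  on.exit(unlink(root, recursive = TRUE), add = TRUE)
  sd <- make_batch_folder(root, "S", 3)
  fill_participant(sd, 1)
  fill_participant(sd, 2, corrupt = TRUE)
  fill_participant(sd, 3)
  p <- preset_pipeline("svs_1h")
  res <- suppressWarnings(run_batch(sd, p))
  expect_null(res$results$PARTICIPANT_2)
  expect_false(is.null(res$results$PARTICIPANT_1))
  expect_false(is.null(res$results$PARTICIPANT_3))
  expect_equal(nrow(res$errors), 1L)
  expect_identical(res$errors$participant, "PARTICIPANT_2")
  ledger <- readLines(file.path(sd, "outputs", "errors.jsonl"))
  expect_length(ledger, 1L)
  entry <- jsonlite::fromJSON(ledger)
  expect_identical(entry$participant, "PARTICIPANT_2")

  # the batch result equals an identical single run on the same files
  single_in <- read_nifti_mrs(file.path(sd, "PARTICIPANT_1",
                                        "scan_metabolite.nii.gz"))
  single_w <- read_nifti_mrs(file.path(sd, "PARTICIPANT_1",
                                       "scan_water_reference.nii.gz"))
  single <- run_pipeline(single_in, p, water_ref = single_w)
  expect_identical(res$results$PARTICIPANT_1$result, single$result)

  # rerun is deterministic
  res2 <- suppressWarnings(run_batch(sd, p))
  expect_identical(res$results$PARTICIPANT_3$result,
                   res2$results$PARTICIPANT_3$result)
})

test_that("eddy-current correction is skipped with a note when water is absent", {
  root <- tempfile("batch")
  dir.create(root)
  on.exit(unlink(root, recursive = TRUE), add = TRUE)
  sd <- make_batch_folder(root, "S", 1)
  fill_participant(sd, 1, water = FALSE)
  res <- run_batch(sd, preset_pipeline("svs_1h"))
  run <- res$results$PARTICIPANT_1
  expect_match(paste(run$log, collapse = " "), "no water reference")
})
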