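test_that("the node registry enforces the plugin contract", {
  expect_error(plugin_node("x", "a", "d"), "process hook")
  expect_error(plugin_node("", "a", "d", process = identity), "label")
  expect_error(plugin_node("x", "a", "d",
                           params = list(p = list(default = 1)),
                           process = function(i, p, c) i),
               "valid type")

  node <- plugin_node("test_scale", "tester", "scales data",
                      params = list(factor = list(type = "numeric",
                                                  default = 2, min = 0,
                                                  max = 10)),
                      process = function(input, params, context) {
                        input$data <- input$data * params$factor
                        input
                      })
  on.exit(unregister_node("test_scale"), add = TRUE)
  register_node(node)
  expect_true("test_scale" %in% list_nodes()$label)
  expect_error(register_node(node), "already registered")
  expect_identical(get_node("test_scale")$author, "tester")
  expect_error(get_node("no_such_node"), "unknown node type")
})

test_that("plugin files in the designated folder register on rescan", {
  dir <- tempfile("nodes")
  dir.create(dir)
  on.exit({
    unlink(dir, recursive = TRUE)
    unregister_node("folder_node")
  }, add = TRUE)
  writeLines(c(
    'register_node(plugin_node(',
    '  "folder_node", "tester", "negates the data",',
    '  process = function(input, params, context) {',
    '    input$data <- -input$data; input',
    '  }))'), file.path(dir, "folder_node.R"))
  load_custom_nodes(dir)
  expect_true("folder_node" %in% list_nodes()$label)
  # rescan is idempotent
  expect_silent(load_custom_nodes(dir))
  # and the node runs inside a pipeline
  ts <- quick_1h(single_peak_cfg(), n_points = 128)
  run <- run_pipeline(ts, chain_pipeline("folder_node"))
  expect_equal(run$result[[1]]$data, -ts$data)
})

test_that("parameter validation fills defaults and rejects bad values", {
  prm <- validate_node_params("bad_average_removal", list())
  expect_equal(prm$k_sd, 3)
  expect_error(validate_node_params("bad_average_removal",
                                    list(k_sd = -1)), "below minimum")
  expect_error(validate_node_params("bad_average_removal",
                                    list(nope = 1)), "declares no parameter")
  expect_error(validate_node_params("coil_combination",
                                    list(method = "magic")), "one of")
  expect_error(validate_node_params("zero_filling",
                                    list(factor = 2.5)), "integer")
})

test_that("an empty pipeline is the identity", {
  ts <- quick_1h(single_peak_cfg(), n_points = 128)
  run <- run_pipeline(ts, pipeline(list(), name = "empty"))
  expect_identical(run$result[[1]], ts)
})

test_that("step mode and full mode produce identical final data", {
  cfg <- sim_config(n_transients = 8, n_channels = 2,
                    channel_sensitivities = c(1, 1i),
                    noise_sigma = 0.005, freq_drift_hz_per_transient = 0.5,
                    seed = 19)
  ts <- quick_1h(cfg, n_points = 256)
  w <- simulate_water_reference(cfg, n_points = 256)
  p <- preset_pipeline("svs_1h")
  full <- run_pipeline(ts, p, water_ref = w, mode = "full")
  seen <- character(0)
  step <- run_pipeline(ts, p, water_ref = w, mode = "step",
                       step_callback = function(id, payloads)
                         seen <<- c(seen, id))
  expect_identical(full$result, step$result)
  expect_identical(seen, vapply(p$nodes, `[[`, character(1), "node_id"))
})

test_that("execution does not mutate its inputs", {
  cfg <- sim_config(n_transients = 8, noise_sigma = 0.01, seed = 23)
  ts <- quick_1h(cfg, n_points = 256)
  snapshot <- ts
  w <- simulate_water_reference(cfg, n_points = 256)
  wsnap <- w
  run_pipeline(ts, preset_pipeline("svs_1h"), water_ref = w)
  expect_identical(ts, snapshot)
  expect_identical(w, wsnap)
})

test_that("a five-node run writes five step folders plus the pipe copy", {
  cfg <- sim_config(n_transients = 8, n_channels = 2,
                    channel_sensitivities = c(1, 1), noise_sigma = 0.01,
                    seed = 29)
  ts <- quick_1h(cfg, n_points = 256)
  w <- simulate_water_reference(cfg, n_points = 256)
  out <- tempfile("run")
  run_pipeline(ts, preset_pipeline("svs_1h"), water_ref = w,
               output_dir = out, save_intermediate = TRUE)
  steps <- list.files(out, pattern = "^step")
  expect_length(steps, 5L)
  expect_true(file.exists(file.path(out, "pipeline.pipe")))
  expect_true(file.exists(file.path(out, "parameters.csv")))
  # saving off: only the pipe copy and parameter CSV appear
  out2 <- tempfile("run")
  run_pipeline(ts, preset_pipeline("svs_1h"), water_ref = w,
               output_dir = out2, save_intermediate = FALSE)
  expect_length(list.files(out2, pattern = "^step"), 0L)
  expect_true(file.exists(file.path(out2, "pipeline.pipe")))
  unlink(c(out, out2), recursive = TRUE)
})

test_that("node failures abort with the node id in the message", {
  ts <- quick_1h(single_peak_cfg(n_transients = 2), n_points = 128)
  p <- chain_pipeline(c("bad_average_removal"))
  expect_error(run_pipeline(ts, p), "bad_average_removal")
})

test_that("pipe files round-trip byte-identically and validate on load", {
  p <- chain_pipeline(c("bad_average_removal", "averaging"),
                      params = list(bad_average_removal = list(k_sd = 3)),
                      name = "roundtrip")
  f1 <- tempfile(fileext = ".pipe")
  f2 <- tempfile(fileext = ".pipe")
  save_pipe(p, f1)
  save_pipe(load_pipe(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
  # the presets round-trip too
  f4 <- tempfile(fileext = ".pipe")
  save_pipe(preset_pipeline("svs_1h"), f4)
  save_pipe(load_pipe(f4), f4)
  expect_identical(readLines(f4),
                   readLines(system.file("pipelines", "svs_1h.pipe",
                                         package = "mrspipe")))
  unlink(f4)

  # hand-edited out-of-range parameter fails at load
  txt <- readLines(f1)
  bad <- sub('"k_sd": 3', '"k_sd": -5', txt)
  f3 <- tempfile(fileext = ".pipe")
  writeLines(bad, f3)
  expect_error(load_pipe(f3), "below minimum")

  # unknown node type is named in the error
  bad2 <- sub('"node_type": "averaging"', '"node_type": "wizardry"', txt)
  writeLines(bad2, f3)
  expect_error(load_pipe(f3), "wizardry")
  unlink(c(f1, f2, f3))
})

test_that("all five shipped presets load and validate from disk", {
  pipe_dir <- system.file("pipelines", package = "mrspipe")
  files <- list.files(pipe_dir, pattern = "\\.pipe$", full.names = TRUE)
  expect_length(files, 5L)
  for (f in files) {
    p <- load_pipe(f)
    expect_s3_class(p, "pipeline_spec")
    expect_gt(length(p$nodes), 0)
  }
})

test_that("pipelines reject merges, cycles and duplicate ids", {
  a <- node_spec("a", "averaging")
  b <- node_spec("b", "averaging", upstream = "a")
  expect_error(pipeline(list(a, node_spec("a", "averaging"))), "duplicate")
  expect_error(pipeline(list(a, b,
                             node_spec("c", "averaging",
                                       upstream = c("a", "b")))),
               "merges")
  c1 <- node_spec("c1", "averaging", upstream = "c2")
  c2 <- node_spec("c2", "averaging", upstream = "c1")
  expect_error(pipeline(list(c1, c2)), "source|cycle")
})
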