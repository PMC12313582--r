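# Built-in node library: thin wrappers exposing the processing operations
# through the plugin contract. Registered at package load.

note_log <- function(ctx, msg) {
  ctx$log <- c(ctx$log, msg)
  invisible(NULL)
}

payload_is_ts <- function(x) inherits(x, "transient_set")
payload_is_csi <- function(x) inherits(x, "csi_grid")

plot_ts_payload <- function(input, output, params) {
  ts <- if (payload_is_ts(output)) output else NULL
  if (is.null(ts) || n_channels(ts) > 1L) return(invisible(NULL))
  sp <- fid_to_spectrum(ts, 1L)
  graphics::plot(sp$ppm_axis, Re(sp$values), type = "l",
                 xlim = rev(range(sp$ppm_axis)),
                 xlab = "chemical shift [ppm]", ylab = "real part")
  invisible(NULL)
}

builtin_node_list <- function() {
  list(
    plugin_node(
      "coil_combination", "mrspipe", "Combine multi-receiver channels",
      params = list(method = list(type = "choice", default = "adaptive",
                                  choices = c("adaptive", "snr2", "svd"))),
      process = function(input, params, context) {
        if (!payload_is_ts(input))
          stop("coil_combination expects a transient_set")
        if (n_channels(input) == 1L) return(input)
        res <- coil_combine(input, method = params$method,
                            water_ref = context$water)
        context$extras[["coil_weights"]] <- res$weights
        if (!is.null(context$water) && n_channels(context$water) > 1L)
          context$water <- apply_coil_weights(context$water, res$weights)
        res$ts
      },
      plot = plot_ts_payload, builtin = TRUE),

    plugin_node(
      "frequency_phase_alignment", "mrspipe",
      "Align frequency and phase to the median spectrum",
      params = list(
        ppm_min = list(type = "numeric", default = NA, min = -1000,
                       max = 1000),
        ppm_max = list(type = "numeric", default = NA, min = -1000,
                       max = 1000),
        max_shift_hz = list(type = "numeric", default = 20, min = 0.1,
                            max = 500)),
      process = function(input, params, context) {
        if (!payload_is_ts(input))
          stop("frequency_phase_alignment expects a transient_set")
        if (n_transients(input) < 2L) {
          note_log(context, "alignment skipped: single transient")
          return(input)
        }
        rng <- if (is.na(params$ppm_min) || is.na(params$ppm_max)) NULL
               else c(params$ppm_min, params$ppm_max)
        res <- align_frequency_phase(input, ppm_range = rng,
                                     max_shift_hz = params$max_shift_hz)
        context$extras[["alignment"]] <- res$shifts
        res$ts
      },
      plot = plot_ts_payload, builtin = TRUE),

    plugin_node(
      "eddy_current_correction", "mrspipe",
      "Klose eddy-current correction from the water reference",
      params = list(),
      process = function(input, params, context) {
        if (is.null(context$water)) {
          note_log(context,
                   "eddy-current correction skipped: no water reference")
          return(input)
        }
        eddy_current_correct(input, context$water)
      },
      plot = plot_ts_payload, builtin = TRUE),

    plugin_node(
      "bad_average_removal", "mrspipe",
      "Reject outlier transients by RMS deviation from the mean",
      params = list(k_sd = list(type = "numeric", default = 3, min = 0,
                                max = 1e6)),
      process = function(input, params, context) {
        res <- remove_bad_averages(input, k_sd = params$k_sd)
        context$extras[["bad_averages"]] <-
          res[c("kept_indices", "removed_indices", "scores", "threshold")]
        res$ts
      },
      plot = plot_ts_payload, builtin = TRUE),

    plugin_node(
      "apodization", "mrspipe", "Lorentzian or Gaussian line broadening",
      params = list(
        shape = list(type = "choice", default = "lorentzian",
                     choices = c("lorentzian", "gaussian")),
        width_hz = list(type = "numeric", default = 2, min = 0, max = 100)),
      process = function(input, params, context) {
        if (payload_is_csi(input)) {
          tvec <- (seq_len(dim(input$data)[4]) - 1) * input$dwell_time
          env <- switch(params$shape,
                        lorentzian = exp(-pi * params$width_hz * tvec),
                        gaussian = exp(-(pi * params$width_hz * tvec)^2 /
                                         (4 * log(2))))
          input$data <- sweep(input$data, 4, env, "*")
          return(input)
        }
        apodize(input, shape = params$shape, width_hz = params$width_hz)
      },
      plot = plot_ts_payload, builtin = TRUE),

    plugin_node(
      "zero_filling", "mrspipe", "Extend FIDs with zeros",
      params = list(factor = list(type = "integer", default = 2, min = 1,
                                  max = 64)),
      process = function(input, params, context)
        zero_fill(input, factor = params$factor),
      plot = plot_ts_payload, builtin = TRUE),

    plugin_node(
      "averaging", "mrspipe", "Average all transients",
      params = list(),
      process = function(input, params, context) average_all(input),
      plot = plot_ts_payload, builtin = TRUE),

    plugin_node(
      "blocked_averaging", "mrspipe",
      "Blocked averaging for functional designs",
      params = list(
        meas_per_block = list(type = "integer", default = 16, min = 1,
                              max = 100000),
        avgs_per_block = list(type = "integer", default = 1, min = 1,
                              max = 100000),
        n_block_types = list(type = "integer", default = 1, min = 1,
                             max = 1000)),
      process = function(input, params, context) {
        res <- blocked_average(input, params$meas_per_block,
                               params$avgs_per_block, params$n_block_types)
        context$extras[["blocked_averaging"]] <- res$table
        res$outputs
      },
      plot = plot_ts_payload, builtin = TRUE),

    plugin_node(
      "moving_averaging", "mrspipe", "Sliding-window averaging",
      params = list(window_length = list(type = "integer", default = 5,
                                         min = 1, max = 100000)),
      process = function(input, params, context)
        moving_average(input, params$window_length),
      plot = plot_ts_payload, builtin = TRUE),

    plugin_node(
      "quality_metrics", "mrspipe",
      "SNR and water linewidth (data pass through unchanged)",
      params = list(
        signal_ppm_min = list(type = "numeric", default = 1.8),
        signal_ppm_max = list(type = "numeric", default = 2.2),
        noise_ppm_min = list(type = "numeric", default = 0.2),
        noise_ppm_max = list(type = "numeric", default = 0.5)),
      process = function(input, params, context) {
        if (payload_is_ts(input) && !is.null(context$water) &&
            n_channels(input) == 1L) {
          qm <- tryCatch(
            quality_metrics(
              fid_to_spectrum(average_all(input)),
              fid_to_spectrum(average_all(context$water)),
              nucleus = input$nucleus,
              signal_ppm = c(params$signal_ppm_min, params$signal_ppm_max),
              noise_ppm = c(params$noise_ppm_min, params$noise_ppm_max)),
            error = function(e) NULL)
          if (!is.null(qm)) context$extras[["quality_metrics"]] <- qm
          else note_log(context, "quality metrics not computable")
        } else {
          note_log(context, "quality metrics skipped")
        }
        input
      },
      plot = plot_ts_payload, builtin = TRUE),

    plugin_node(
      "hanning_filter_3d", "mrspipe", "3D Hanning k-space filter for CSI",
      params = list(),
      process = function(input, params, context) {
        if (!payload_is_csi(input))
          stop("hanning_filter_3d expects a csi_grid")
        was_image <- input$state == "image"
        out <- hanning_filter_3d(csi_to_kspace(input))
        if (was_image) csi_to_image(out) else out
      },
      builtin = TRUE),

    plugin_node(
      "entropy_phasing", "mrspipe",
      "Entropy-minimization zero/first order phasing",
      params = list(gamma = list(type = "numeric", default = 1000, min = 0,
                                 max = 1e9)),
      process = function(input, params, context) {
        if (!payload_is_ts(input) || n_transients(input) != 1L ||
            n_channels(input) != 1L)
          stop("entropy_phasing expects one averaged single-channel transient")
        res <- entropy_min_phase(fid_to_spectrum(input),
                                 gamma = params$gamma)
        context$extras[["entropy_phasing"]] <-
          res[c("phi0_deg", "phi1_deg_per_ppm")]
        set_data(input, spectrum_to_fid(res$spectrum))
      },
      plot = plot_ts_payload, builtin = TRUE),

    plugin_node(
      "manual_adjustment", "mrspipe",
      "Manual frequency offset and zero/first order phasing",
      params = list(
        freq_offset_hz = list(type = "numeric", default = 0, min = -1000,
                              max = 1000),
        phi0_deg = list(type = "numeric", default = 0, min = -360,
                        max = 360),
        phi1_deg_per_ppm = list(type = "numeric", default = 0, min = -360,
                                max = 360)),
      process = function(input, params, context)
        manual_adjust(input, params$freq_offset_hz, params$phi0_deg,
                      params$phi1_deg_per_ppm,
                      log_file = context$adjust_log),
      plot = plot_ts_payload, builtin = TRUE))
}

register_builtin_nodes <- function() {
  for (node in builtin_node_list()) register_node(node, overwrite = TRUE)
}
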