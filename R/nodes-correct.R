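#' Klose eddy-current correction
#'
#' Removes the time-dependent phase distortion induced by gradient eddy
#' currents using the phase of the unsuppressed water acquisition: with
#' \eqn{\bar w(n)} the mean water FID,
#' \deqn{s_{corr}(n) = s(n)\, e^{-i \arg \bar w(n)}}
#' applied to every transient. Since metabolite and water acquisitions see
#' the same eddy-current phase, the distortion cancels exactly. Water
#' samples whose magnitude falls below machine precision carry no usable
#' phase; the last valid phase is held there.
#'
#' @param ts A single-channel metabolite [transient_set].
#' @param water_ts The matching single-channel water-reference
#'   [transient_set] (same number of points and dwell time).
#' @return The corrected [transient_set].
#' @export
eddy_current_correct <- function(ts, water_ts) {
  validate_transient_set(ts)
  validate_transient_set(water_ts)
  if (n_channels(ts) > 1L || n_channels(water_ts) > 1L)
    stop("combine coils before eddy-current correction", call. = FALSE)
  if (n_points(ts) != n_points(water_ts))
    stop("metabolite and water data differ in n_points", call. = FALSE)
  if (abs(ts$dwell_time - water_ts$dwell_time) > 1e-12 * ts$dwell_time)
    stop("metabolite and water data differ in dwell time", call. = FALSE)

  wbar <- apply(water_ts$data[, 1L, , drop = FALSE], 3, mean)
  mag <- Mod(wbar)
  valid <- mag > .Machine$double.eps * max(mag)
  phase <- Arg(wbar)
  if (!all(valid)) {
    if (!any(valid))
      stop("water reference is identically zero", call. = FALSE)
    # hold phase from the last valid sample
    last <- phase[which(valid)[1]]
    for (n in seq_along(phase)) {
      if (valid[n]) last <- phase[n] else phase[n] <- last
    }
  }
  corr <- exp(-1i * phase)
  for (t in seq_len(n_transients(ts)))
    ts$data[t, 1L, ] <- ts$data[t, 1L, ] * corr
  ts
}

#' Remove motion-corrupted or outlier transients
#'
#' Scores each transient by the root-mean-square of its complex difference
#' from the mean of all transients, and drops those whose score exceeds
#' \eqn{\mu_{score} + k \cdot \sigma_{score}}. A single pass is made; the
#' order and content of the surviving transients are untouched. If the rule
#' would remove every transient, the input is returned unchanged with a
#' warning.
#'
#' @param ts A single-channel [transient_set] with at least 3 transients.
#' @param k_sd Rejection threshold in score standard deviations (default 3).
#' @return A list with class `bad_average_result`: `ts` (kept transients),
#'   `kept_indices`, `removed_indices`, `scores`, `threshold`.
#' @export
remove_bad_averages <- function(ts, k_sd = 3) {
  validate_transient_set(ts)
  if (n_channels(ts) > 1L)
    stop("combine coils before bad-average removal", call. = FALSE)
  nt <- n_transients(ts)
  if (nt < 3L)
    stop("bad-average removal needs at least 3 transients", call. = FALSE)
  mean_fid <- apply(ts$data[, 1L, , drop = FALSE], 3, mean)
  scores <- vapply(seq_len(nt), function(t)
    sqrt(mean(Mod(ts$data[t, 1L, ] - mean_fid)^2)), numeric(1))
  threshold <- mean(scores) + k_sd * stats::sd(scores)
  keep <- which(scores <= threshold)
  if (length(keep) == 0L) {
    warning("bad-average removal would drop every transient; keeping all",
            call. = FALSE)
    keep <- seq_len(nt)
  }
  structure(list(ts = subset_transients(ts, keep), kept_indices = keep,
                 removed_indices = setdiff(seq_len(nt), keep),
                 scores = scores, threshold = threshold),
            class = "bad_average_result")
}
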