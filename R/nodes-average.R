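#' Blocked averaging for functional MRS
#'
#' Splits the acquisition into experimental blocks of `meas_per_block`
#' consecutive transients, assigns block types cyclically
#' (type = block index mod `n_block_types`, for e.g. rest/active designs),
#' and produces `avgs_per_block` averaged spectra per block by averaging
#' consecutive groups of `meas_per_block / avgs_per_block` transients.
#' Example: a 16-transient block with 4 averages per block yields 4 outputs,
#' each averaging 4 consecutive transients; 128 transients at 16 per block
#' with 1 average per block and 2 block types yield 8 outputs. Each block
#' type is treated independently: outputs are grouped by type.
#'
#' @param ts A [transient_set]; `n_transients` must divide into whole
#'   blocks, and `meas_per_block` into whole averaging groups.
#' @param meas_per_block Transients per experimental block.
#' @param avgs_per_block Averaged spectra to produce per block.
#' @param n_block_types Number of distinct experimental conditions.
#' @return A list with class `blocked_average_result`: `outputs` (flat list
#'   of single-transient [transient_set]s in acquisition order, each tagged
#'   with `block_type`, `block_index` and `group_in_block` in `acq_meta`),
#'   `by_type` (the same outputs grouped per block type), and `table`
#'   (a data frame indexing the outputs).
#' @export
blocked_average <- function(ts, meas_per_block, avgs_per_block,
                            n_block_types = 1L) {
  validate_transient_set(ts)
  nt <- n_transients(ts)
  if (nt %% meas_per_block != 0)
    stop(sprintf(
      "n_transients (%d) is not divisible by meas_per_block (%d)",
      nt, meas_per_block), call. = FALSE)
  if (meas_per_block %% avgs_per_block != 0)
    stop(sprintf(
      "meas_per_block (%d) is not divisible by avgs_per_block (%d)",
      meas_per_block, avgs_per_block), call. = FALSE)
  stopifnot(n_block_types >= 1)
  n_blocks <- nt %/% meas_per_block
  group_size <- meas_per_block %/% avgs_per_block

  outputs <- list()
  rows <- list()
  for (b in seq_len(n_blocks)) {
    btype <- ((b - 1L) %% n_block_types) + 1L
    block_start <- (b - 1L) * meas_per_block
    for (g in seq_len(avgs_per_block)) {
      idx <- block_start + (g - 1L) * group_size + seq_len(group_size)
      avg <- average_all(subset_transients(ts, idx))
      avg$acq_meta$block_type <- btype
      avg$acq_meta$block_index <- b
      avg$acq_meta$group_in_block <- g
      outputs[[length(outputs) + 1L]] <- avg
      rows[[length(rows) + 1L]] <-
        data.frame(output = length(outputs), block_index = b,
                   block_type = btype, group_in_block = g,
                   first_transient = idx[1], last_transient = idx[length(idx)])
    }
  }
  tab <- do.call(rbind, rows)
  by_type <- lapply(seq_len(n_block_types), function(bt)
    outputs[tab$block_type == bt])
  names(by_type) <- paste0("type_", seq_len(n_block_types))
  structure(list(outputs = outputs, by_type = by_type, table = tab),
            class = "blocked_average_result")
}

#' Moving (sliding-window) averaging
#'
#' Averages every `window_length` consecutive transients, advancing the
#' window by one transient at each step: output \eqn{k} is the mean of
#' transients \eqn{k, \dots, k + w - 1}, giving
#' \eqn{n - w + 1} outputs. Preserves temporal resolution while improving
#' SNR for dynamic quantification.
#'
#' @param ts A [transient_set].
#' @param window_length Window size, between 1 (identity) and
#'   `n_transients` (equivalent to [average_all()]).
#' @return A list of single-transient [transient_set]s, each tagged with
#'   `window_start` in `acq_meta`.
#' @export
moving_average <- function(ts, window_length) {
  validate_transient_set(ts)
  nt <- n_transients(ts)
  if (!is.numeric(window_length) || window_length %% 1 != 0 ||
      window_length < 1 || window_length > nt)
    stop(sprintf("`window_length` must be an integer in 1..%d", nt),
         call. = FALSE)
  window_length <- as.integer(window_length)
  lapply(seq_len(nt - window_length + 1L), function(k) {
    avg <- average_all(subset_transients(ts, k + seq_len(window_length) - 1L))
    avg$acq_meta$window_start <- k
    avg
  })
}
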