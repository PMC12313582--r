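#' Combine multi-channel FIDs into a single receiver signal
#'
#' Three standard receiver-combination schemes:
#' \describe{
#'   \item{`snr2`}{Signal/noise-squared weighting: \eqn{w_c \propto
#'     \bar S_c^* / \sigma_c^2}, with \eqn{S_c} the first time point of the
#'     (mean) water-reference FID on channel \eqn{c} and \eqn{\sigma_c} the
#'     channel noise SD estimated from the last 10\% of the FID.}
#'   \item{`svd`}{Weights are the conjugate of the first left singular
#'     vector of the water-reference channel-by-time matrix.}
#'   \item{`adaptive`}{Weights maximise the generalised Rayleigh quotient
#'     \eqn{w^\dagger R_s w / w^\dagger R_n w}, with the signal covariance
#'     \eqn{R_s} built from the leading 5\% of FID samples and the noise
#'     covariance \eqn{R_n} from the last 10\%.}
#' }
#' All methods use the water reference when supplied (falling back to the
#' metabolite data itself otherwise), normalise the weights to unit norm,
#' and rotate them by a global phase so that the combined reference
#' first point is real and positive. Channels carrying no signal get weight
#' zero, with a warning.
#'
#' @param ts A [transient_set] (any number of channels).
#' @param method One of `"adaptive"`, `"snr2"`, `"svd"`.
#' @param water_ref Optional water-reference [transient_set] with the same
#'   channel count; used to derive the weights.
#' @return A list with class `coil_combine_result`:
#'   `ts` (single-channel [transient_set]), `weights` (complex, one per
#'   input channel), `method`.
#' @export
coil_combine <- function(ts, method = c("adaptive", "snr2", "svd"),
                         water_ref = NULL) {
  method <- match.arg(method)
  validate_transient_set(ts)
  nc <- n_channels(ts)
  if (!is.null(water_ref)) {
    validate_transient_set(water_ref)
    if (n_channels(water_ref) != nc)
      stop("water reference has a different channel count", call. = FALSE)
  }
  if (nc == 1L) {
    return(structure(list(ts = ts, weights = complex(real = 1),
                          method = method),
                     class = "coil_combine_result"))
  }

  ref <- if (!is.null(water_ref)) water_ref else ts
  # channel x time matrix of the mean reference FID
  M <- apply(ref$data, c(2, 3), mean)
  dead <- apply(M, 1, function(r) max(Mod(r)) == 0)
  if (any(dead))
    warning(sprintf("channel(s) %s carry no signal; weight set to 0",
                    paste(which(dead), collapse = ", ")), call. = FALSE)

  npts <- ncol(M)
  lead <- seq_len(max(2L, ceiling(0.05 * npts)))
  tail_idx <- seq.int(npts - max(2L, ceiling(0.10 * npts)) + 1L, npts)

  w <- switch(method,
    svd = {
      sv <- svd(M)
      Conj(sv$u[, 1])
    },
    snr2 = {
      s1 <- M[, 1]
      sigma <- apply(M[, tail_idx, drop = FALSE], 1,
                     function(r) stats::sd(c(Re(r), Im(r))))
      sigma[sigma == 0] <- 1   # noiseless reference: plain conjugate match
      Conj(s1) / sigma^2
    },
    adaptive = {
      A <- M[, lead, drop = FALSE]
      N <- M[, tail_idx, drop = FALSE]
      Rs <- A %*% Conj(t(A)) / ncol(A)
      Rn <- N %*% Conj(t(N)) / ncol(N)
      trn <- sum(Mod(diag(Rn)))
      Rn <- if (trn == 0) diag(nrow(Rn)) else
        Rn + diag(1e-6 * trn / nrow(Rn), nrow(Rn))
      ev <- eigen(solve(Rn, Rs))
      Conj(ev$vectors[, which.max(Mod(ev$values))])
    })

  w[dead] <- 0 + 0i
  if (all(Mod(w) == 0))
    stop("all channels carry zero signal; cannot combine", call. = FALSE)
  w <- w / sqrt(sum(Mod(w)^2))
  # global phase: combined reference first point real-positive
  p0 <- sum(w * M[, 1])
  if (Mod(p0) > 0) w <- w * exp(-1i * Arg(p0))

  structure(list(ts = apply_coil_weights(ts, w), weights = w,
                 method = method),
            class = "coil_combine_result")
}

#' Apply previously derived coil weights to a transient set
#'
#' Used to combine a paired acquisition (e.g. the water reference) with the
#' weights derived from [coil_combine()], so both signals see the identical
#' receive combination.
#'
#' @param ts A [transient_set].
#' @param weights Complex vector, one weight per channel.
#' @return A single-channel [transient_set].
#' @export
apply_coil_weights <- function(ts, weights) {
  validate_transient_set(ts)
  if (length(weights) != n_channels(ts))
    stop("one weight per channel required", call. = FALSE)
  nt <- n_transients(ts)
  np <- n_points(ts)
  out <- array(0 + 0i, dim = c(nt, 1L, np))
  if (n_channels(ts) == 1L) {
    out[, 1L, ] <- ts$data[, 1L, ] * weights[1L]
  } else {
    for (t in seq_len(nt)) {
      chans <- array(ts$data[t, , , drop = FALSE], dim = dim(ts$data)[2:3])
      out[t, 1L, ] <- as.vector(weights %*% chans)
    }
  }
  set_data(ts, out)
}
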