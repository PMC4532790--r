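#' Causal Gaussian smoothing of binned counts
#'
#' Convolves each channel with a one-sided (causal) Gaussian kernel:
#' weights \eqn{w_j \propto \exp(-(j\Delta t)^2 / 2\sigma^2)} over past
#' lags `j = 0..floor(4 sigma / dt)`, renormalized to sum to one over the
#' lags actually available at each bin (so a constant input is preserved
#' everywhere, including the start of the session). `kernel_sd = 0` is the
#' identity.
#'
#' @param Y a [spike_counts()] or numeric matrix (channels x bins).
#' @param kernel_sd kernel standard deviation in seconds (`>= 0`).
#' @param bin_width bin width in seconds; taken from `Y` when it is a
#'   `spike_counts` object.
#' @return numeric matrix of the same shape as the input counts.
#' @export
causal_gaussian_smooth <- function(Y, kernel_sd, bin_width = NULL) {
  Ym <- as_count_matrix(Y)
  if (is.null(bin_width))
    bin_width <- if (inherits(Y, "spike_counts")) Y$bin_width else 0.015
  if (kernel_sd < 0) stop("`kernel_sd` must be >= 0", call. = FALSE)
  if (kernel_sd == 0) return(Ym)
  L <- floor(4 * kernel_sd / bin_width)          # truncate at 4 s.d.
  w <- exp(-((0:L) * bin_width)^2 / (2 * kernel_sd^2))
  K <- ncol(Ym)
  out <- matrix(0, nrow(Ym), K)
  # cross-correlation with the reversed kernel == causal convolution;
  # per-bin renormalization handles the left edge
  for (j in 0:min(L, K - 1)) {
    cols <- (j + 1):K
    out[, cols] <- out[, cols] + w[j + 1] * Ym[, cols - j, drop = FALSE]
  }
  norm <- numeric(K)
  for (k in seq_len(K)) norm[k] <- sum(w[seq_len(min(L + 1, k))])
  sweep(out, 2, norm, "/")
}
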