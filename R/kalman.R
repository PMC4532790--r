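#' Kalman filter for the latent LDS
#'
#' Runs the standard linear-Gaussian filtering recursion over binned spike
#' counts, seeded with the prior of the first state, \eqn{s_1 \sim N(\pi_1,
#' S_1)}. In `mode = "steady_state"` the gain is frozen once successive
#' prior covariances agree to `cov_tol` in Frobenius norm (the
#' computationally efficient form used when fitting readouts and decoding);
#' in `mode = "exact"` the per-bin gains are used throughout and the
#' returned `loglik` is the exact innovations-form marginal log-likelihood.
#'
#' @param params an [lds_params()].
#' @param Y a [spike_counts()] (or bare N x K matrix) with `N` matching
#'   `params$N`.
#' @param mode `"exact"` or `"steady_state"`.
#' @param cov_tol Frobenius tolerance for freezing the gain in
#'   steady-state mode.
#' @param keep_gains store the d x N gain for every bin (memory-heavy for
#'   long sessions; the update identity `shat = prior + K nu` is testable
#'   only when gains are kept).
#' @param keep_covs store per-bin prior/posterior state covariances.
#' @return an object of class `filter_result` with elements `shat`
#'   (d x K filtered means), `prior_shat`, `innovations`, `loglik`,
#'   `gains` (list of d x N matrices, or `NULL`), `steady_gain`,
#'   `steady_from`, and optionally `post_cov`/`pred_cov` (d x d x K
#'   arrays).
#' @export
kalman_filter <- function(params, Y, mode = c("exact", "steady_state"),
                          cov_tol = 1e-8, keep_gains = FALSE,
                          keep_covs = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "lds_params"))
  Ym <- as_count_matrix(Y)
  if (nrow(Ym) != params$N)
    stop(sprintf("channel mismatch: params expect %d channels, data has %d",
                 params$N, nrow(Ym)), call. = FALSE)
  if (ncol(Ym) < 1L) stop("need at least one bin", call. = FALSE)
  res <- kalman_filter_cpp(params$M, params$P, params$Ncov, params$R,
                           params$pi1, params$S1, Ym,
                           steady = (mode == "steady_state"),
                           cov_tol = cov_tol, keep_gains = keep_gains,
                           keep_covs = keep_covs)
  gains <- NULL
  if (keep_gains) {
    gains <- lapply(seq_len(ncol(Ym)), function(k) res$gains[, , k, drop = TRUE])
    gains <- lapply(gains, function(g) matrix(g, nrow = params$d))
  }
  structure(list(shat = res$shat, prior_shat = res$prior_shat,
                 innovations = res$innovations, loglik = res$loglik,
                 gains = gains, steady_gain = res$steady_gain,
                 steady_from = res$steady_from,
                 post_cov = res$post_cov, pred_cov = res$pred_cov,
                 mode = mode),
            class = "filter_result")
}

#' Kalman (RTS) smoother
#'
#' Forward filter followed by the Rauch-Tung-Striebel backward pass.
#' Returns smoothed means, covariances, and the lag-one cross-covariances
#' \eqn{Cov(s_k, s_{k-1} \mid Y)} needed by the EM M-step. The returned
#' `loglik` is identical to the exact filter's.
#'
#' @inheritParams kalman_filter
#' @param steady use the steady-state approximation in the forward pass.
#' @return an object of class `smoother_result` with `means` (d x K),
#'   `covs` (d x d x K), `cross_covs` (d x d x (K-1)), `loglik`.
#' @export
kalman_smoother <- function(params, Y, steady = FALSE, cov_tol = 1e-8) {
  stopifnot(inherits(params, "lds_params"))
  Ym <- as_count_matrix(Y)
  if (nrow(Ym) != params$N)
    stop(sprintf("channel mismatch: params expect %d channels, data has %d",
                 params$N, nrow(Ym)), call. = FALSE)
  res <- kalman_smoother_cpp(params$M, params$P, params$Ncov, params$R,
                             params$pi1, params$S1, Ym, steady, cov_tol)
  structure(res, class = "smoother_result")
}

#' Steady-state Kalman gain
#'
#' Fixed point of the discrete Riccati recursion for the one-step prior
#' state covariance, and the corresponding frozen gain.
#'
#' @param params an [lds_params()].
#' @param tol Frobenius convergence tolerance on the prior covariance.
#' @param max_iter iteration cap (error with the residual norm if exceeded).
#' @return list with `gain` (d x N), `prior_cov` (d x d), `iterations`,
#'   `residual`.
#' @export
steady_state_gain <- function(params, tol = 1e-10, max_iter = 100000L) {
  stopifnot(inherits(params, "lds_params"))
  steady_state_gain_cpp(params$M, params$P, params$Ncov, params$R,
                        tol, as.integer(max_iter))
}

#' Marginal log-likelihood of spike counts under an LDS
#'
#' Exact Gaussian innovations-form log-likelihood, equal to the value
#' accumulated by `kalman_filter(mode = "exact")` and by the smoother.
#'
#' @inheritParams kalman_filter
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(params, Y) {
  kalman_filter(params, Y, mode = "exact")$loglik
}
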