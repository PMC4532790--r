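#' Latent linear dynamical system parameters
#'
#' The model is
#' \deqn{s_k = M s_{k-1} + n_k, \qquad n_k \sim N(0, N_{cov})}
#' \deqn{y_k = P s_k + r_k, \qquad r_k \sim N(0, R)}
#' with initial state \eqn{s_1 \sim N(\pi_1, S_1)}. `Ncov` and `R` are
#' diagonal by model assumption; they are stored as full matrices but
#' validated to be diagonal unless `check_diagonal = FALSE` (used by the
#' similarity-transform invariance tests, where diagonality is not
#' preserved).
#'
#' The observation-noise covariance is called `Ncov` here to avoid the
#' clash between the process-noise covariance and the channel count, both
#' conventionally written N.
#'
#' @param M d x d dynamics matrix.
#' @param P N x d observation matrix.
#' @param Ncov d x d process-noise covariance (diagonal, positive).
#' @param R N x N observation-noise covariance (diagonal, positive).
#' @param pi1 length-d initial state mean.
#' @param S1 d x d initial state covariance (symmetric PSD).
#' @param bin_width bin width in seconds.
#' @param check_diagonal validate that `Ncov` and `R` are diagonal.
#' @return an object of class `lds_params`.
#' @export
lds_params <- function(M, P, Ncov, R, pi1 = NULL, S1 = NULL,
                       bin_width = 0.015, check_diagonal = TRUE) {
  M <- as.matrix(M); P <- as.matrix(P)
  d <- nrow(M)
  if (ncol(M) != d) stop("`M` must be square", call. = FALSE)
  if (ncol(P) != d) stop("`P` must have d columns", call. = FALSE)
  N <- nrow(P)
  if (length(Ncov) == 1L) Ncov <- diag(as.numeric(Ncov), d)
  if (is.vector(Ncov)) Ncov <- diag(Ncov, nrow = d)
  if (length(R) == 1L) R <- diag(as.numeric(R), N)
  if (is.vector(R)) R <- diag(R, nrow = N)
  Ncov <- as.matrix(Ncov); R <- as.matrix(R)
  if (!all(dim(Ncov) == d)) stop("`Ncov` must be d x d", call. = FALSE)
  if (!all(dim(R) == N)) stop("`R` must be N x N", call. = FALSE)
  if (check_diagonal) {
    offd <- function(A) max(abs(A - diag(diag(A), nrow(A))))
    if (offd(Ncov) > 0 || offd(R) > 0)
      stop("`Ncov` and `R` must be diagonal (set check_diagonal = FALSE to relax)",
           call. = FALSE)
    if (any(diag(Ncov) < 0) || any(diag(R) < 0))
      stop("noise variances must be non-negative", call. = FALSE)
  }
  if (is.null(pi1)) pi1 <- numeric(d)
  if (is.null(S1)) S1 <- diag(1, d)
  if (length(S1) == 1L) S1 <- diag(as.numeric(S1), d)
  S1 <- as.matrix(S1)
  pi1 <- as.numeric(pi1)
  if (length(pi1) != d) stop("`pi1` must have length d", call. = FALSE)
  if (!all(dim(S1) == d)) stop("`S1` must be d x d", call. = FALSE)
  if (max(abs(S1 - t(S1))) > 1e-8 * (1 + max(abs(S1))))
    stop("`S1` must be symmetric", call. = FALSE)
  structure(list(M = M, P = P, Ncov = Ncov, R = R, pi1 = pi1,
                 S1 = (S1 + t(S1)) / 2, d = d, N = N,
                 bin_width = bin_width),
            class = "lds_params")
}

#' @export
print.lds_params <- function(x, ...) {
  cat(sprintf("<lds_params> d = %d latent, N = %d channels, dt = %g ms, spectral radius %.4f\n",
              x$d, x$N, 1000 * x$bin_width, max(Mod(eigen(x$M, only.values = TRUE)$values))))
  invisible(x)
}

#' Eigenstructure summary of the dynamics matrix
#'
#' Reports, per eigenvalue of `M` (sorted by modulus, descending), the
#' modulus, the exponential-decay time constant \eqn{\tau = -\Delta t /
#' \log|\lambda|} in seconds (`Inf` when \eqn{|\lambda| = 1}), and the
#' rotational frequency \eqn{|\arg\lambda| / (2\pi\Delta t)} in Hz.
#'
#' @param params an [lds_params()].
#' @return a data.frame with columns `eigenvalue` (complex), `modulus`,
#'   `tau_s`, `freq_hz`.
#' @export
eigen_summary <- function(params) {
  stopifnot(inherits(params, "lds_params"))
  ev <- eigen(params$M, only.values = TRUE)$values
  ev <- ev[order(Mod(ev), decreasing = TRUE)]
  mod <- Mod(ev)
  dt <- params$bin_width
  tau <- ifelse(mod == 1, Inf, -dt / log(mod))
  tau[mod == 0] <- 0
  data.frame(eigenvalue = ev, modulus = mod, tau_s = tau,
             freq_hz = abs(Arg(ev)) / (2 * pi * dt))
}

#' Permute the columns of the dynamics matrix
#'
#' Control used to destroy the learned dynamical structure while preserving
#' the marginal scale of `M`: returns a copy of `params` with the columns of
#' `M` permuted by a uniformly random non-identity permutation. Everything
#' else is unchanged.
#'
#' @param params an [lds_params()] with `d >= 2`.
#' @param seed integer seed for the permutation draw.
#' @return the permuted [lds_params()], with the permutation stored in
#'   attribute `"perm"`.
#' @export
permute_dynamics <- function(params, seed) {
  stopifnot(inherits(params, "lds_params"))
  if (params$d < 2L)
    stop("`d` must be at least 2: no non-identity permutation exists",
         call. = FALSE)
  rng <- local_rng(seed)
  repeat {
    perm <- rng$sample(params$d)
    if (any(perm != seq_len(params$d))) break
  }
  out <- params
  out$M <- params$M[, perm, drop = FALSE]
  attr(out, "perm") <- perm
  out
}

#' One-step observation prediction
#'
#' Predicts the next spike-count observation from the current filtered
#' state: \eqn{\hat y_k = P M \hat s_{k-1}} (the mean of the one-step
#' predictive density under the observation process).
#'
#' @param params an [lds_params()].
#' @param shat_prev length-d filtered state at bin `k-1`.
#' @return length-N predicted observation.
#' @export
predict_next_observation <- function(params, shat_prev) {
  stopifnot(inherits(params, "lds_params"))
  drop(params$P %*% (params$M %*% as.numeric(shat_prev)))
}
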