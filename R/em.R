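# EM learning of the latent LDS, initialized with factor analysis.

# Small EM factor analyser on a second-moment matrix. Returns loadings
# (N x d) and uniquenesses (length N). Self-contained so that the
# initialization has no hidden dependencies and handles d up to N.
fa_em <- function(S, d, max_iter = 200L, tol = 1e-8) {
  N <- nrow(S)
  es <- eigen(S, symmetric = TRUE)
  ev <- pmax(es$values, 0)
  L <- es$vectors[, seq_len(d), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(d)]), d)
  psi <- pmax(diag(S) - rowSums(L^2), 1e-6 * mean(diag(S)))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E-step moments of z | y under the current factor model
    Sigma <- L %*% t(L) + diag(psi, N)
    cS <- chol(Sigma)
    iSL <- backsolve(cS, forwardsolve(t(cS), L))     # Sigma^{-1} L
    G <- diag(1, d) - t(L) %*% iSL + t(iSL) %*% S %*% iSL  # E[zz'] factor
    B <- S %*% iSL                                   # E[y z'] = S Sigma^{-1} L
    L <- B %*% solve(G)
    psi <- pmax(diag(S - L %*% t(B)), 1e-10)
    ld <- 2 * sum(log(diag(cS)))
    tr <- sum(diag(backsolve(cS, forwardsolve(t(cS), S))))
    ll <- -0.5 * (ld + tr)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(loadings = L, uniquenesses = psi)
}

#' Factor-analysis initialization for EM
#'
#' Fits a `d`-factor model to the spike counts; the loadings seed the
#' observation matrix `P` and the uniquenesses seed the diagonal of `R`.
#' The dynamics matrix `M` is seeded by least-squares regression of the
#' factor scores at bin `k` on bin `k-1`, and `Ncov` by the diagonalized
#' residual covariance of that regression. `pi1` is set to zero and `S1`
#' to the score covariance. Consistent with the zero-mean observation
#' model, second moments are taken about zero unless `offset = TRUE`
#' (per-channel means removed first).
#'
#' @param Y a [spike_counts()] or N x K matrix.
#' @param d latent dimension (`d <= N`).
#' @param seed unused placeholder kept for interface stability (the
#'   initialization is deterministic); reserved for future stochastic
#'   variants.
#' @param offset remove per-channel means before fitting.
#' @return an [lds_params()].
#' @export
fa_init <- function(Y, d, seed = NULL, offset = FALSE) {
  Ym <- as_count_matrix(Y)
  bw <- if (inherits(Y, "spike_counts")) Y$bin_width else 0.015
  N <- nrow(Ym); K <- ncol(Ym)
  if (d > N) stop("`d` must not exceed the number of channels", call. = FALSE)
  v <- apply(Ym, 1, stats::var)
  if (any(v == 0))
    stop(sprintf("degenerate (zero-variance) channels: %s",
                 paste(which(v == 0), collapse = ", ")), call. = FALSE)
  mu <- if (offset) rowMeans(Ym) else numeric(N)
  Yc <- Ym - mu
  S <- tcrossprod(Yc) / K
  fa <- fa_em(S, d)
  P <- fa$loadings
  psi <- pmax(fa$uniquenesses, 1e-10)
  # posterior-mean factor scores
  Sigma <- P %*% t(P) + diag(psi, N)
  cS <- chol(Sigma)
  Z <- t(backsolve(cS, forwardsolve(t(cS), P))) %*% Yc   # d x K
  Z0 <- Z[, -K, drop = FALSE]; Z1 <- Z[, -1, drop = FALSE]
  M <- t(solve(tcrossprod(Z0) + 1e-10 * diag(d), Z0 %*% t(Z1)))
  resid <- Z1 - M %*% Z0
  Ncov <- pmax(diag(tcrossprod(resid) / (K - 1)), 1e-10)
  S1 <- tcrossprod(Z) / K
  lds_params(M = M, P = P, Ncov = diag(Ncov, d), R = diag(psi, N),
             pi1 = numeric(d), S1 = S1, bin_width = bw)
}

#' Fit a latent LDS to spike counts by EM
#'
#' Alternates the exact (or steady-state-approximated) E-step, computed by
#' Kalman smoothing, with the closed-form M-step. `Ncov` and `R` are
#' projected to diagonal at each M-step, with variances floored at `1e-10`
#' to guard silent channels. `pi1` and `S1` are re-estimated each
#' iteration; after filter burn-in they have no practical effect on
#' decoding. Convergence is declared when the relative log-likelihood
#' improvement drops below `tol`.
#'
#' @param Y a [spike_counts()] or N x K matrix (`K >> d` recommended).
#' @param d latent dimension (default 20).
#' @param init `"factor_analysis"`, `"random"`, or an [lds_params()] to
#'   warm-start from.
#' @param max_iter iteration cap (default 200).
#' @param tol relative log-likelihood convergence tolerance.
#' @param estep `"steady"` freezes the filter gain once the prior state
#'   covariance converges (Frobenius `1e-8`), the approximation used for
#'   long sessions; `"exact"` guarantees monotone log-likelihood.
#' @param seed seed for `init = "random"`.
#' @param offset estimate and remove per-channel means before EM
#'   (escape hatch; default `FALSE`, the zero-mean model as written).
#' @return list with `params` (an [lds_params()]; when `offset = TRUE` it
#'   carries the channel means in attribute `"offset"`) and `trace`
#'   (class `em_trace`: per-iteration `logliks`, `n_iter`, `converged`,
#'   `init_method`).
#' @export
em_fit <- function(Y, d = 20L, init = "factor_analysis", max_iter = 200L,
                   tol = 1e-6, estep = c("steady", "exact"), seed = NULL,
                   offset = FALSE) {
  estep <- match.arg(estep)
  Ym <- as_count_matrix(Y)
  bw <- if (inherits(Y, "spike_counts")) Y$bin_width else 0.015
  N <- nrow(Ym); K <- ncol(Ym)
  if (d > N) stop("`d` must not exceed the number of channels", call. = FALSE)
  if (K < 2L) stop("need at least two bins", call. = FALSE)
  mu <- if (offset) rowMeans(Ym) else numeric(N)
  Yfit <- Ym - mu

  if (inherits(init, "lds_params")) {
    params <- init
    init_method <- "warm_start"
    if (params$N != N || params$d != d)
      stop("warm-start parameters do not match data dimensions", call. = FALSE)
  } else if (identical(init, "factor_analysis")) {
    params <- fa_init(spike_counts(Yfit, bin_width = bw), d)
    init_method <- "factor_analysis"
  } else if (identical(init, "random")) {
    params <- with_seed(seed, {
      M0 <- 0.5 * diag(d) + matrix(stats::rnorm(d * d, sd = 0.1), d)
      P0 <- matrix(stats::rnorm(N * d), N, d)
      lds_params(M0, P0, diag(0.1, d), diag(stats::var(as.numeric(Yfit)), N),
                 numeric(d), diag(1, d), bin_width = bw)
    })
    init_method <- "random"
  } else stop("unknown `init`", call. = FALSE)

  steady <- estep == "steady"
  logliks <- numeric(0)
  converged <- FALSE
  floor_v <- 1e-10
  for (it in seq_len(max_iter)) {
    st <- em_estep_cpp(params$M, params$P, params$Ncov, params$R,
                       params$pi1, params$S1, Yfit,
                       steady = steady, cov_tol = 1e-8)
    ll <- st$loglik
    if (length(logliks)) {
      rel <- (ll - logliks[length(logliks)]) /
        (abs(logliks[length(logliks)]) + .Machine$double.eps)
      dec_tol <- if (estep == "exact") 1e-8 else 1e-4
      if (rel < -dec_tol)
        stop(sprintf("log-likelihood decreased at iteration %d (rel %g)",
                     it, rel), call. = FALSE)
      logliks <- c(logliks, ll)
      if (abs(rel) < tol) { converged <- TRUE; break }
    } else logliks <- ll
    # M-step (sums from the smoothed posterior)
    M_new <- t(solve(st$S_head, t(st$S_lag)))
    Ncov_new <- (st$S_tail - M_new %*% t(st$S_lag)) / (K - 1)
    Ncov_new <- pmax(diag(Ncov_new), floor_v)
    P_new <- t(solve(st$S_all, t(st$Sys)))
    R_new <- (as.numeric(st$Syy_diag) - rowSums(P_new * st$Sys)) / K
    R_new <- pmax(R_new, floor_v)
    params <- lds_params(M = M_new, P = P_new,
                         Ncov = diag(Ncov_new, d), R = diag(R_new, N),
                         pi1 = st$Ex1, S1 = st$V1, bin_width = bw)
  }
  if (offset) attr(params, "offset") <- mu
  trace <- structure(list(logliks = logliks, n_iter = length(logliks),
                          converged = converged, init_method = init_method),
                     class = "em_trace")
  list(params = params, trace = trace)
}

#' @export
print.em_trace <- function(x, ...) {
  cat(sprintf("<em_trace> %d iterations (%s init), %s, final loglik %.3f\n",
              x$n_iter, x$init_method,
              if (x$converged) "converged" else "not converged",
              x$logliks[length(x$logliks)]))
  invisible(x)
}
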