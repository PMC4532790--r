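# Decoder models: NDF, OLE, WF, KKF, PC-smooth. All share the blended
# position output rule and a strictly causal `decode()` path.

new_decoder <- function(type, fields) {
  structure(c(list(decoder_type = type), fields),
            class = c(paste0(type, "_model"), "decoder_model"))
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf("<decoder_model:%s>\n", x$decoder_type))
  invisible(x)
}

#' Fit a neural dynamical filter (NDF)
#'
#' Learns a latent LDS from the training spike counts by EM, runs the
#' steady-state Kalman filter over the training data to obtain the
#' filtered neural-state sequence, and fits the least-squares readout from
#' filtered states (plus bias) to the paired kinematics.
#'
#' @param Y training [spike_counts()].
#' @param X paired [kin_series()].
#' @param d latent dimension (default 20).
#' @param em_opts list of arguments forwarded to [em_fit()] (e.g.
#'   `max_iter`, `init`, `estep`).
#' @param lds optionally, an already-fitted [lds_params()]; skips EM (used
#'   by the permuted-dynamics control).
#' @return an `ndf_model` decoder.
#' @export
fit_ndf <- function(Y, X, d = 20L, em_opts = list(), lds = NULL) {
  if (is.null(lds)) {
    fit <- do.call(em_fit, c(list(Y = Y, d = d), em_opts))
    lds <- fit$params
    trace <- fit$trace
  } else trace <- NULL
  fr <- kalman_filter(lds, Y, mode = "steady_state")
  ro <- fit_readout(fr$shat, X)
  new_decoder("ndf", list(lds = lds, L = ro$L, bias = ro$bias,
                          steady_gain = fr$steady_gain, em_trace = trace))
}

#' Fit an optimal linear estimator (OLE)
#'
#' Least-squares readout from causally Gaussian-smoothed spike counts
#' (plus bias) to kinematics. `kernel_sd = 0` regresses on raw counts.
#'
#' @inheritParams fit_ndf
#' @param kernel_sd causal Gaussian kernel s.d. in seconds.
#' @return an `ole_model` decoder.
#' @export
fit_ole <- function(Y, X, kernel_sd = 0.100) {
  Ys <- causal_gaussian_smooth(Y, kernel_sd)
  ro <- fit_readout(Ys, X)
  new_decoder("ole", list(L = ro$L, bias = ro$bias, kernel_sd = kernel_sd))
}

# History-stacked design matrix for the Wiener filter: rows are
# [y_k; y_{k-1}; ...; y_{k-p+1}], zero-padded before bin p.
wf_design <- function(Ym, p) {
  N <- nrow(Ym); K <- ncol(Ym)
  Z <- matrix(0, N * p, K)
  for (j in 0:(p - 1)) {
    cols <- (j + 1):K
    Z[j * N + seq_len(N), cols] <- Ym[, cols - j, drop = FALSE]
  }
  Z
}

#' Fit a Wiener filter (WF)
#'
#' Ridge-regularized least squares from a stacked history of `p` bins of
#' spike counts (plus bias) to kinematics. The bias row is not penalized.
#' The first `p - 1` bins use zero-padded history so the decoder is
#' defined from bin 1.
#'
#' @inheritParams fit_ndf
#' @param p history length in bins (`>= 1`; 250 ms of history at 15-ms
#'   bins is `p = 17`).
#' @param lam ridge weight (`>= 0`).
#' @return a `wf_model` decoder.
#' @export
fit_wf <- function(Y, X, p = 17L, lam = 0) {
  if (p < 1L) stop("`p` must be >= 1", call. = FALSE)
  Ym <- as_count_matrix(Y)
  if (lam == 0 && ncol(Ym) <= p * nrow(Ym) + 1L)
    stop("underdetermined history regression; use lam > 0", call. = FALSE)
  Z <- wf_design(Ym, p)
  ro <- fit_readout(Z, X, lam = lam)
  N <- nrow(Ym)
  blocks <- lapply(0:(p - 1), function(j)
    ro$L[, j * N + seq_len(N), drop = FALSE])
  new_decoder("wf", list(L_blocks = blocks, bias = ro$bias, p = as.integer(p),
                         lam = lam))
}

#' Fit a kinematic-state Kalman filter (KKF)
#'
#' Models the 4D kinematic state `x_k = [pos; vel]` as the latent state:
#' `x_k = A x_{k-1} + w_k`, `y_k = C x_k + q_k`. `A` and `C` are learned by
#' least squares on the training pairs; `W` and `Q` are the sample
#' covariances of the respective residuals (1/K convention, K = number of
#' residual columns).
#'
#' @inheritParams fit_ndf
#' @param velocity_only model and decode only the velocity rows (position
#'   follows from integration); provided for the comparison noted in the
#'   source analyses that a pure velocity filter underperforms.
#' @return a `kkf_model` decoder.
#' @export
fit_kkf <- function(Y, X, velocity_only = FALSE) {
  Ym <- as_count_matrix(Y)
  Xm <- kin_matrix(X)
  if (velocity_only) Xm <- Xm[3:4, , drop = FALSE]
  K <- ncol(Xm)
  if (any(apply(Xm, 1, stats::sd) == 0))
    stop("degenerate (constant) kinematics", call. = FALSE)
  X0 <- Xm[, -K, drop = FALSE]; X1 <- Xm[, -1, drop = FALSE]
  A <- t(solve(tcrossprod(X0), X0 %*% t(X1)))
  C <- t(solve(tcrossprod(Xm), Xm %*% t(Ym)))
  rw <- X1 - A %*% X0
  W <- tcrossprod(rw) / ncol(rw)
  rq <- Ym - C %*% Xm
  Q <- tcrossprod(rq) / ncol(rq)
  new_decoder("kkf", list(A = A, C = C, W = (W + t(W)) / 2,
                          Q = (Q + t(Q)) / 2,
                          velocity_only = velocity_only))
}

#' Fit the PC-smooth control decoder
#'
#' PCA on the training counts, keeping the first 20 components; each
#' component is causally smoothed with a 100-ms Gaussian kernel, and the
#' readout is least squares from the smoothed components (plus bias) to
#' kinematics.
#'
#' @inheritParams fit_ndf
#' @param n_components number of principal components (default 20).
#' @param kernel_sd smoothing kernel s.d. in seconds (default 0.100).
#' @return a `pcsmooth_model` decoder.
#' @export
fit_pcsmooth <- function(Y, X, n_components = 20L, kernel_sd = 0.100) {
  Ym <- as_count_matrix(Y)
  bw <- if (inherits(Y, "spike_counts")) Y$bin_width else 0.015
  if (nrow(Ym) < n_components)
    stop("fewer channels than requested components", call. = FALSE)
  mu <- rowMeans(Ym)
  sv <- svd(Ym - mu, nu = n_components, nv = 0)
  G <- sv$u[, seq_len(n_components), drop = FALSE]   # N x 20, orthonormal
  comp <- t(G) %*% (Ym - mu)
  comp_s <- causal_gaussian_smooth(comp, kernel_sd, bin_width = bw)
  ro <- fit_readout(comp_s, X)
  new_decoder("pcsmooth", list(components = G, center = mu, L = ro$L,
                               bias = ro$bias, kernel_sd = kernel_sd,
                               n_components = as.integer(n_components)))
}

#' Decode cursor kinematics from spike counts
#'
#' Runs a fitted decoder causally over a session of spike counts: per bin,
#' features are computed from bins `<= k` only (steady-state Kalman-filtered
#' neural state for the NDF; causally smoothed counts for the OLE;
#' zero-padded history stack for the WF; Kalman-filtered kinematic state
#' for the KKF; smoothed principal components for PC-smooth), the readout
#' yields decoded position and velocity, and the displayed position is
#' produced by [blend_position()].
#'
#' @param model a fitted decoder.
#' @param Y a [spike_counts()] with the training channel count.
#' @param init_pos initial cursor position (cm), default workspace center.
#' @param alpha blending weight (default 0.975).
#' @param ... unused.
#' @return a [kin_series()] with blended positions and decoded velocities;
#'   the pre-blend decoded positions are attached as attribute `"p_hat"`.
#' @export
decode <- function(model, Y, init_pos = c(0, 0), alpha = 0.975, ...) {
  UseMethod("decode")
}

decode_finish <- function(p_hat, v_hat, init_pos, alpha, dt) {
  pos <- blend_path(p_hat, v_hat, init_pos = init_pos, alpha = alpha, dt = dt)
  out <- kin_series(pos, v_hat, bin_width = dt)
  attr(out, "p_hat") <- p_hat
  out
}

check_channels <- function(model_n, Y) {
  if (n_channels(Y) != model_n)
    stop(sprintf("channel mismatch: model trained on %d channels, data has %d",
                 model_n, n_channels(Y)), call. = FALSE)
}

#' @export
decode.ndf_model <- function(model, Y, init_pos = c(0, 0), alpha = 0.975,
                             ...) {
  check_channels(model$lds$N, Y)
  fr <- kalman_filter(model$lds, Y, mode = "steady_state")
  XY <- model$L %*% fr$shat + model$bias
  decode_finish(XY[1:2, , drop = FALSE], XY[3:4, , drop = FALSE],
                init_pos, alpha, model$lds$bin_width)
}

#' @export
decode.ole_model <- function(model, Y, init_pos = c(0, 0), alpha = 0.975,
                             ...) {
  check_channels(ncol(model$L), Y)
  dt <- if (inherits(Y, "spike_counts")) Y$bin_width else 0.015
  Ys <- causal_gaussian_smooth(Y, model$kernel_sd)
  XY <- model$L %*% Ys + model$bias
  decode_finish(XY[1:2, , drop = FALSE], XY[3:4, , drop = FALSE],
                init_pos, alpha, dt)
}

#' @export
decode.wf_model <- function(model, Y, init_pos = c(0, 0), alpha = 0.975,
                            ...) {
  check_channels(ncol(model$L_blocks[[1]]), Y)
  dt <- if (inherits(Y, "spike_counts")) Y$bin_width else 0.015
  Ym <- as_count_matrix(Y)
  Z <- wf_design(Ym, model$p)
  L <- do.call(cbind, model$L_blocks)
  XY <- L %*% Z + model$bias
  decode_finish(XY[1:2, , drop = FALSE], XY[3:4, , drop = FALSE],
                init_pos, alpha, dt)
}

#' @export
decode.kkf_model <- function(model, Y, init_pos = c(0, 0), alpha = 0.975,
                             ...) {
  check_channels(nrow(model$C), Y)
  dt <- if (inherits(Y, "spike_counts")) Y$bin_width else 0.015
  dim_x <- nrow(model$A)
  x0 <- if (model$velocity_only) numeric(2) else c(init_pos, 0, 0)
  kparams <- lds_params(M = model$A, P = model$C, Ncov = model$W,
                        R = model$Q, pi1 = x0, S1 = model$W,
                        bin_width = dt, check_diagonal = FALSE)
  fr <- kalman_filter(kparams, Y, mode = "exact")
  if (model$velocity_only) {
    v_hat <- fr$shat
    p_hat <- matrix(init_pos, 2, ncol(v_hat)) # unused under full blending
    out <- decode_finish(p_hat, v_hat, init_pos, alpha = 1, dt = dt)
  } else {
    out <- decode_finish(fr$shat[1:2, , drop = FALSE],
                         fr$shat[3:4, , drop = FALSE], init_pos, alpha, dt)
  }
  attr(out, "state") <- fr$shat
  out
}

#' @export
decode.pcsmooth_model <- function(model, Y, init_pos = c(0, 0),
                                  alpha = 0.975, ...) {
  check_channels(nrow(model$components), Y)
  dt <- if (inherits(Y, "spike_counts")) Y$bin_width else 0.015
  Ym <- as_count_matrix(Y) - model$center
  comp <- t(model$components) %*% Ym
  comp_s <- causal_gaussian_smooth(comp, model$kernel_sd, bin_width = dt)
  XY <- model$L %*% comp_s + model$bias
  decode_finish(XY[1:2, , drop = FALSE], XY[3:4, , drop = FALSE],
                init_pos, alpha, dt)
}
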