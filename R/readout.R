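#' Least-squares kinematic readout with bias
#'
#' Solves \eqn{\min_L \|X - L [F; 1]\|^2} for the linear map from feature
#' rows (filtered states, smoothed counts, ...) to the 4 kinematic rows
#' `[pos_x, pos_y, vel_x, vel_y]`, with a bias obtained by appending a row
#' of ones to the features.
#'
#' @param F features x K matrix (e.g. filtered states or smoothed counts).
#' @param X 4 x K kinematics matrix, or a [kin_series()].
#' @param lam optional ridge weight applied to the non-bias coefficients.
#' @return list with `L` (4 x features) and `bias` (length 4).
#' @export
fit_readout <- function(F, X, lam = 0) {
  F <- as.matrix(F)
  Xm <- kin_matrix(X)
  K <- ncol(F)
  if (ncol(Xm) != K)
    stop("features and kinematics must share the number of bins", call. = FALSE)
  if (K <= nrow(F) + 1L && lam == 0)
    stop("need more bins than features (+1 for the bias); consider ridge",
         call. = FALSE)
  # all-zero feature rows carry no information: their coefficients are 0
  # (the minimum-norm choice) and they are dropped from the solve
  live <- rowSums(abs(F)) > 0
  Fl <- F[live, , drop = FALSE]
  Fb <- rbind(Fl, 1)
  G <- tcrossprod(Fb)
  if (lam > 0) {
    pen <- c(rep(lam, nrow(Fl)), 0)   # bias row unpenalized
    G <- G + diag(pen, nrow(Fb))
  }
  sol <- tryCatch(solve(G, Fb %*% t(Xm)),
                  error = function(e)
                    stop("rank-deficient feature matrix; try lam > 0",
                         call. = FALSE))
  Lb <- t(sol)
  L <- matrix(0, nrow(Xm), nrow(F))
  L[, live] <- Lb[, seq_len(nrow(Fl)), drop = FALSE]
  list(L = L, bias = Lb[, nrow(Fb)])
}

#' Position blending
#'
#' The decoded position shown to the user mixes the directly decoded
#' position with the velocity-integrated position:
#' \deqn{p_k = (1-\alpha)\,\hat p_k + \alpha\,(p_{k-1} + \Delta t\,\hat v_k)}
#' with \eqn{\alpha = 0.975} by default, i.e. 2.5% weight on the decoded
#' position and 97.5% on the integrated velocity.
#'
#' @param p_hat decoded position (2-vector, cm).
#' @param v_hat decoded velocity (2-vector, cm/s).
#' @param p_prev previous blended position (2-vector, cm).
#' @param alpha blending weight in `[0, 1]`.
#' @param dt bin width in seconds.
#' @return blended position (2-vector, cm).
#' @export
blend_position <- function(p_hat, v_hat, p_prev, alpha = 0.975, dt = 0.015) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]", call. = FALSE)
  (1 - alpha) * p_hat + alpha * (p_prev + dt * v_hat)
}

# Vectorized blending over a session: takes 2 x K decoded positions and
# velocities, returns the 2 x K blended position path.
blend_path <- function(p_hat, v_hat, init_pos = c(0, 0), alpha = 0.975,
                       dt = 0.015) {
  K <- ncol(p_hat)
  out <- matrix(0, 2, K)
  prev <- init_pos
  for (k in seq_len(K)) {
    prev <- blend_position(p_hat[, k], v_hat[, k], prev, alpha, dt)
    out[, k] <- prev
  }
  out
}
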