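# Synthetic ground-truth systems and sessions: a known latent LDS with a
# linear kinematic readout, driven through center-out-and-back trials, so
# that every analysis stage can be exercised without recorded data.

# Discrete Lyapunov fixed point Sigma = M Sigma M' + Q by iteration.
lyapunov_cov <- function(M, Q, tol = 1e-12, max_iter = 100000L) {
  S <- Q
  for (i in seq_len(max_iter)) {
    S_new <- M %*% S %*% t(M) + Q
    if (max(abs(S_new - S)) < tol) return((S_new + t(S_new)) / 2)
    S <- S_new
  }
  stop("Lyapunov iteration did not converge (unstable dynamics?)",
       call. = FALSE)
}

#' Construct a ground-truth latent LDS with task geometry
#'
#' Builds a stable, full-rank, non-normal dynamics matrix from a
#' block-diagonal design conjugated by a random well-conditioned
#' similarity. The blocks are: a 2D slow "posture" subspace occupied while
#' holding a target (real eigenvalues `hold_contraction`, near 1, so a
#' state parked there barely moves), a 2D fast-decaying movement subspace
#' carrying velocity (real eigenvalues `vel_decay`), and damped rotations
#' for the remaining dimensions with moduli drawn from `decay_range` and
#' rotation frequencies from `rot_freq_hz`. The kinematic readout maps the
#' posture subspace to position (cm) and the movement subspace to velocity
#' (cm/s).
#'
#' @param d latent dimension (default 20; must be `>= 4`).
#' @param N number of channels (default 96; `N >= d`).
#' @param seed integer seed.
#' @param decay_range range of rotational-mode moduli.
#' @param rot_freq_hz range of rotational frequencies (Hz).
#' @param hold_contraction modulus of the slow posture modes.
#' @param vel_decay modulus of the velocity modes.
#' @param proc_noise length-3 process-noise s.d. for (posture, velocity,
#'   rotational) latent dimensions.
#' @param obs_gain scale of the random observation matrix.
#' @param obs_noise per-channel observation-noise s.d. (high relative to
#'   the per-channel signal: single 15-ms bins are noisy).
#' @param bin_width bin width in seconds.
#' @return an object of class `ground_truth`: `lds` (an [lds_params()]
#'   with `S1` the stationary fluctuation covariance), `kin_readout`
#'   (4 x d), `geometry` (target radius 12 cm, 8 targets, 0.5-s holds,
#'   ~60 bins per acquisition), and internal block/coordinate data.
#' @export
make_ground_truth_lds <- function(d = 20L, N = 96L, seed = 1L,
                                  decay_range = c(0.95, 0.985),
                                  rot_freq_hz = c(0.5, 2.5),
                                  hold_contraction = 0.998,
                                  vel_decay = 0.92,
                                  proc_noise = c(0.01, 0.03, 0.06),
                                  obs_gain = 1.0, obs_noise = 1.0,
                                  bin_width = 0.015) {
  if (d < 4L) stop("`d` must be at least 4 (posture + movement subspaces)",
                   call. = FALSE)
  if (N < d) stop("`N` must be at least `d`", call. = FALSE)
  with_seed(seed, {
    B <- matrix(0, d, d)
    B[1, 1] <- B[2, 2] <- hold_contraction
    B[3, 3] <- B[4, 4] <- vel_decay
    extra <- d - 4L
    n_pairs <- extra %/% 2L
    idx <- 5L
    for (j in seq_len(n_pairs)) {
      mod <- stats::runif(1, decay_range[1], decay_range[2])
      fr <- stats::runif(1, rot_freq_hz[1], rot_freq_hz[2])
      th <- 2 * pi * fr * bin_width
      R2 <- mod * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      B[idx:(idx + 1), idx:(idx + 1)] <- R2
      idx <- idx + 2L
    }
    if (extra %% 2L == 1L)
      B[d, d] <- stats::runif(1, decay_range[1], decay_range[2])
    # well-conditioned random similarity. Block-structured: the posture
    # pair mixes only within itself so the slow subspace keeps its small
    # process noise after the diagonal projection of Ncov below; the
    # remaining dimensions mix freely (non-normal, full rank).
    rnd_sim <- function(m) {
      Qa <- qr.Q(qr(matrix(stats::rnorm(m * m), m)))
      Qb <- qr.Q(qr(matrix(stats::rnorm(m * m), m)))
      Qa %*% diag(stats::runif(m, 0.8, 1.25), m) %*% Qb
    }
    Tm <- matrix(0, d, d)
    Tm[1:2, 1:2] <- rnd_sim(2L)
    Tm[3:d, 3:d] <- rnd_sim(d - 2L)
    Tinv <- solve(Tm)
    M <- Tm %*% B %*% Tinv
    nvec <- c(rep(proc_noise[1]^2, 2), rep(proc_noise[2]^2, 2),
              rep(proc_noise[3]^2, max(extra, 0)))
    # process noise specified in block coordinates, mapped through T, then
    # diagonalized (the model assumes diagonal Ncov)
    Ncov_full <- Tm %*% diag(nvec, d) %*% t(Tm)
    Ncov <- diag(pmax(diag(Ncov_full), 1e-10), d)
    P <- obs_gain * matrix(stats::rnorm(N * d), N, d) / sqrt(d)
    R <- diag(rep(obs_noise^2, N), N)
    S1 <- lyapunov_cov(M, Ncov)
    lds <- lds_params(M, P, Ncov, R, pi1 = numeric(d), S1 = S1,
                      bin_width = bin_width)
    pos_scale <- 6    # cm per latent unit in the posture subspace
    vel_scale <- 30   # cm/s per latent unit in the movement subspace
    kin_readout <- rbind(pos_scale * Tinv[1:2, , drop = FALSE],
                         vel_scale * Tinv[3:4, , drop = FALSE])
    structure(list(lds = lds, kin_readout = kin_readout,
                   Tm = Tm, Tinv = Tinv,
                   scales = c(pos = pos_scale, vel = vel_scale),
                   geometry = list(n_targets = 8L, radius_cm = 12,
                                   hold_s = 0.5,
                                   move_bins = 26L, hold_bins = 34L),
                   seed = as.integer(seed)),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> d = %d, N = %d, spectral radius %.4f\n",
              x$lds$d, x$lds$N,
              max(Mod(eigen(x$lds$M, only.values = TRUE)$values))))
  invisible(x)
}

#' Ancestral sampling from a latent LDS
#'
#' Draws `s_1 ~ N(pi1, S1)`, iterates the dynamics process, and emits
#' observations. Gaussian emission follows the observation process
#' exactly; Poisson emission (robustness testing only) uses rates
#' `softplus(P s_k + poisson_offset)` counts per bin.
#'
#' @param params an [lds_params()].
#' @param K number of bins.
#' @param seed integer seed.
#' @param emission `"gaussian"` or `"poisson"`.
#' @param poisson_offset additive pre-softplus offset setting the baseline
#'   rate (default gives ~0.5 counts per 15-ms bin).
#' @return list with `latents` (d x K) and `counts` ([spike_counts()]).
#' @export
simulate_lds <- function(params, K, seed = 1L,
                         emission = c("gaussian", "poisson"),
                         poisson_offset = 0.25) {
  emission <- match.arg(emission)
  stopifnot(inherits(params, "lds_params"))
  with_seed(seed, {
    d <- params$d; N <- params$N
    S <- matrix(0, d, K)
    cS1 <- chol_psd(params$S1)
    cN <- chol_psd(params$Ncov)
    S[, 1] <- params$pi1 + cS1 %*% stats::rnorm(d)
    for (k in seq_len(K - 1))
      S[, k + 1] <- params$M %*% S[, k] + cN %*% stats::rnorm(d)
    eta <- params$P %*% S
    if (emission == "gaussian") {
      cR <- chol_psd(params$R)
      Y <- eta + cR %*% matrix(stats::rnorm(N * K), N, K)
    } else {
      rate <- log1p(exp(pmin(eta + poisson_offset, 30)))
      Y <- matrix(stats::rpois(N * K, lambda = rate), N, K)
    }
    list(latents = S,
         counts = spike_counts(Y, bin_width = params$bin_width,
                               integer_counts = (emission == "poisson")))
  })
}

# Lower-triangular PSD square root (tolerates zero variances).
chol_psd <- function(A) {
  A <- as.matrix(A)
  if (all(A == 0)) return(A)
  es <- eigen((A + t(A)) / 2, symmetric = TRUE)
  es$vectors %*% diag(sqrt(pmax(es$values, 0)), nrow(A)) %*% t(es$vectors)
}

# Minimum-jerk position/speed profile over nb bins covering distance D.
min_jerk <- function(nb, D) {
  tt <- seq_len(nb) / nb
  pos <- D * (10 * tt^3 - 15 * tt^4 + 6 * tt^5)
  vel <- D * (30 * tt^2 - 60 * tt^3 + 30 * tt^4) / (nb)  # per-bin units
  list(pos = pos, vel_per_bin = vel)
}

#' Simulate a center-out-and-back reaching session
#'
#' Each trial is one target acquisition (~60 bins: a ~0.4-s minimum-jerk
#' movement followed by a 0.5-s hold), alternating center-to-target
#' ("out", condition = target index 1..8) and target-to-center ("back")
#' legs, with 8 targets on a 12-cm circle. A designed latent path `s*`
#' traces the task: position in the slow posture subspace, velocity in the
#' movement subspace, plus condition-dependent excitation of the
#' rotational modes during movement. The realized latent state is steered
#' along `s*` by a deterministic input while fluctuating around it with
#' the ground-truth autonomous dynamics (`e_k = M e_{k-1} + n_k`); spike
#' counts follow the observation process and kinematics are the linear
#' readout of the state plus small measurement noise.
#'
#' Epoch labels: "reach" for center-out movement bins, "hold" for all hold
#' bins, "other" for back-to-center movement bins (the hold/reach analyses
#' use center-out movements only).
#'
#' @param gt a [make_ground_truth_lds()] object.
#' @param n_trials number of target acquisitions (default 500, ~30,000
#'   bins).
#' @param seed integer seed.
#' @param rot_drive amplitude of condition-dependent rotational-mode
#'   excitation during movement.
#' @param kin_noise length-2 measurement noise s.d. for (position cm,
#'   velocity cm/s).
#' @return list with `Y` ([spike_counts()]), `X` (labelled
#'   [kin_series()]), `mask` (the standard hold/reach [epoch_mask()]), and
#'   `truth` (list: `latents`, `s_star`).
#' @export
simulate_reach_session <- function(gt, n_trials = 500L, seed = 1L,
                                   rot_drive = 0.8,
                                   kin_noise = c(0.1, 0.5)) {
  stopifnot(inherits(gt, "ground_truth"))
  lds <- gt$lds
  d <- lds$d
  geo <- gt$geometry
  nb_move <- geo$move_bins; nb_hold <- geo$hold_bins
  nb_leg <- nb_move + nb_hold
  K <- n_trials * nb_leg
  with_seed(seed, {
    angles <- 2 * pi * (seq_len(geo$n_targets) - 1) / geo$n_targets
    targets <- geo$radius_cm * rbind(cos(angles), sin(angles))
    n_rot <- d - 4L
    rot_dirs <- if (n_rot > 0)
      matrix(stats::rnorm(n_rot * geo$n_targets), n_rot) else NULL
    if (!is.null(rot_dirs))
      rot_dirs <- sweep(rot_dirs, 2, sqrt(colSums(rot_dirs^2)), "/")

    z_star <- matrix(0, d, K)       # designed path, block coordinates
    epoch <- character(K); trial <- integer(K); condition <- character(K)
    cur_target <- 0L                # 0 = at center
    mj <- min_jerk(nb_move, 1)      # unit profile, scaled per leg
    for (tr in seq_len(n_trials)) {
      out_leg <- cur_target == 0L
      if (out_leg) {
        tgt <- sample(geo$n_targets, 1L)
        from <- c(0, 0); to <- targets[, tgt]
        cond <- sprintf("out%d", tgt); lab <- "reach"
      } else {
        tgt <- 0L
        from <- targets[, cur_target]; to <- c(0, 0)
        cond <- "back"; lab <- "other"
      }
      rot_idx <- if (out_leg) tgt else cur_target
      cols <- (tr - 1L) * nb_leg + seq_len(nb_leg)
      mv <- cols[seq_len(nb_move)]
      hd <- cols[nb_move + seq_len(nb_hold)]
      delta <- to - from
      pos <- from + outer(delta, mj$pos)               # 2 x nb_move
      vel <- outer(delta, mj$vel_per_bin) / lds$bin_width
      z_star[1:2, mv] <- pos / gt$scales["pos"]
      z_star[3:4, mv] <- vel / gt$scales["vel"]
      z_star[1:2, hd] <- to / gt$scales["pos"]
      # velocity and rotational modes silent during hold
      if (n_rot > 0) {
        bell <- mj$vel_per_bin / max(mj$vel_per_bin)
        z_star[4L + seq_len(n_rot), mv] <-
          rot_drive * rot_dirs[, rot_idx] %o% bell
      }
      epoch[mv] <- lab; epoch[hd] <- "hold"
      trial[cols] <- tr; condition[cols] <- cond
      cur_target <- if (out_leg) tgt else 0L
    }
    s_star <- gt$Tm %*% z_star
    # steer: s_k = M s_{k-1} + u_k + n_k with u_k = s*_k - M s*_{k-1}
    # so e = s - s* follows the autonomous dynamics exactly
    cN <- chol_psd(lds$Ncov)
    E <- matrix(0, d, K)
    E[, 1] <- chol_psd(lds$S1) %*% stats::rnorm(d)
    noise <- cN %*% matrix(stats::rnorm(d * (K - 1)), d)
    for (k in seq_len(K - 1))
      E[, k + 1] <- lds$M %*% E[, k] + noise[, k]
    S <- s_star + E
    Y <- lds$P %*% S +
      chol_psd(lds$R) %*% matrix(stats::rnorm(lds$N * K), lds$N, K)
    XY <- gt$kin_readout %*% S
    XY[1:2, ] <- XY[1:2, ] + kin_noise[1] * matrix(stats::rnorm(2 * K), 2)
    XY[3:4, ] <- XY[3:4, ] + kin_noise[2] * matrix(stats::rnorm(2 * K), 2)
    X <- kin_series(XY[1:2, , drop = FALSE], XY[3:4, , drop = FALSE],
                    bin_width = lds$bin_width, epoch = epoch,
                    trial = trial, condition = condition)
    list(Y = spike_counts(Y, bin_width = lds$bin_width),
         X = X,
         mask = epoch_mask_from_labels(X),
         truth = list(latents = S, s_star = s_star))
  })
}

#' Simulate a grid-task selection stream
#'
#' Generates a [selection_log()] with Bernoulli(`success_rate`) outcomes.
#' Acquire times are `dwell` plus an exponential with mean
#' `mean_acquire_s - dwell`, truncated below the `timeout`; a fraction
#' `timeout_rate` of events instead time out (consuming `timeout`
#' seconds). A `lockout` gap follows every selection.
#'
#' @param success_rate probability a selection is correct.
#' @param n_selections number of events.
#' @param mean_acquire_s mean acquire time in seconds.
#' @param dwell dwell requirement (seconds, default 0.450).
#' @param lockout post-selection lockout (seconds, default 0.200).
#' @param timeout selection timeout (seconds, default 5).
#' @param timeout_rate probability an event times out.
#' @param seed integer seed.
#' @return a [selection_log()].
#' @export
simulate_grid_session <- function(success_rate, n_selections = 100L,
                                  mean_acquire_s = 1.5, dwell = 0.450,
                                  lockout = 0.200, timeout = 5.0,
                                  timeout_rate = 0, seed = 1L) {
  if (success_rate < 0 || success_rate > 1)
    stop("`success_rate` must be in [0, 1]", call. = FALSE)
  with_seed(seed, {
    is_to <- stats::runif(n_selections) < timeout_rate
    acq <- dwell + stats::rexp(n_selections,
                               rate = 1 / max(mean_acquire_s - dwell, 1e-6))
    acq <- pmin(acq, timeout - 1e-3)
    acq[is_to] <- timeout
    outcome <- ifelse(is_to, "timeout",
                      ifelse(stats::runif(n_selections) < success_rate,
                             "correct", "incorrect"))
    gaps <- acq + c(0, rep(lockout, n_selections - 1))
    selection_log(cumsum(gaps), outcome, n_targets = 36L)
  })
}

#' Write a small fixture session to disk
#'
#' Single entry point used by the test suite and CLI smoke tests: builds a
#' desk-scale ground truth, simulates `n_trials` acquisitions, and writes
#' the session in the package's delimited-text format.
#'
#' @param prefix path prefix for [write_session()].
#' @param n_trials number of acquisitions (default 50).
#' @param seed integer seed.
#' @param d,N ground-truth latent dimension and channel count.
#' @return (invisibly) the simulated session list.
#' @export
make_fixture_session <- function(prefix, n_trials = 50L, seed = 1L,
                                 d = 8L, N = 24L) {
  gt <- make_ground_truth_lds(d = d, N = N, seed = seed)
  ses <- simulate_reach_session(gt, n_trials = n_trials, seed = seed + 1L)
  write_session(prefix, ses$Y, ses$X)
  invisible(ses)
}
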