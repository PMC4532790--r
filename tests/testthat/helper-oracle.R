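# Brute-force joint-Gaussian oracle for small LDS instances, independent of
# the package's recursive filter/smoother: assemble the explicit joint
# covariance of (s_1..s_K, y_1..y_K) and condition by Schur complement.

oracle_joint <- function(params, K) {
  d <- params$d; N <- params$N
  M <- params$M; P <- params$P
  mu_s <- matrix(0, d, K)
  mu_s[, 1] <- params$pi1
  V <- array(0, c(d, d, K))
  V[, , 1] <- params$S1
  if (K > 1) for (k in 2:K) {
    mu_s[, k] <- M %*% mu_s[, k - 1]
    V[, , k] <- M %*% V[, , k - 1] %*% t(M) + params$Ncov
  }
  Css <- matrix(0, d * K, d * K)
  for (j in 1:K) for (k in j:K) {
    C <- V[, , j]
    if (k > j) for (i in 1:(k - j)) C <- M %*% C
    Css[((k - 1) * d + 1):(k * d), ((j - 1) * d + 1):(j * d)] <- C
    Css[((j - 1) * d + 1):(j * d), ((k - 1) * d + 1):(k * d)] <- t(C)
  }
  Pb <- kronecker(diag(K), P)
  list(mu_s = as.numeric(mu_s),
       mu_y = as.numeric(Pb %*% as.numeric(mu_s)),
       Css = Css,
       Csy = Css %*% t(Pb),
       Cyy = Pb %*% Css %*% t(Pb) + kronecker(diag(K), params$R))
}

# Conditional mean of s_k given y_1..y_j (j = k: filtered; j = K: smoothed).
oracle_state_mean <- function(or, yvec, d, N, k, j) {
  iy <- 1:(N * j)
  is <- ((k - 1) * d + 1):(k * d)
  as.numeric(or$mu_s[is] +
             or$Csy[is, iy, drop = FALSE] %*%
             solve(or$Cyy[iy, iy], yvec[iy] - or$mu_y[iy]))
}

oracle_state_cov <- function(or, d, N, k, j) {
  iy <- 1:(N * j)
  is <- ((k - 1) * d + 1):(k * d)
  or$Css[is, is] - or$Csy[is, iy, drop = FALSE] %*%
    solve(or$Cyy[iy, iy], t(or$Csy[is, iy, drop = FALSE]))
}

oracle_loglik <- function(or, yvec) {
  n <- length(yvec)
  ch <- chol(or$Cyy)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
          sum(backsolve(ch, yvec - or$mu_y, transpose = TRUE)^2))
}

# Random small, well-conditioned LDS instance.
random_lds <- function(d, N, seed, bin_width = 0.015) {
  set.seed(seed)
  M <- matrix(rnorm(d * d, sd = 0.5 / sqrt(d)), d)
  M <- M * (0.9 / max(1, max(Mod(eigen(M, only.values = TRUE)$values))))
  P <- matrix(rnorm(N * d), N, d)
  S1r <- matrix(rnorm(d * d, sd = 0.5), d)
  lds_params(M, P,
             Ncov = diag(runif(d, 0.2, 0.6), d),
             R = diag(runif(N, 0.3, 0.9), N),
             pi1 = rnorm(d, sd = 0.5),
             S1 = crossprod(S1r) / d + diag(0.1, d),
             bin_width = bin_width)
}

# Minimal-assignment eigenvalue matching (small d: enumerate permutations).
perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub))) }))
}

match_eigen <- function(ev_a, ev_b) {
  pp <- perms(length(ev_a))
  costs <- apply(pp, 1, function(p) sum(Mod(ev_a - ev_b[p])))
  ev_b[pp[which.min(costs), ]]
}

# Desk-scale synthetic world used by the 20-seed qualitative analyses
# (scaled down from the 500-trial, 96-channel default for test runtime;
# the generative structure is identical).
desk_world <- function(seed, n_train = 120L, n_test = 40L, d = 10L,
                       N = 48L) {
  gt <- make_ground_truth_lds(d = d, N = N, seed = seed)
  list(gt = gt,
       train = simulate_reach_session(gt, n_trials = n_train,
                                      seed = seed + 1000L),
       test = simulate_reach_session(gt, n_trials = n_test,
                                     seed = seed + 2000L))
}

# KKF model with prescribed parameters (bypasses fitting).
new_kkf_for_test <- function(A, C, W, Q) {
  ndfilter:::new_decoder("kkf", list(A = A, C = C, W = W, Q = Q,
                                     velocity_only = FALSE))
}

vel_mse <- function(model, ses) {
  dec <- decode(model, ses$Y)
  mean((dec$vel - ses$X$vel)^2)
}
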