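// Kalman filter / RTS smoother / steady-state Riccati / EM E-step for the
// latent LDS  s_k = M s_{k-1} + n_k,  y_k = P s_k + r_k,  s_1 ~ N(pi1, S1).
//
// Conventions: the filter is seeded with the prior of s_1 directly, i.e.
// prior mean pi1, prior covariance S1 at k = 1; for k >= 2 the prior is the
// usual one-step prediction. The log-likelihood is the exact Gaussian
// innovations form. In steady-state mode the gain (and the innovation
// covariance factorization) is frozen once successive prior covariances
// agree to cov_tol in Frobenius norm.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

struct FilterPass {
  mat shat;        // d x K filtered means
  mat prior_shat;  // d x K one-step predicted means
  mat innov;       // N x K innovations y_k - P * prior
  cube post_cov;   // d x d x K posterior covariances
  cube pred_cov;   // d x d x K prior covariances
  cube gains;      // d x N x K (only filled if keep_gains)
  mat steady_gain; // d x N frozen gain (steady mode)
  int steady_from; // 1-based bin at which the gain was frozen; 0 if never
  double loglik;
};

static FilterPass run_filter(const mat& M, const mat& P, const mat& Ncov,
                             const mat& R, const vec& pi1, const mat& S1,
                             const mat& Y, bool steady, double cov_tol,
                             bool keep_gains, bool keep_covs) {
  const int d = M.n_rows, N = P.n_rows, K = Y.n_cols;
  FilterPass fp;
  fp.shat.set_size(d, K);
  fp.prior_shat.set_size(d, K);
  fp.innov.set_size(N, K);
  if (keep_covs) { fp.post_cov.set_size(d, d, K); fp.pred_cov.set_size(d, d, K); }
  if (keep_gains) fp.gains.set_size(d, N, K);
  fp.steady_from = 0;
  fp.loglik = 0.0;

  mat post(d, d), pred(d, d), prev_pred(d, d, fill::zeros);
  mat Kk(d, N), Schol(N, N);
  double logdetS = 0.0;
  bool frozen = false;
  vec m_pred(d);

  for (int k = 0; k < K; ++k) {
    if (k == 0) {
      m_pred = pi1;
      pred = S1;
    } else {
      m_pred = M * fp.shat.col(k - 1);
      if (!frozen) pred = symmatu(M * post * M.t() + Ncov);
    }
    if (!frozen) {
      mat S = symmatu(P * pred * P.t() + R);
      bool ok = chol(Schol, S, "lower");
      if (!ok)
        Rcpp::stop("innovation covariance not positive definite at bin %d", k + 1);
      logdetS = 2.0 * accu(log(Schol.diag()));
      // gain = pred * P' * S^{-1} via the Cholesky factor
      mat PtSinv = solve(trimatl(Schol), P * pred);      // L^{-1} P pred
      PtSinv = solve(trimatu(Schol.t()), PtSinv);        // S^{-1} P pred
      Kk = PtSinv.t();                                   // pred P' S^{-1}
      post = symmatu(pred - Kk * P * pred);
      if (steady && k >= 1) {
        double diff = norm(pred - prev_pred, "fro");
        if (diff < cov_tol) { frozen = true; fp.steady_from = k + 1; }
      }
      prev_pred = pred;
    }
    vec nu = Y.col(k) - P * m_pred;
    vec z = solve(trimatl(Schol), nu);
    fp.loglik += -0.5 * (N * LOG2PI + logdetS + dot(z, z));
    fp.prior_shat.col(k) = m_pred;
    fp.innov.col(k) = nu;
    fp.shat.col(k) = m_pred + Kk * nu;
    if (keep_covs) { fp.post_cov.slice(k) = post; fp.pred_cov.slice(k) = pred; }
    if (keep_gains) fp.gains.slice(k) = Kk;
  }
  fp.steady_gain = Kk;
  return fp;
}

// [[Rcpp::export]]
Rcpp::List kalman_filter_cpp(const arma::mat& M, const arma::mat& P,
                             const arma::mat& Ncov, const arma::mat& R,
                             const arma::vec& pi1, const arma::mat& S1,
                             const arma::mat& Y, bool steady,
                             double cov_tol, bool keep_gains,
                             bool keep_covs) {
  FilterPass fp = run_filter(M, P, Ncov, R, pi1, S1, Y, steady, cov_tol,
                             keep_gains, keep_covs);
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("shat") = fp.shat,
    Rcpp::Named("prior_shat") = fp.prior_shat,
    Rcpp::Named("innovations") = fp.innov,
    Rcpp::Named("loglik") = fp.loglik,
    Rcpp::Named("steady_from") = fp.steady_from,
    Rcpp::Named("steady_gain") = fp.steady_gain);
  if (keep_covs) {
    out["post_cov"] = fp.post_cov;
    out["pred_cov"] = fp.pred_cov;
  }
  if (keep_gains) out["gains"] = fp.gains;
  return out;
}

// [[Rcpp::export]]
Rcpp::List kalman_smoother_cpp(const arma::mat& M, const arma::mat& P,
                               const arma::mat& Ncov, const arma::mat& R,
                               const arma::vec& pi1, const arma::mat& S1,
                               const arma::mat& Y, bool steady,
                               double cov_tol) {
  const int d = M.n_rows, K = Y.n_cols;
  FilterPass fp = run_filter(M, P, Ncov, R, pi1, S1, Y, steady, cov_tol,
                             false, true);
  mat means(d, K);
  cube covs(d, d, K), cross(d, d, std::max(K - 1, 0));
  means.col(K - 1) = fp.shat.col(K - 1);
  covs.slice(K - 1) = fp.post_cov.slice(K - 1);
  for (int k = K - 2; k >= 0; --k) {
    const mat& pred_next = fp.pred_cov.slice(k + 1);
    mat J = solve(pred_next, M * fp.post_cov.slice(k)).t(); // post M' pred^{-1}
    means.col(k) = fp.shat.col(k) +
      J * (means.col(k + 1) - fp.prior_shat.col(k + 1));
    covs.slice(k) = symmatu(fp.post_cov.slice(k) +
      J * (covs.slice(k + 1) - pred_next) * J.t());
    // Cov(s_{k+1}, s_k | Y) = V^s_{k+1} J_k'
    cross.slice(k) = covs.slice(k + 1) * J.t();
  }
  return Rcpp::List::create(
    Rcpp::Named("means") = means,
    Rcpp::Named("covs") = covs,
    Rcpp::Named("cross_covs") = cross,
    Rcpp::Named("loglik") = fp.loglik);
}

// E-step sufficient statistics for the closed-form M-step.
// Returns loglik plus:
//   Ex1, V1   : smoothed mean / covariance of s_1
//   S_all     : sum_k E[s_k s_k']
//   S_head    : sum_{k=1..K-1} E[s_k s_k']
//   S_tail    : sum_{k=2..K}   E[s_k s_k']
//   S_lag     : sum_{k=2..K}   E[s_k s_{k-1}']
//   Sys       : sum_k y_k E[s_k]'
//   Syy_diag  : sum_k y_k % y_k (elementwise squares)
// [[Rcpp::export]]
Rcpp::List em_estep_cpp(const arma::mat& M, const arma::mat& P,
                        const arma::mat& Ncov, const arma::mat& R,
                        const arma::vec& pi1, const arma::mat& S1,
                        const arma::mat& Y, bool steady, double cov_tol) {
  const int d = M.n_rows, K = Y.n_cols;
  FilterPass fp = run_filter(M, P, Ncov, R, pi1, S1, Y, steady, cov_tol,
                             false, true);
  mat means(d, K);
  mat S_all(d, d, fill::zeros), S_head(d, d, fill::zeros),
      S_tail(d, d, fill::zeros), S_lag(d, d, fill::zeros);
  means.col(K - 1) = fp.shat.col(K - 1);
  mat cov_next = fp.post_cov.slice(K - 1);
  mat E_next = cov_next + means.col(K - 1) * means.col(K - 1).t();
  S_all += E_next;
  S_tail += E_next;
  mat V1 = cov_next;  // overwritten unless K == 1
  // in the frozen-gain region the filter covariances are constant, so the
  // smoother gain J is too; compute it once
  mat J_frozen;
  bool have_frozen = fp.steady_from > 0;
  if (have_frozen) {
    int kf = fp.steady_from - 1;  // 0-based first frozen bin
    J_frozen = solve(fp.pred_cov.slice(kf), M * fp.post_cov.slice(kf)).t();
  }
  for (int k = K - 2; k >= 0; --k) {
    const mat& pred_next = fp.pred_cov.slice(k + 1);
    mat J = (have_frozen && k >= fp.steady_from - 1 && k + 1 >= fp.steady_from - 1)
      ? J_frozen
      : mat(solve(pred_next, M * fp.post_cov.slice(k)).t());
    means.col(k) = fp.shat.col(k) +
      J * (means.col(k + 1) - fp.prior_shat.col(k + 1));
    mat cov_k = symmatu(fp.post_cov.slice(k) +
      J * (cov_next - pred_next) * J.t());
    mat E_k = cov_k + means.col(k) * means.col(k).t();
    mat E_cross = cov_next * J.t() + means.col(k + 1) * means.col(k).t();
    S_all += E_k;
    S_head += E_k;
    if (k >= 1) S_tail += E_k;
    S_lag += E_cross;
    cov_next = cov_k;
    E_next = E_k;
    if (k == 0) V1 = cov_k;
  }
  mat Sys = Y * means.t();
  vec Syy = sum(square(Y), 1);
  return Rcpp::List::create(
    Rcpp::Named("loglik") = fp.loglik,
    Rcpp::Named("means") = means,
    Rcpp::Named("Ex1") = vec(means.col(0)),
    Rcpp::Named("V1") = V1,
    Rcpp::Named("S_all") = S_all,
    Rcpp::Named("S_head") = S_head,
    Rcpp::Named("S_tail") = S_tail,
    Rcpp::Named("S_lag") = S_lag,
    Rcpp::Named("Sys") = Sys,
    Rcpp::Named("Syy_diag") = Syy);
}

// Fixed point of the discrete Riccati recursion for the prior covariance.
// [[Rcpp::export]]
Rcpp::List steady_state_gain_cpp(const arma::mat& M, const arma::mat& P,
                                 const arma::mat& Ncov, const arma::mat& R,
                                 double tol, int max_iter) {
  const int N = P.n_rows;
  mat pred = symmatu(Ncov + 1e-12 * eye(M.n_rows, M.n_rows));
  mat Kk;
  double resid = datum::inf;
  for (int it = 0; it < max_iter; ++it) {
    mat S = symmatu(P * pred * P.t() + R);
    mat Schol;
    if (!chol(Schol, S, "lower"))
      Rcpp::stop("innovation covariance not positive definite in Riccati iteration");
    mat PtSinv = solve(trimatu(Schol.t()), solve(trimatl(Schol), P * pred));
    Kk = PtSinv.t();
    mat post = symmatu(pred - Kk * P * pred);
    mat pred_new = symmatu(M * post * M.t() + Ncov);
    resid = norm(pred_new - pred, "fro");
    pred = pred_new;
    if (resid < tol) {
      mat S2 = symmatu(P * pred * P.t() + R);
      mat K2 = (solve(S2, P * pred)).t();
      return Rcpp::List::create(Rcpp::Named("gain") = K2,
                                Rcpp::Named("prior_cov") = pred,
                                Rcpp::Named("iterations") = it + 1,
                                Rcpp::Named("residual") = resid);
    }
  }
  Rcpp::stop("Riccati iteration did not converge in %d iterations (residual %g)",
             max_iter, resid);
}
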