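# Diagnostic statistics for dynamical models of neural population activity.

#' Contribution of the dynamics process versus the innovations process
#'
#' Decomposes each Kalman-filter state update into the first-order
#' dynamics contribution \eqn{a_k = \|(M - I)\hat s_{k-1}\|_2} (the
#' model-predicted state change; `(M - I)/dt` is the first-order
#' approximation of the continuous dynamics) and the innovations
#' contribution \eqn{b_k = \|K_k (y_k - P M \hat s_{k-1})\|_2}, and
#' reports \eqn{\rho_k = a_k / (a_k + b_k)} per bin and its average
#' \eqn{\bar\rho} over bins (bins with \eqn{a_k + b_k = 0} are excluded).
#'
#' @param params an [lds_params()].
#' @param Y a [spike_counts()].
#' @param mode filtering mode passed to [kalman_filter()].
#' @return list with `rho_bar` (scalar in `[0, 1]`) and `per_bin`
#'   (length `K - 1`, for bins `k = 2..K`).
#' @export
dynamics_contribution <- function(params, Y,
                                  mode = c("steady_state", "exact")) {
  mode <- match.arg(mode)
  if (n_bins(Y) < 2L) stop("need at least two bins", call. = FALSE)
  fr <- kalman_filter(params, Y, mode = mode)
  K <- ncol(fr$shat)
  ks <- 2:K
  MI <- params$M - diag(params$d)
  a <- sqrt(colSums((MI %*% fr$shat[, ks - 1, drop = FALSE])^2))
  # K_k nu_k is exactly the posterior-minus-prior state update
  upd <- fr$shat[, ks, drop = FALSE] - fr$prior_shat[, ks, drop = FALSE]
  b <- sqrt(colSums(upd^2))
  tot <- a + b
  ok <- tot > 0
  if (!any(ok)) stop("all bins degenerate (zero update)", call. = FALSE)
  rho <- ifelse(ok, a / tot, NA_real_)
  list(rho_bar = mean(rho[ok]), per_bin = rho)
}

#' Fraction of variance captured by a prediction
#'
#' \eqn{1 - SSE/SST} with \eqn{SSE = \sum_k \|y_k - \hat y_k\|^2} and
#' \eqn{SST = \sum_k \|y_k - \bar y\|^2}, \eqn{\bar y} the per-channel
#' temporal mean, pooled across channels and time. Can be negative for
#' predictors worse than the mean.
#'
#' @param Y_true,Y_pred N x K matrices (or [spike_counts()]).
#' @return scalar fraction.
#' @export
captured_variance <- function(Y_true, Y_pred) {
  Yt <- as_count_matrix(Y_true); Yp <- as_count_matrix(Y_pred)
  if (!all(dim(Yt) == dim(Yp)))
    stop("shape mismatch between truth and prediction", call. = FALSE)
  sst <- sum((Yt - rowMeans(Yt))^2)
  if (sst == 0) stop("zero total variance", call. = FALSE)
  1 - sum((Yt - Yp)^2) / sst
}

#' Forward prediction of neural activity under three predictors
#'
#' Scores one-step-ahead prediction of \eqn{y_k} (for `k = 2..K`) by
#' [captured_variance()] under: (i) `smoothing` — the causally
#' Gaussian-smoothed counts at `k - 1`; (ii) `lds_single` — \eqn{P M \hat
#' s_{k-1}} with the filter run under single-trial-fitted parameters;
#' (iii) `lds_condavg` — the same using parameters fitted to
#' condition-averaged training data but filtered on the single-trial `Y`.
#'
#' @param Y held-out [spike_counts()].
#' @param params_single LDS fitted on single-trial training data.
#' @param params_condavg LDS fitted on condition-averaged training data
#'   (optional; its entry is `NA` when omitted).
#' @param kernel_sd smoothing kernel s.d. in seconds (default 0.100).
#' @return named numeric vector `c(smoothing, lds_single, lds_condavg)`.
#' @export
forward_prediction_study <- function(Y, params_single, params_condavg = NULL,
                                     kernel_sd = 0.100) {
  Ym <- as_count_matrix(Y)
  K <- ncol(Ym)
  truth <- Ym[, 2:K, drop = FALSE]
  Ys <- causal_gaussian_smooth(Y, kernel_sd)
  cv_smooth <- captured_variance(truth, Ys[, 1:(K - 1), drop = FALSE])
  lds_pred <- function(params) {
    fr <- kalman_filter(params, Y, mode = "steady_state")
    pred <- params$P %*% (params$M %*% fr$shat[, 1:(K - 1), drop = FALSE])
    captured_variance(truth, pred)
  }
  cv_single <- lds_pred(params_single)
  cv_condavg <- if (is.null(params_condavg)) NA_real_
                else lds_pred(params_condavg)
  c(smoothing = cv_smooth, lds_single = cv_single, lds_condavg = cv_condavg)
}

#' Condition-averaged responses
#'
#' Averages single-trial responses across trials of the same condition at
#' matched within-trial bins (trials truncated to the shortest trial of
#' the condition); the output concatenates the per-condition averages.
#'
#' @param Y a [spike_counts()].
#' @param condition_ids,trial_ids per-bin labels (length K).
#' @return a [spike_counts()] of concatenated condition averages, with
#'   per-bin attributes `condition_ids` and `bin_in_trial`.
#' @export
condition_average <- function(Y, condition_ids, trial_ids) {
  Ym <- as_count_matrix(Y)
  bw <- if (inherits(Y, "spike_counts")) Y$bin_width else 0.015
  K <- ncol(Ym)
  if (length(condition_ids) != K || length(trial_ids) != K)
    stop("labels must have one entry per bin", call. = FALSE)
  conds <- unique(condition_ids[!is.na(condition_ids)])
  pieces <- list(); out_cond <- list(); out_bin <- list()
  for (cc in conds) {
    trials <- unique(trial_ids[condition_ids == cc & !is.na(trial_ids)])
    if (length(trials) < 1L)
      stop(sprintf("condition %s has no trials", cc), call. = FALSE)
    mats <- lapply(trials, function(tr)
      Ym[, trial_ids == tr & condition_ids == cc, drop = FALSE])
    len <- min(vapply(mats, ncol, integer(1)))
    if (len == 0L) stop(sprintf("condition %s is empty", cc), call. = FALSE)
    avg <- Reduce(`+`, lapply(mats, function(m) m[, 1:len, drop = FALSE])) /
      length(mats)
    pieces[[length(pieces) + 1L]] <- avg
    out_cond[[length(out_cond) + 1L]] <- rep(cc, len)
    out_bin[[length(out_bin) + 1L]] <- seq_len(len)
  }
  out <- spike_counts(do.call(cbind, pieces), bin_width = bw)
  attr(out, "condition_ids") <- unlist(out_cond)
  attr(out, "bin_in_trial") <- unlist(out_bin)
  out
}

#' Hold/reach speed ratio
#'
#' `mode = "observed_diff"`: ratio of the mean per-bin population speed
#' \eqn{\|y_{k+1} - y_k\|} over hold bins to the same mean over reach
#' bins. `mode = "model_state"`: the same ratio for the first-order
#' model-predicted state speed \eqn{\|(M - I) s_k\|} evaluated on the
#' supplied state sequence (requires `M`).
#'
#' @param signal matrix over bins: observations (N x K) for
#'   `observed_diff`, filtered/smoothed states (d x K) for `model_state`.
#' @param mask an [epoch_mask()]; bins indexing columns of `signal`.
#' @param mode `"observed_diff"` or `"model_state"`.
#' @param M dynamics matrix (required for `model_state`).
#' @return scalar hold/reach ratio.
#' @export
speed_ratio <- function(signal, mask, mode = c("observed_diff", "model_state"),
                        M = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(mask, "epoch_mask"))
  sig <- as_count_matrix(signal)
  K <- ncol(sig)
  if (!length(mask$hold_bins) || !length(mask$reach_bins))
    stop("both epoch sets must be nonempty", call. = FALSE)
  if (mode == "observed_diff") {
    sp <- sqrt(colSums((sig[, 2:K, drop = FALSE] -
                        sig[, 1:(K - 1), drop = FALSE])^2))
    usable <- function(b) b[b <= K - 1]
  } else {
    if (is.null(M)) stop("`M` is required for model_state mode", call. = FALSE)
    sp <- sqrt(colSums(((M - diag(nrow(M))) %*% sig)^2))
    usable <- function(b) b[b <= K]
  }
  hold <- mean(sp[usable(mask$hold_bins)])
  reach <- mean(sp[usable(mask$reach_bins)])
  if (reach == 0) stop("mean reach-epoch speed is zero", call. = FALSE)
  hold / reach
}
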