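# ndfilter

Latent linear dynamical systems (LDS) and neural dynamical filtering for
decoding cursor kinematics from binned spike counts.

## The problem

Motor cortical population activity has its own temporal structure: the
population state at one moment is informative about the state a moment
later. A practical way to exploit that structure is to model binned
threshold-crossing counts `y_k` (N channels, non-overlapping 15-ms bins)
as noisy observations of a low-dimensional latent *neural state* `s_k`
that evolves under linear dynamics:

```
s_k = M s_{k-1} + n_k        n_k ~ N(0, Ncov)     (dynamics process)
y_k = P s_k     + r_k        r_k ~ N(0, R)        (observation process)
```

with `Ncov` and `R` diagonal. The parameters `(M, P, Ncov, R, pi1, S1)`
are learned from training data by expectation-maximization (EM,
initialized with factor analysis), and the neural state is estimated
online with the steady-state Kalman filter. The **neural dynamical filter
(NDF)** then decodes 2D cursor position and velocity as a linear readout
(plus bias) of the filtered neural state,

```
x_hat_k = L_s [s_hat_k; 1]
```

and displays the blended position
`p_k = (1 - alpha) p_hat_k + alpha (p_{k-1} + dt v_hat_k)` with
`alpha = 0.975`. Because the dynamics denoise the single-trial state
estimate, the NDF outperforms decoders driven by the raw (or merely
smoothed) counts. The package implements the NDF together with its
standard comparison decoders — optimal linear estimator (OLE, causally
Gaussian-smoothed counts), Wiener filter (WF, ridge regression on a
stacked spike-count history), kinematic-state Kalman filter (KKF, a
Kalman filter whose latent state is the cursor kinematics), and a
PC-smooth control (20 smoothed principal components) — plus the
diagnostics used to characterize such models:

* `dynamics_contribution()` — per-bin ratio of the first-order dynamics
  contribution `||(M - I) s_hat_{k-1}||` to the total state update
  (dynamics + innovations), averaged over bins;
* `forward_prediction_study()` — variance of `y_k` captured by causal
  smoothing at `k-1` versus the one-step LDS prediction `P M s_hat_{k-1}`
  (single-trial or condition-averaged dynamics);
* `speed_ratio()` — hold-epoch to reach-epoch ratio of observed
  population speed `||y_{k+1} - y_k||` or model-predicted state speed
  `||(M - I) s_k||`;
* `grid_bitrate()` — achieved bitrate of a 36-target selection task,
  `max(0, c - l) log2(36) / T` bits/s, so a 50% success rate conveys
  zero information.

No recorded data ship with the package: `make_ground_truth_lds()` and
`simulate_reach_session()` generate center-out-and-back sessions (8
targets on a 12-cm circle, 500-ms holds, ~60 bins per acquisition) from a
known ground-truth LDS with a linear kinematic readout, and
`simulate_grid_session()` generates grid-task selection streams.

## Worked example

```r
library(ndfilter)

gt  <- make_ground_truth_lds(d = 10, N = 48, seed = 1)
trn <- simulate_reach_session(gt, n_trials = 120, seed = 1001)
tst <- simulate_reach_session(gt, n_trials = 40,  seed = 2001)

ndf <- fit_ndf(trn$Y, trn$X, d = 10, em_opts = list(max_iter = 40))
ole <- fit_ole(trn$Y, trn$X, kernel_sd = 0.100)

mse <- function(m) mean((decode(m, tst$Y)$vel - tst$X$vel)^2)
cat(sprintf("velocity MSE  NDF %.1f  OLE %.1f (cm/s)^2\n", mse(ndf), mse(ole)))

dc <- dynamics_contribution(ndf$lds, trn$Y)
fr <- kalman_filter(ndf$lds, tst$Y, mode = "steady_state")
cat(sprintf("dynamics contribution %.2f\n", dc$rho_bar))
cat(sprintf("hold/reach model speed ratio %.2f\n",
            speed_ratio(fr$shat, tst$mask, "model_state", M = ndf$lds$M)))
print(round(forward_prediction_study(tst$Y, ndf$lds), 3))
```

prints (R 4.3, this package version):

```
velocity MSE  NDF 55.8  OLE 96.2 (cm/s)^2
dynamics contribution 0.29
hold/reach model speed ratio 0.76
  smoothing  lds_single lds_condavg
      0.124       0.204          NA
```

The NDF tracks velocity better than the OLE because the Kalman filter
pools information over time using the learned dynamics; the dynamics
process contributes about a third of each state update; model-predicted
neural-state speeds are slower while holding than reaching; and one-step
LDS prediction captures more future neural variance than causal
smoothing.

The same pipeline is scriptable: `inst/cli/ndf` exposes
`simulate | fit | decode | metrics | bitrate` subcommands over the
delimited-text session format (see `?ndf_cli`).

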