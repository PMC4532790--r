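---
title: "Neural dynamical filtering: models, diagnostics, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural dynamical filtering: models, diagnostics, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndfilter)
```

## The model and its assumptions

`ndfilter` models binned spike counts $y_k \in \mathbb{R}^N$ (threshold
crossings per channel in non-overlapping bins of width $\Delta t$,
default 15 ms) as noisy linear observations of a latent neural state
$s_k \in \mathbb{R}^d$ evolving under autonomous linear dynamics:

$$ s_k = M s_{k-1} + n_k, \qquad n_k \sim \mathcal N(0, N_{cov}) $$
$$ y_k = P s_k + r_k, \qquad r_k \sim \mathcal N(0, R) $$

with $s_1 \sim \mathcal N(\pi_1, S_1)$ and $N_{cov}$, $R$ diagonal. The
assumptions worth keeping in mind:

* **Linearity and time invariance.** One global $(M, P)$ describes the
  whole session. Real population activity is at best locally linear;
  the model's value is that the fitted $M$ still captures dominant decay
  and rotation time-scales, and that its filtered state is a usable,
  denoised low-dimensional summary.
* **Gaussianity.** Counts in 15-ms bins are small integers with
  Poisson-like noise; the Gaussian observation model treats them as
  real-valued. The model is fit without any preprocessing of the counts
  and without an explicit mean term — the latent state absorbs mean
  structure. An optional per-channel offset (estimated as the channel
  mean, removed before EM, restored on prediction) is available via
  `em_fit(..., offset = TRUE)` for poorly conditioned regimes; it is off
  by default.
* **Diagonal noise.** Channel noise is conditionally independent given
  the state; shared variability must route through the $d$-dimensional
  state.

## Learning and inference

* **EM.** `em_fit()` alternates Kalman smoothing (E-step) with the
  closed-form M-step; $N_{cov}$ and $R$ are projected to diagonal each
  M-step (the standard constrained M-step for this model class), with
  variances floored at $10^{-10}$ against silent channels. $\pi_1, S_1$
  are re-estimated each iteration; after filter burn-in they are
  operationally irrelevant. Initialization is factor analysis by
  default: loadings seed $P$, uniquenesses seed $R$, a lag-1 regression
  of the factor scores seeds $M$, and the diagonalized score-regression
  residual covariance seeds $N_{cov}$. Warm starts from a previous
  `lds_params` are supported and sometimes find better optima.
* **Convergence.** EM stops when the relative log-likelihood improvement
  falls below `tol` ($10^{-6}$) or after `max_iter` (200) iterations. No
  tolerances are canonical for this model family; these reproduce
  convergence in seconds-to-minutes at session scale.
* **Steady-state approximation.** The default E-step (`estep =
  "steady"`) freezes the filter gain once successive one-step prior
  covariances agree to $10^{-8}$ in Frobenius norm, and reuses the
  frozen smoother gain in that region; `estep = "exact"` guarantees a
  monotone log-likelihood and is what the monotonicity tests use. The
  freezing threshold is a design choice; at $10^{-8}$ the two E-steps
  agree to well below the EM convergence tolerance in practice.
* **Filtering.** `kalman_filter(mode = "steady_state")` freezes the gain
  the same way; this is the form used for decoding (convergence takes on
  the order of seconds of data). `mode = "exact"` keeps per-bin gains
  and returns the exact innovations-form log-likelihood.
  `steady_state_gain()` iterates the discrete Riccati recursion to its
  fixed point.
* **Conventions.** Bins are 1-based; bin $k$ covers
  $[(k-1)\Delta t, k\Delta t)$. The filter is seeded with the prior of
  the *first* state: at $k = 1$ the prior mean/covariance are
  $(\pi_1, S_1)$, and from $k \ge 2$ the usual one-step prediction
  applies. Positions are cm, velocities cm/s, durations seconds,
  frequencies Hz.

## Decoders and their tunable parameters

All decoders map causally computed features to the 4-vector
$[p_x, p_y, v_x, v_y]$ by least squares with a bias (ones-row
augmentation), and blend the displayed position as
$p_k = (1-\alpha)\hat p_k + \alpha(p_{k-1} + \Delta t\, \hat v_k)$ with
$\alpha = 0.975$ — 2.5% decoded position, 97.5% integrated velocity.

| parameter | default | meaning |
|---|---|---|
| `d` | 20 | latent dimension; 10–20 captures most shared variance in reach data |
| `alpha` | 0.975 | position-blending weight |
| `kernel_sd` (OLE) | 0–0.200 s | causal Gaussian smoothing; grid `{0, 25, 50, 100, 150, 200}` ms |
| `p` (WF) | 17 bins | spike-history length (~250 ms at 15-ms bins) |
| `lam` (WF) | ≥ 0 | ridge weight on the non-bias coefficients |
| `n_components` (PC-smooth) | 20 | principal components kept, 100-ms causal smoothing |

Numerical and boundary choices that the interfaces expose but the model
class does not dictate:

* **Causal Gaussian kernel.** Truncated at lag 0 (no future) and at 4
  s.d. in the past, renormalized to sum to 1 *over the lags available at
  each bin*, so constants are preserved from the first bin onward. (A
  fixed-normalization kernel with zero-padding would attenuate the first
  few hundred milliseconds instead; either convention is defensible, we
  prefer constant preservation.)
* **WF start-up.** The first $p - 1$ bins use zero-padded history, so
  output is defined from bin 1, matching streaming use. The ridge
  penalty $\lambda\|L\|^2$ is applied to the unscaled normal equations
  and never to the bias row.
* **Readout degeneracies.** All-zero feature rows get zero coefficients
  (the minimum-norm choice); any other rank deficiency is an error
  suggesting ridge, since silently picking one of many least-squares
  solutions would make fits irreproducible across BLAS libraries.
* **KKF.** Full 4D position+velocity state (a pure-velocity variant sits
  behind `velocity_only`, reflecting the observation that pure velocity
  filters decode worse); $A$, $C$ by least squares, $W$, $Q$ as residual
  sample covariances with the maximum-likelihood $1/K$ normalizer ($K$ =
  number of residual columns), stated so oracles agree. The decode
  filter starts at $[{\rm init\_pos}, 0, 0]$ with covariance $W$.
* **Decoding defaults.** `init_pos` is the workspace center $(0,0)$.
  Every decoder is strictly causal: output at bin $k$ depends only on
  bins $\le k$ (a tested invariant).

## Diagnostics

* **Dynamics versus innovations.** Each filter update decomposes as
  $\hat s_k = M\hat s_{k-1} + K_k\nu_k$. We report
  $\rho_k = a_k/(a_k + b_k)$ with $a_k = \|(M - I)\hat s_{k-1}\|_2$ (the
  first-order dynamics contribution to the state *change*; $(M-I)/\Delta
  t$ approximates the continuous dynamics) and $b_k = \|K_k \nu_k\|_2$,
  and the average $\bar\rho$ over bins $2..K$ (degenerate bins with
  $a_k + b_k = 0$ excluded). This composition — norms of the two update
  components, ratio of dynamics to their sum — is one concrete reading
  of "relative contribution"; it is bounded in $[0,1]$ and weakly
  increases as observation noise grows (tested).
* **Captured variance.** $1 - SSE/SST$ pooled across channels and time,
  with $SST$ about the per-channel temporal mean. Pooling (rather than
  per-channel averaging) weights channels by their variance; the
  alternative is a one-line change and was not needed.
* **Speed ratios.** Observed population speed $\|y_{k+1}-y_k\|$ and
  model-predicted state speed $\|(M-I)s_k\|$, averaged over hold bins
  (100 ms after hold initiation to 150 ms before completion) and reach
  bins (center-out movements), ratio hold/reach. Epoch masks are caller
  (or generator) supplied; no movement-onset detection is implemented.
* **Grid bitrate.** $\max(0, c - \ell)\log_2 36 / T$: each incorrect
  selection cancels a correct one, so 50% success conveys nothing.
  Timeouts consume time but count in neither $c$ nor $\ell$.

## The synthetic world

The generator provides the *stated world* every simulation-based test
runs in; its defaults mirror the task conditions the model class was
built for, and were chosen once:

* **Geometry and scale.** 8 targets on a 12-cm circle, 500-ms holds,
  ~60 bins (0.9 s) per target acquisition — a ~0.4-s minimum-jerk
  movement plus the hold — so the default 500 acquisitions give ~30,000
  bins. Default $d = 20$, $N = 96$ channels.
* **Dynamics.** $M = T B T^{-1}$ with $B$ block-diagonal: a slow
  "posture" pair (real eigenvalues 0.998 — a state parked there barely
  moves, which is what lets a hold be a hold under autonomous dynamics),
  a fast "movement" pair (0.92, ~0.2-s decay), and damped rotations with
  moduli in [0.95, 0.985] and frequencies in [0.5, 2.5] Hz. $T$ is a
  well-conditioned random similarity, block-structured so the posture
  subspace keeps its small process noise after $N_{cov}$ is projected to
  diagonal; the result is non-normal and full rank.
* **Trajectories.** A designed latent path $s^*$ traces the task
  (position in the posture subspace, velocity in the movement subspace,
  condition-dependent rotational excitation during movement); the
  realized state is steered along $s^*$ by a deterministic input while
  its fluctuation $e_k = s_k - s^*_k$ follows the autonomous dynamics
  exactly. Kinematics are the linear readout of the state plus small
  measurement noise (0.1 cm, 0.5 cm/s) — the structural assumption under
  which the NDF is well-specified.
* **Noise levels.** Process-noise s.d. (0.01, 0.03, 0.06) for
  posture/movement/rotational dimensions gives ~1 cm of positional
  wander during holds and keeps hold-epoch hand speed below 20% of
  reach-epoch speed; observation noise s.d. 1.0 per channel against
  per-channel signal s.d. of roughly 0.3–0.5 makes single bins noisy
  enough that dynamical denoising visibly beats kernel smoothing, the
  regime the decoder comparisons are about. These defaults are
  calibrated only to reproduce qualitative orderings, not any particular
  published number.
* **Emission.** Gaussian emission follows the observation process
  exactly and produces real-valued (occasionally negative) "counts";
  the `spike_counts` container therefore validates integrality only on
  request. Poisson emission (softplus rates) exists for robustness
  checks only; all model fitting is Gaussian.

**What a green test does and does not establish.** The generator
realizes the model assumptions by construction (linear readout, Gaussian
noise, a single global LDS perturbed by a task input). Green
simulation tests establish internal correctness and the direction of the
qualitative effects — dynamical one-step prediction beats causal
smoothing, single-trial dynamics beat condition-averaged dynamics,
hold-region state speeds are slower, permuting the dynamics matrix hurts
decoding — under those assumptions. They do not establish effect sizes
on real recordings, closed-loop performance (no feedback loop or subject
adaptation is simulated), robustness to non-Poisson overdispersion,
electrode drift, or model mismatch beyond the steering input.

## Scale-down for test budgets

The 20-seed qualitative analyses in the test suite run the desk-scale
world (120 training + 40 test acquisitions, $d = 10$, $N = 48$, EM
capped at 40 iterations) rather than the 500-trial default, purely for
runtime; the generative structure is identical and the full-scale
defaults reproduce the same orderings (checked interactively, ~2 min per
fit).

## Known limitations

* Fitting an autonomous LDS to *steered* session data (the generator
  drives the latent state along the task path with a deterministic
  input) biases the recovered spectrum: the fitted $M$ must also explain
  the task-locked mean trajectories, so eigenvalue moduli — especially
  the slow posture modes — come out compressed relative to the
  generating block design. Exact spectrum recovery holds on purely
  autonomous data (tested to 0.05 modulus; observed ~2e-4); on session
  data only the qualitative structure (stability, slow/fast separation,
  rotational band) is recovered.
* The EM objective is non-convex; different initializations can reach
  different local optima (warm starts are provided for exactly this
  reason). Recovery tests therefore compare eigenvalue spectra through a
  minimal-cost assignment, not raw parameters, since the latent basis is
  only identified up to similarity.
* The steady-state E-step sacrifices the monotonicity guarantee; gross
  decreases (relative $10^{-4}$) still error.
* Condition-averaged fitting concatenates per-condition averages into
  one sequence; the few bins at condition boundaries violate the
  dynamics, a negligible effect at the tested scales.
* `dynamics_contribution` depends on the filter's gain schedule; with
  `mode = "exact"` the first bins (large transient gains) slightly
  depress $\bar\rho$, with `mode = "steady_state"` (default) the frozen
  gain is used throughout.
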