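Package: ndfilter
Title: Latent Linear Dynamical Systems and Neural Dynamical Filtering for
    Spike-Count Decoding
Version: 0.1.0
Authors@R:
    person("ndfilter", "developers", email = "ndfilter@example.org",
           role = c("aut", "cre"))
Description: Learns latent-state linear dynamical systems (LDS) from binned
    neural spike counts by expectation-maximization, estimates the latent
    neural state with exact and steady-state Kalman filters and an RTS
    smoother, and decodes 2D cursor kinematics with a neural dynamical
    filter (NDF) alongside comparison decoders (optimal linear estimator,
    Wiener filter, kinematic-state Kalman filter, smoothed principal
    components). Includes diagnostics for dynamical models of neural
    population activity (dynamics-versus-innovations contribution,
    forward-prediction captured variance, hold/reach neural speed ratios,
    achieved bitrate of grid-based target selection) and a synthetic
    center-out-and-back session generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
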