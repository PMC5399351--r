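#' Synthetic fixtures with analytically known statistics
#'
#' Generates small, exactly-characterized inputs for estimator tests:
#'
#' * `"ou_free"` -- a flat-potential ensemble; the activity marginal is
#'   \eqn{N(0, D/\tau)} and the long-time diffusivity is `D`.
#' * `"harmonic_exact"` -- iid Gaussian `(x, v)` samples drawn from the
#'   closed-form stationary law of the harmonic well: under the GCN
#'   dynamics the stationary `(x, v)` covariance is diagonal with
#'   \deqn{\mathrm{Var}(x) = \frac{D\gamma}{k}\,\frac{1}{1 + \tau k/\gamma},
#'    \qquad \mathrm{Var}(v) = \frac{D}{\tau}\,\frac{1}{1 + \tau k/\gamma}
#'    = \theta,}
#'   (linear filtering of Ornstein-Uhlenbeck noise; note
#'   \eqn{\mathrm{Var}(v) = \theta(x)} since \eqn{\Gamma = 1 + \tau
#'   k/\gamma} is constant).  Packaged as a `trajectory_ensemble` whose
#'   "recorded times" are independent draws.
#' * `"ucna_phase_space"` -- the exact local-Maxwellian grid distribution
#'   built on the UCNA density; all heat-flux estimators vanish on it
#'   identically.
#' * `"double_well_short"` -- a short seeded double-well run at the
#'   showcase parameters (`gamma = D = 1, tau = 0.7`), for smoke tests.
#'
#' @param kind fixture name (see above).
#' @param params a [gcn_params()]; defaults per kind.
#' @param seed integer seed.
#' @param n number of trajectories (samples per time for the iid kinds).
#' @param k spring constant for `"harmonic_exact"`.
#' @return A `trajectory_ensemble` or a `phase_space_dist` (for
#'   `"ucna_phase_space"`).
#' @export
make_fixture <- function(kind, params = NULL, seed = 1, n = 256, k = 1) {
  switch(kind,
    ou_free = {
      p <- params %||% gcn_params(tau = 0.5)
      simulate_xa(pot_flat(), p,
                  sim_config(n_traj = n, n_steps = 20000, dt = p$tau / 100,
                             burn_in = 2000, seed = seed))
    },
    harmonic_exact = {
      p <- params %||% gcn_params(tau = 0.5)
      set.seed(seed)
      gam_fac <- 1 + p$tau * k / p$gamma
      vx <- p$D * p$gamma / k / gam_fac
      vv <- p$T_b / gam_fac
      nt <- 40L
      x <- matrix(stats::rnorm(nt * n, 0, sqrt(vx)), nt, n)
      v <- matrix(stats::rnorm(nt * n, 0, sqrt(vv)), nt, n)
      cfg <- sim_config(n_traj = n, n_steps = nt, dt = 1, seed = seed)
      new_ensemble(seq_len(nt), x, v, "xv", p, cfg)
    },
    ucna_phase_space = {
      p <- params %||% gcn_params(tau = 0.7)
      pot <- pot_double_well()
      xg <- seq(-2.2, 2.2, length.out = 201)
      local_maxwellian(pot, p, ucna_density(pot, p, xg))
    },
    double_well_short = {
      p <- params %||% gcn_params(tau = 0.7)
      simulate_xv(pot_double_well(), p,
                  sim_config(n_traj = n, n_steps = 50000, dt = 1e-3 * p$tau,
                             burn_in = 20000, seed = seed))
    },
    stop("unknown fixture kind: ", kind)
  )
}
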