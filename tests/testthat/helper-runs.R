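# Shared heavy computations, memoized across test files.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# Reference ensemble experiment, desk scale: double well, gamma = D = 1,
# tau = 0.7, dt = 1e-3 tau, 256 trajectories, 10^6 steps after a 100 tau
# burn-in.
double_well_run <- function() {
  cached("dw_run", {
    p <- gcn_params(gamma = 1, D = 1, tau = 0.7)
    dt <- 1e-3 * p$tau
    burn <- ceiling(100 * p$tau / dt)
    cfg <- sim_config(n_traj = 256, n_steps = 1e6 + burn, dt = dt,
                      burn_in = burn, seed = 1, init_x = 0)
    simulate_xv(pot_double_well(), p, cfg)
  })
}

double_well_profile <- function() {
  cached("dw_profile", {
    ens <- double_well_run()
    entropy_flux_density(estimate_fields(ens, pot_double_well()))
  })
}

# Converged spectral steady state at the same parameters.
double_well_steady <- function() {
  cached("dw_steady", {
    solve_kramers(pot_double_well(), gcn_params(tau = 0.7),
                  kramers_grid(nx = 97, nv = 100, L = 2.8))
  })
}

kramers_steady_matrix <- function() {
  cached("steady_matrix", {
    cases <- list(
      flat = list(pot_flat(), gcn_params(tau = 0.5),
                  kramers_grid(nx = 33, nv = 24, L = 1.5)),
      linear = list(pot_linear(1), gcn_params(tau = 0.5),
                    kramers_grid(nx = 129, nv = 32, L = 7)),
      harmonic = list(pot_harmonic(1), gcn_params(tau = 0.5),
                      kramers_grid(nx = 97, nv = 40, L = 6)),
      dw_tau02 = list(pot_double_well(), gcn_params(tau = 0.2),
                      kramers_grid(nx = 97, nv = 64, L = 3.2)),
      dw_tau07 = list(pot_double_well(), gcn_params(tau = 0.7),
                      kramers_grid(nx = 97, nv = 100, L = 2.8)))
    lapply(cases, function(cs) solve_kramers(cs[[1]], cs[[2]], cs[[3]]))
  })
}

zeta_solution <- function(zeta) {
  cached(paste0("zeta_", zeta), {
    solve_kramers(pot_double_well(), gcn_params(tau = 1 / zeta^2),
                  kramers_grid(nx = 97, nv = 40, L = 3.3))
  })
}
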