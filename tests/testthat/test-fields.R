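# synthetic ensemble with iid product samples: x ~ any law, v ~ N(0, theta0)
product_ensemble <- function(n_traj = 64, n_rec = 400, theta0 = 1.3, seed = 2) {
  set.seed(seed)
  p <- gcn_params(tau = 1 / theta0)      # so T_b = theta0
  x <- matrix(stats::rnorm(n_traj * n_rec, 0, 0.8), n_rec, n_traj)
  v <- matrix(stats::rnorm(n_traj * n_rec, 0, sqrt(theta0)), n_rec, n_traj)
  cfg <- sim_config(n_traj = n_traj, n_steps = n_rec, dt = 1, seed = seed)
  gcntherm:::new_ensemble(seq_len(n_rec), x, v, "xv", p, cfg)
}

test_that("estimated fields recover a known product density", {
  theta0 <- 1.3
  ens <- product_ensemble(theta0 = theta0)
  fp <- estimate_fields(ens, pot_flat(), ens$params,
                        x_edges = seq(-2.5, 2.5, length.out = 26),
                        min_count = 50)
  ok <- !fp$masked
  expect_gt(sum(ok), 10)
  # density normalized over all bins
  dx <- diff(attr(fp, "x_edges"))
  expect_lt(abs(sum(fp$n * dx, na.rm = TRUE) - 1), 0.05)  # tail spill only
  # conditional temperature = theta0 and Gaussian third moment = 0, per bin
  expect_true(all(abs(fp$T[ok] - theta0) < 3.5 * fp$se_msv[ok]))
  expect_true(all(fp$T[ok] >= 0))
  mu3 <- 2 * fp$j_q[ok] / fp$n[ok]
  expect_lt(max(abs(mu3)), 3.5 * sqrt(15 * theta0^3 / min(fp$counts[ok])) * 3)
})

test_that("masking: sparse bins are NA, never zero-filled", {
  ens <- product_ensemble(n_traj = 8, n_rec = 50)
  fp <- estimate_fields(ens, pot_flat(), ens$params,
                        x_edges = seq(-4, 4, length.out = 81), min_count = 30)
  expect_true(any(fp$masked))
  expect_true(all(is.na(fp$T[fp$masked])))
  expect_error(estimate_fields(product_ensemble(n_traj = 1), pot_flat()),
               "2 trajectories")
})

test_that("heat flux vanishes when the particle sits at the bath temperature", {
  # grid local-Maxwellian with T(x) = theta(x) exactly: qdot == 0 at machine tol
  fx <- make_fixture("ucna_phase_space")
  p <- gcn_params(tau = 0.7)
  gp <- grid_profile(fx$P, fx$x, fx$v, pot_double_well(), p)
  gp <- entropy_flux_density(gp)
  ok <- !gp$masked
  scale <- max(abs(gp$theta[ok])) / p$tau
  expect_lt(max(abs(gp$qdot[ok])), 1e-6 * scale)
  expect_lt(max(abs(gp$j_q[ok])), 1e-10)
  expect_lt(max(abs(gp$sigma_m[ok])), 1e-6)
  bud <- thermo_budget(gp)
  expect_lt(abs(bud$total_qdot), 1e-6)
  expect_lt(abs(bud$total_entropy_flux), 1e-6)
})

test_that("harmonic ensemble has flat kinetic-temperature profile at theta", {
  k <- 1
  p <- gcn_params(tau = 0.5)
  fx <- make_fixture("harmonic_exact", params = p, seed = 8, n = 2048, k = k)
  fp <- estimate_fields(fx, pot_harmonic(k), p,
                        x_edges = seq(-1.5, 1.5, length.out = 16),
                        min_count = 100)
  ok <- !fp$masked
  theta <- p$T_b / (1 + p$tau * k / p$gamma)
  expect_true(all(abs(fp$msv[ok] - theta) < 3.5 * fp$se_msv[ok]))
})

test_that("budget z-scores are invariant under heat-flux prefactor rescaling", {
  fp <- double_well_profile()
  bud <- thermo_budget(fp)
  fp2 <- fp
  attr(fp2, "qdot_traj") <- 17 * attr(fp, "qdot_traj")
  attr(fp2, "sm_traj") <- 17 * attr(fp, "sm_traj")
  fp2$qdot <- 17 * fp2$qdot; fp2$se_qdot <- 17 * fp2$se_qdot
  fp2$sigma_m <- 17 * fp2$sigma_m; fp2$se_sigma_m <- 17 * fp2$se_sigma_m
  bud2 <- thermo_budget(fp2)
  expect_equal(bud2$z_qdot, bud$z_qdot)
  expect_equal(bud2$z_entropy_flux, bud$z_entropy_flux)
  expect_equal(bud2$total_qdot, 17 * bud$total_qdot)
})

test_that("field estimators converge at the Monte Carlo 1/sqrt(N) rate", {
  theta0 <- 1.3
  err_at <- function(n_rec, seed) {
    ens <- product_ensemble(n_traj = 64, n_rec = n_rec, theta0 = theta0,
                            seed = seed)
    fp <- estimate_fields(ens, pot_flat(), ens$params,
                          x_edges = seq(-1, 1, length.out = 6),
                          min_count = 50)
    sqrt(mean((fp$T[!fp$masked] - theta0)^2))
  }
  e_small <- mean(sapply(1:4, function(s) err_at(160, s)))
  e_large <- mean(sapply(1:4, function(s) err_at(16000, s + 10)))
  ratio <- e_small / e_large       # expect ~ sqrt(100) = 10
  expect_gt(ratio, 4)
  expect_lt(ratio, 25)
})

test_that("hydrodynamic balance residuals vanish for a stationary state", {
  # three identical copies of an exact stationary profile -> residuals ~ 0
  p <- gcn_params(tau = 0.2)
  d <- solve_kramers(pot_double_well(), p, kramers_grid(nx = 97, nv = 40, L = 3.2))
  pr <- kramers_profile(d)
  fp <- data.frame(x = pr$x, n = pr$n, u = pr$u, msv = pr$msv,
                   j_q = 0 * pr$n)  # odd moments ~ 0 in steady state
  # j_q from solver third moment
  fp$j_q <- (d$m3 - 3 * d$u * d$n * d$msv + 2 * d$n * d$u^3) / 2 * p$v_T^3 / p$length_scale
  fps <- list(fp, fp, fp)
  res <- hydro_residuals(fps, times = c(0, 1, 2), pot_double_well(), p)
  # time derivatives are exactly zero; gradient terms cancel to FD accuracy
  interior <- !is.na(res$momentum[1, ])
  scale <- max(abs(pr$n * pr$msv)) / p$tau
  # time derivatives vanish exactly; the rest is central-difference
  # truncation of the spatial gradients on the 97-point grid
  expect_lt(max(abs(res$continuity[1, interior])), 1e-6 * scale)
  expect_lt(max(abs(res$momentum[1, interior])), 2e-2 * scale)
  expect_lt(max(abs(res$energy[1, interior])), 5e-2 * scale)
})

test_that("continuity residual of a relaxing solver transient shrinks with the time step", {
  # spatial moments are near-exact (spectral), so the residual of the
  # recorded transient is dominated by the O(dt) time discretization
  p <- gcn_params(tau = 0.2)
  res_norm <- function(dt) {
    mm <- kramers_march(pot_double_well(), p,
                        kramers_grid(nx = 97, nv = 24, L = 3.2),
                        init = function(X, V) exp(-4 * X^2 - V^2),
                        dt = dt, n_steps = 6, record_every = 1)
    prof <- lapply(mm$snapshots, function(d) {
      pr <- kramers_profile(d)
      data.frame(x = pr$x, n = pr$n, u = pr$u, msv = pr$msv, j_q = 0 * pr$n)
    })
    r <- hydro_residuals(prof, mm$times, pot_double_well(), p)
    max(abs(r$continuity), na.rm = TRUE)
  }
  r1 <- res_norm(0.02)
  r2 <- res_norm(0.01)
  expect_lt(r2, r1 / 1.4)
})

test_that("profile CSV serialization round-trips", {
  fx <- make_fixture("harmonic_exact", seed = 3, n = 128)
  fp <- estimate_fields(fx, pot_harmonic(1), fx$params,
                        x_edges = seq(-2, 2, length.out = 21), min_count = 20)
  f <- tempfile(fileext = ".csv")
  write_profile_csv(fp, f)
  back <- read_profile_csv(f)
  expect_equal(back$n, fp$n, tolerance = 1e-12)
  expect_equal(back$msv, fp$msv, tolerance = 1e-12)
  unlink(f)
})
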