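test_that("flat potential: exact global Maxwellian with unit temperature", {
  d <- kramers_steady_matrix()$flat
  expect_lt(d$residual, 1e-8)
  expect_lt(diff(range(d$n)), 1e-8)
  expect_lt(max(abs(d$msv - 1)), 1e-8)        # nondimensional T_b = 1
  expect_equal(sum(d$n) * d$dx, 1, tolerance = 1e-10)
  cur <- kramers_currents(d)
  expect_identical(max(abs(cur$I_x_D)), 0)
  expect_lt(max(abs(cur$I_v_D)), 1e-8)
})

test_that("harmonic potential: detailed balance to spectral accuracy", {
  d <- kramers_steady_matrix()$harmonic
  p <- d$params; k <- 1
  expect_lt(d$residual, 1e-10)
  # closed-form covariances (nondimensional): Var(X) and <V^2>
  g0 <- 1 + p$tau * k / p$gamma
  varX <- gcntherm:::trapz(d$X, d$X^2 * d$n)
  expect_equal(varX, p$D * p$gamma / k / g0, tolerance = 1e-6)
  bulk <- d$n > 1e-3 * max(d$n)   # msv is a ratio: mask noise-floor tails
  expect_lt(max(abs(d$msv - 1 / g0)[bulk]), 1e-8)
  cur <- kramers_currents(d)
  expect_lt(max(abs(cur$I_v_D)), 1e-8)
  eb <- kramers_entropy_budget(d)
  expect_lt(abs(eb$S_irr_rate), 1e-8)
  expect_lt(abs(eb$S_m_rate), 1e-8)
})

test_that("linear potential: the Boltzmann-form state is dissipation-free", {
  # detailed-balance state e^{-g0 U(X)} x Maxwellian evaluated through the
  # current decomposition (velocity-space functionals are wrap-independent)
  p <- gcn_params(tau = 0.5)
  g0 <- 1                                   # w'' = 0
  st <- kramers_state(pot_linear(1), p, kramers_grid(nx = 97, nv = 40, L = 3),
                      function(X, V) exp(-g0 * (X + V^2 / 2)))
  cur <- kramers_currents(st)
  expect_lt(max(abs(cur$I_v_D)), 1e-8)
  eb <- kramers_entropy_budget(st)
  expect_lt(abs(eb$S_irr_rate), 1e-8)
})

test_that("double well at tau = 0.7: non-equilibrium steady-state structure", {
  d <- double_well_steady()
  expect_lt(d$residual, 1e-8)
  expect_lt(d$boundary_mass, 1e-8)
  expect_equal(sum(d$n) * d$dx, 1, tolerance = 1e-10)
  # positivity of the spectral reconstruction (no clipping applied)
  rec <- gcntherm:::kramers_reconstruct(d)
  expect_gt(min(rec$P), -1e-8 * max(rec$P))
  expect_true(min(d$n) > -1e-10)
  # bimodal density with modes near +-1
  i0 <- which.min(abs(d$X)); i1 <- which.min(abs(d$X - 1))
  expect_gt(d$n[i1], 2 * d$n[i0])
  # theta - <V^2>_X crosses from positive (barrier) to negative (wells)
  theta <- 1 / d$g
  expect_gt((theta - d$msv)[i0], 0)
  expect_lt((theta - d$msv)[i1], 0)
  # qdot positive at the barrier, negative in the wells, near-zero total
  expect_gt(d$qdot[i0], 0)
  expect_lt(d$qdot[i1], 0)
  expect_lt(abs(sum(d$qdot) * d$dx), 1e-4)
})

test_that("entropy budget: S_irr >= 0 and balances -S_m in steady state", {
  mat <- kramers_steady_matrix()
  for (nm in names(mat)) {
    eb <- kramers_entropy_budget(mat[[nm]])
    expect_gte(eb$S_irr_rate, 0)
    expect_lt(abs(eb$dS_dt), 1e-6)
  }
  eb02 <- kramers_entropy_budget(mat$dw_tau02, xi = seq(-9, 9, length.out = 601),
                                 floor = 1e-14)
  expect_lt(abs(eb02$S_irr_rate + eb02$S_m_rate) / abs(eb02$S_m_rate), 1e-6)
  eb07 <- kramers_entropy_budget(mat$dw_tau07)
  expect_lt(abs(eb07$S_irr_rate + eb07$S_m_rate) / abs(eb07$S_m_rate), 1e-3)
  expect_lt(eb07$S_m_rate, 0)
  expect_gt(eb07$S_irr_rate, 0)
})

test_that("energy balance: steady states are stationary, transients obey dE/dt = Qdot", {
  for (d in kramers_steady_matrix()[c("flat", "harmonic", "dw_tau07")]) {
    er <- kramers_energy_rates(d)
    expect_lt(abs(er$dE_dt), 1e-8)
  }
  # double well: total heat ~ 0 while local qdot is sign-varying
  d <- double_well_steady()
  er <- kramers_energy_rates(d)
  expect_lt(abs(er$Q_rate), 1e-4)
  expect_gt(max(d$qdot), 0.05)
  expect_lt(min(d$qdot), -0.05)
  # flat-potential transient from a squeezed Gaussian: no work, so the
  # energy balance dE/dt = Q_rate holds at every recorded step
  p <- gcn_params(tau = 0.5)
  mm <- kramers_march(pot_flat(), p, kramers_grid(nx = 33, nv = 96, L = 1.5),
                      init = function(X, V) exp(-V^2 / 0.8),
                      dt = 0.02, n_steps = 30, record_every = 5)
  for (snap in mm$snapshots) {
    er <- kramers_energy_rates(snap)
    expect_equal(er$dE_dt, er$Q_rate, tolerance = 1e-8)
  }
})

test_that("time marching conserves mass and relaxes toward the steady state", {
  p <- gcn_params(tau = 0.2)
  mm <- kramers_march(pot_double_well(), p,
                      kramers_grid(nx = 97, nv = 40, L = 3.2),
                      dt = 0.05, n_steps = 200, record_every = 200)
  final <- mm$snapshots[[length(mm$snapshots)]]
  expect_lt(abs(sum(final$n) * final$dx - 1), 1e-12)
  d <- kramers_steady_matrix()$dw_tau02
  expect_lt(max(abs(final$n - d$n)), 1e-3)
  # discrete mass conservation on a resolved state: the generator leaks
  # mass only through truncation tails, < 1e-12 per unit time
  op <- gcntherm:::kramers_operator(pot_double_well(), p,
                                    kramers_grid(nx = 97, nv = 40, L = 3.2))
  mass <- as.vector(outer(sqrt(op$geo$s) * op$geo$dx, op$hb$mu))
  cvec <- gcntherm:::B_to_coef(rbind(exp(-op$geo$U), matrix(0, 39, 97)))
  cvec <- cvec / sum(mass * cvec)
  expect_lt(abs(sum(mass * as.numeric(op$A %*% cvec))), 1e-12)
})

test_that("divergence of the total current balances dP/dt on constant-scale grids", {
  # finite-difference check, independent of the spectral machinery
  d <- kramers_steady_matrix()$harmonic
  cur <- kramers_currents(d, xi = seq(-6, 6, length.out = 201))
  expect_lt(diff(range(d$s)), 1e-14)          # constant basis scale
  s <- d$s[1]; dxi <- cur$xi[2] - cur$xi[1]
  Iv <- cur$I_v_R + cur$I_v_D
  div_v <- (Iv[, -(1:2)] - Iv[, -(200:201)]) / (2 * dxi * s)
  Ix <- cur$I_x_R
  div_x <- (Ix[-(1:2), ] - Ix[-(96:97), ]) / (2 * d$dx)
  tot <- div_x[, 2:200] + div_v[2:96, ]
  # steady state: the two FD divergence pieces cancel to truncation order,
  # though each is individually large (a genuine, non-trivial cancellation)
  expect_lt(max(abs(tot)), 1e-2 * max(abs(div_x)))
  expect_gt(max(abs(div_v)), 0.1 * max(abs(div_x)))
})

test_that("solver cross-checks the perturbative expansion at large zeta", {
  d <- zeta_solution(8)
  st <- msv_expansion(pot_double_well(), d$params, d$X)
  w <- abs(d$X) <= 1.5
  # order-4 truncation beats the order-2 (UCNA) truncation
  e4 <- max(abs(d$msv - st$msv_order4)[w])
  e2 <- max(abs(d$msv - st$msv_order2)[w])
  expect_lt(e4, e2 / 2)
  expect_lt(e4, 5e-4)
})
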