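test_that("UCNA density: uniform for flat, closed-form Gaussian for harmonic", {
  p <- gcn_params(tau = 0.5)
  xg <- seq(-1, 1, length.out = 201)
  df <- ucna_density(pot_flat(), p, xg)
  expect_lt(diff(range(df$density)), 1e-12)
  expect_equal(gcntherm:::trapz(xg, df$density), 1, tolerance = 1e-10)

  k <- 2
  xh <- seq(-5, 5, length.out = 2001)
  dh <- ucna_density(pot_harmonic(k), p, xh)
  v_target <- p$D * p$gamma / k / (1 + p$tau * k / p$gamma)
  v_est <- gcntherm:::trapz(xh, xh^2 * dh$density)
  expect_equal(v_est, v_target, tolerance = 1e-8)
  expect_equal(gcntherm:::trapz(xh, dh$density), 1, tolerance = 1e-10)
})

test_that("UCNA density satisfies the hydrostatic balance d(n theta)/dx = n f/(tau gamma)", {
  p <- gcn_params(tau = 0.7)
  pot <- pot_double_well()
  xg <- seq(-2.5, 2.5, length.out = 4001)
  d <- ucna_density(pot, p, xg)
  theta <- p$T_b / gamma_factor(pot, xg, p)
  ntheta <- d$density * theta
  h <- xg[2] - xg[1]
  lhs <- (ntheta[3:4001] - ntheta[1:3999]) / (2 * h)
  rhs <- (d$density * (-pot$dw(xg)) / (p$tau * p$gamma))[2:4000]
  # central-difference truncation only: O(h^2) ~ 1e-6 relative
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-5)
})

test_that("Fox generator: UCNA-identical stationary state, Smoluchowski limit", {
  p <- gcn_params(tau = 0.7)
  pot <- pot_double_well()
  xg <- seq(-2.5, 2.5, length.out = 2001)
  du <- ucna_density(pot, p, xg)
  df <- fox_stationary(pot, p, xg)
  expect_lt(max(abs(du$density - df$density)), 1e-8)

  p0 <- gcn_params(tau = 1e-9)
  fx <- fox_generator(pot, p0, xg)
  expect_equal(fx$drift, -pot$dw(xg) / p0$gamma)
  expect_equal(fx$diffusion, rep(p0$D, length(xg)), tolerance = 1e-7)

  # harmonic stationary variance agrees with the UCNA/Langevin closed form
  k <- 1.5; ph <- gcn_params(tau = 0.4)
  xh <- seq(-5, 5, length.out = 2001)
  dfh <- fox_stationary(pot_harmonic(k), ph, xh)
  expect_equal(gcntherm:::trapz(xh, xh^2 * dfh$density),
               ph$D * ph$gamma / k / (1 + ph$tau * k / ph$gamma),
               tolerance = 1e-7)
})

test_that("tau -> 0 recovers Boltzmann statistics", {
  p0 <- gcn_params(tau = 1e-10)
  pot <- pot_double_well()
  xg <- seq(-2.5, 2.5, length.out = 1001)
  d <- ucna_density(pot, p0, xg)
  boltz <- exp(-pot$w(xg) / (p0$D * p0$gamma))
  boltz <- boltz / gcntherm:::trapz(xg, boltz)
  expect_equal(d$density, boltz, tolerance = 1e-8)
})

test_that("local Maxwellian: normalized columns, variance theta, zero skew", {
  p <- gcn_params(tau = 0.7)
  pot <- pot_double_well()
  xg <- seq(-2, 2, length.out = 81)
  lm <- local_maxwellian(pot, p, ucna_density(pot, p, xg))
  dv <- lm$v[2] - lm$v[1]
  dens <- rowSums(lm$P) * dv
  i0 <- which.min(abs(xg))
  col <- lm$P[i0, ] / dens[i0]
  expect_equal(sum(col) * dv, 1, tolerance = 1e-10)
  expect_equal(sum(col * lm$v^2) * dv, 1 / (0.7 * 0.3), tolerance = 1e-7)
  expect_lt(abs(sum(col * lm$v^3) * dv), 1e-10)
  # flat potential: x-independent global Maxwellian at T_b
  lmf <- local_maxwellian(pot_flat(), p,
                          ucna_density(pot_flat(), p, seq(-1, 1, length.out = 11)))
  expect_lt(max(abs(sweep(lmf$P, 2, lmf$P[1, ], "-"))), 1e-12)
})

test_that("detailed balance holds exactly iff the curvature is constant", {
  p <- gcn_params(tau = 0.7)
  expect_identical(detailed_balance_diagnostic(pot_harmonic(3), p)$status, "exact")
  expect_identical(detailed_balance_diagnostic(pot_linear(2), p)$status, "exact")
  expect_identical(detailed_balance_diagnostic(pot_flat(), p)$status, "exact")
  db <- detailed_balance_diagnostic(pot_double_well(), p)
  expect_identical(db$status, "violated")
  expect_gt(db$g_variation, 0.1)
})

test_that("order-2 expansion equals the UCNA temperature on every potential", {
  X <- seq(-2, 2, length.out = 101)
  for (pot in list(pot_flat(), pot_linear(1), pot_harmonic(2), pot_double_well())) {
    p <- gcn_params(tau = 1 / 16)
    st <- msv_expansion(pot, p, X)
    expect_equal(st$msv_order2, 1 / st$g)
    expect_equal(st$delta, st$msv_order2 - st$msv_order4)
  }
})

test_that("the zeta^-4 remainder vanishes exactly for harmonic and linear wells", {
  X <- seq(-3, 3, length.out = 61)
  p <- gcn_params(tau = 1 / 16)
  for (pot in list(pot_harmonic(2.3), pot_linear(1.7), pot_flat())) {
    st <- msv_expansion(pot, p, X)
    expect_equal(st$R, rep(0, length(X)))
    expect_equal(st$msv_order4, st$msv_order2)
  }
  expect_warning(msv_expansion(pot_double_well(), gcn_params(tau = 0.9),
                               X), "untrustworthy")
})

test_that("quartic worked example matches the generic path bit-for-bit", {
  X <- seq(-2.2, 2.2, length.out = 101)
  q <- quartic_worked_example(zeta = 4, X_grid = X)
  expect_lt(max(abs(q$msv - q$msv_generic)), 1e-14)
  expect_lt(max(abs(q$delta - q$delta_generic)), 1e-14)
  # positive near the origin, negative beyond X* = sqrt((1+sqrt(5))/2)
  xstar <- sqrt((1 + sqrt(5)) / 2)
  expect_true(all(q$delta[abs(X) < xstar - 0.05] > 0))
  expect_true(all(q$delta[abs(X) > xstar + 0.05] < 0))
  # equilibrium limit: Delta -> 0 uniformly as zeta -> infinity
  q2 <- quartic_worked_example(zeta = 1e4, X_grid = X)
  expect_lt(max(abs(q2$delta)), 1e-14)
})

test_that("perturbative entropy production: zero for harmonic, negative and ~zeta^-5 for the quartic", {
  X <- seq(-3.3, 3.3, length.out = 801)
  p <- gcn_params(tau = 1 / 16)
  expect_identical(perturbative_entropy_production(pot_harmonic(1), p, X)$S_m, 0)
  pe <- perturbative_entropy_production(pot_double_well(), p, X,
                                        zetas = c(4, 8, 16))
  expect_lt(pe$S_m, 0)
  expect_true(all(pe$by_zeta$S_m < 0))
  # Boltzmann average of R vanishes by parts, so the decay is zeta^-5
  expect_lt(abs(pe$scaling_exponent + 5), 0.15)
})

test_that("UCNA phase-space ansatz carries zero dissipation through the estimators", {
  p <- gcn_params(tau = 0.7)
  pot <- pot_double_well()
  xg <- seq(-2.2, 2.2, length.out = 201)
  lm <- local_maxwellian(pot, p, ucna_density(pot, p, xg))
  gp <- entropy_flux_density(grid_profile(lm$P, lm$x, lm$v, pot, p))
  ok <- !gp$masked
  expect_lt(max(abs(gp$qdot[ok])), 1e-6)
  expect_lt(max(abs(gp$sigma_m[ok])), 1e-6)
  expect_lt(max(abs(gp$j_q[ok])), 1e-10)
})
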