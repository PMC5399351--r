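#' Grid specification for the Kramers solver
#'
#' The solver discretizes the dimensionless Kramers equation
#' \deqn{\partial_{\bar t} P + V\partial_X P + F(X)\partial_V P
#'   = \zeta\,\partial_V\!\bigl[g(X)VP + \partial_V P\bigr]}
#' with Fourier collocation in `X` (periodic on `[-L, L)`, odd point count:
#' the even-count Fourier differentiation matrix has a spurious sawtooth
#' null mode) and an orthonormal Hermite-function basis in `V` whose scale
#' follows the local bath temperature, `s(X)^2 = alpha / max(|g(X)|,
#' g_floor)`.  Streaming is discretely skew-symmetric and the collision
#' term dissipative, so the discretization is stable and, for spatially
#' constant `g` (flat/linear/harmonic potentials), reproduces the
#' detailed-balance steady state to spectral accuracy.
#'
#' @param nx number of Fourier collocation points (forced odd).
#' @param nv number of Hermite modes.  The narrower the local velocity
#'   distribution relative to the widest one, the more modes are needed;
#'   the defaults resolve the double-well showcase at `tau = 0.7`.
#' @param L half-width of the periodic position domain; default
#'   `1.5 * max(|domain_hint|)` of the potential.  Must be large enough
#'   that the density is negligible at `|X| = L` (monitored via
#'   `boundary_mass`).
#' @param alpha velocity-scale safety factor.
#' @param g_floor floor on `|g|` used in the scale (keeps the basis finite
#'   where the friction factor crosses zero).
#' @return List of class `kramers_grid`.
#' @export
kramers_grid <- function(nx = 161, nv = 80, L = NULL, alpha = 1.3,
                         g_floor = 0.05) {
  nx <- as.integer(nx); if (nx %% 2L == 0L) nx <- nx + 1L
  structure(list(nx = nx, nv = as.integer(nv), L = L, alpha = alpha,
                 g_floor = g_floor), class = "kramers_grid")
}

# odd-N Fourier spectral differentiation matrix on [-L, L)
fourier_diff_matrix <- function(N, L) {
  h <- 2 * pi / N
  K <- outer(seq_len(N), seq_len(N), "-")
  D <- 0.5 * (-1)^K / sin(K * h / 2)
  D[K == 0] <- 0
  D * (pi / L)
}

# Orthonormal Hermite-function (physicists', weight e^{-xi^2/2}) operator
# matrices: Xi = multiplication by xi, Dxi = d/dxi, Sh = scale-coupling,
# mu = integrals of the basis functions.
hermite_basis <- function(nv) {
  Xi <- matrix(0, nv, nv); Dxi <- matrix(0, nv, nv); Sh <- matrix(0, nv, nv)
  for (nn in seq_len(nv)) {        # nn = math index n + 1
    n <- nn - 1
    if (nn > 1) { Xi[nn - 1, nn] <- sqrt(n / 2); Dxi[nn - 1, nn] <- sqrt(n / 2) }
    if (nn < nv) { Xi[nn + 1, nn] <- sqrt((n + 1) / 2); Dxi[nn + 1, nn] <- -sqrt((n + 1) / 2) }
    if (nn > 2)      Sh[nn - 2, nn] <- -sqrt(n * (n - 1)) / 2
    if (nn + 2 <= nv) Sh[nn + 2, nn] <- sqrt((n + 1) * (n + 2)) / 2
  }
  # mu_n = int h_n(xi) dxi ; I_{n+1} = 2 n I_{n-1}, I_0 = sqrt(2 pi)
  logI <- rep(-Inf, nv); logI[1] <- 0.5 * log(2 * pi)
  if (nv > 2) for (nn in seq(3, nv, by = 2)) {
    logI[nn] <- logI[nn - 2] + log(2 * (nn - 2))
  }
  n <- seq_len(nv) - 1
  mu <- exp(logI - 0.5 * (n * log(2) + lgamma(n + 1) + 0.5 * log(pi)))
  list(Xi = Xi, Dxi = Dxi, Sh = Sh, mu = mu)
}

# pointwise values h_n(xi) for n = 0..nv-1 (rows: xi, cols: n)
hermite_eval <- function(nv, xi) {
  H <- matrix(0, length(xi), nv)
  H[, 1] <- pi^(-1 / 4) * exp(-xi^2 / 2)
  if (nv > 1) H[, 2] <- sqrt(2) * xi * H[, 1]
  if (nv > 2) for (nn in 3:nv) {
    n <- nn - 2  # h_{n+1} = xi sqrt(2/(n+1)) h_n - sqrt(n/(n+1)) h_{n-1}
    H[, nn] <- xi * sqrt(2 / (n + 1)) * H[, nn - 1] - sqrt(n / (n + 1)) * H[, nn - 2]
  }
  H
}

# geometry + model fields shared by operator assembly and post-processing
kramers_geometry <- function(pot, params, grid) {
  L <- grid$L %||% (1.5 * max(abs(pot$domain_hint)))
  nx <- grid$nx
  X <- -L + 2 * L * (seq_len(nx) - 1) / nx
  nd <- nondimensionalize(params, pot)
  g <- nd$g(X); gp <- nd$Uppp(X) / params$zeta^2
  ga <- pmax(abs(g), grid$g_floor)
  s <- sqrt(grid$alpha / ga)
  sp <- ifelse(abs(g) > grid$g_floor, -s * gp / (2 * g), 0)
  list(X = X, dx = 2 * L / nx, L = L, g = g, s = s, sp = sp,
       U = nd$U(X), F = nd$F(X), zeta = params$zeta, nd = nd)
}

# Sparse generator A such that dP/dt = A c in coefficient space.
# Unknown ordering is position-fastest (index = (n_mode - 1) * nx + i): the
# Hermite couplings reach only n +/- 3, so the matrix is banded (bandwidth
# ~ 3 nx) and the natural-order sparse LU stays fill-free enough to be fast.
kramers_operator <- function(pot, params, grid) {
  geo <- kramers_geometry(pot, params, grid)
  nx <- grid$nx; nv <- grid$nv; N <- nx * nv
  hb <- hermite_basis(nv)
  zeta <- geo$zeta

  trip <- function(M) {
    idx <- which(M != 0, arr.ind = TRUE)
    list(r = idx[, 1], c = idx[, 2], v = M[idx])
  }
  blocks <- list(
    list(M = trip(hb$Xi %*% hb$Sh),  coef = -geo$sp),
    list(M = trip(hb$Dxi),           coef = -geo$F / geo$s),
    list(M = trip(hb$Dxi %*% hb$Xi), coef = zeta * geo$g),
    list(M = trip(hb$Dxi %*% hb$Dxi), coef = zeta / geo$s^2))
  ri <- ci <- vi <- vector("list", length(blocks) + 1)
  ix <- seq_len(nx)
  for (b in seq_along(blocks)) {
    tr <- blocks[[b]]$M; nb <- length(tr$r)
    ri[[b]] <- rep((tr$r - 1) * nx, each = nx) + rep(ix, times = nb)
    ci[[b]] <- rep((tr$c - 1) * nx, each = nx) + rep(ix, times = nb)
    vi[[b]] <- rep(tr$v, each = nx) * rep(blocks[[b]]$coef, times = nb)
  }
  # advection -Dx[i,k] * s_i * Xi
  Dx <- fourier_diff_matrix(nx, geo$L)
  nzd <- which(Dx != 0, arr.ind = TRUE)
  dvv <- Dx[nzd]; ii <- nzd[, 1]; kk <- nzd[, 2]; ndx <- length(ii)
  tx <- trip(hb$Xi); nb <- length(tx$r)
  last <- length(blocks) + 1
  ri[[last]] <- rep((tx$r - 1) * nx, each = ndx) + rep(ii, times = nb)
  ci[[last]] <- rep((tx$c - 1) * nx, each = ndx) + rep(kk, times = nb)
  vi[[last]] <- rep(tx$v, each = ndx) * rep(-dvv * geo$s[ii], times = nb)

  A <- Matrix::sparseMatrix(i = unlist(ri), j = unlist(ci), x = unlist(vi),
                            dims = c(N, N), repr = "C")
  list(A = A, geo = geo, hb = hb, nx = nx, nv = nv)
}

# coefficient vector (position-fastest) <-> mode x position matrix
coef_to_B <- function(cvec, nx, nv) t(matrix(cvec, nx, nv))
B_to_coef <- function(B) as.vector(t(B))

#' Steady state of the Kramers equation
#'
#' Solves the dimensionless stationary Kramers equation of the GCN model
#' (see [kramers_grid()] for the discretization).  The default method
#' replaces one row of the singular generator with the mass constraint and
#' solves the sparse linear system directly; `method = "march"` runs
#' implicit-Euler pseudo-time iterations from a local-Maxwellian guess
#' instead (robust fallback; factors once, reuses).
#'
#' Exact moment relations of the basis give the density `n(X)`, mean
#' velocity, local kinetic temperature \eqn{\langle V^2\rangle_X}, the
#' heat-flux density \eqn{\dot q(X) = \zeta n(X)[1 - g(X)\langle
#' V^2\rangle_X]} and entropy-flux density \eqn{\sigma_m = g\,\dot q}
#' without velocity-quadrature error.
#'
#' All returned quantities are dimensionless; [kramers_profile()] converts
#' to the dimensional units of the Langevin side.
#'
#' @param pot a [potential()]; `Gamma < 0` regions are admissible (only the
#'   basis scale is floored, see [kramers_grid()]).
#' @param params a [gcn_params()].
#' @param grid a [kramers_grid()].
#' @param method `"direct"` (default) or `"march"`.
#' @param march_dt,march_steps implicit-Euler settings for `"march"`.
#' @return A `grid_distribution`: coefficients, geometry, exact moments
#'   (`n`, `u`, `msv`, `qdot`, `sigma_m`), the stationarity residual
#'   `residual` (L1 norm of \eqn{\partial_t P}) and `boundary_mass`.
#' @export
solve_kramers <- function(pot, params, grid = kramers_grid(),
                          method = c("direct", "march"),
                          march_dt = 5, march_steps = 400) {
  method <- match.arg(method)
  op <- kramers_operator(pot, params, grid)
  geo <- op$geo; nx <- op$nx; nv <- op$nv; N <- nx * nv
  # mass functional: all even Hermite modes contribute to int P dV
  mass_full <- as.vector(outer(sqrt(geo$s) * geo$dx, op$hb$mu))

  if (method == "direct") {
    r <- which.min(abs(geo$X))          # mode-0 row at the domain center
    A2 <- op$A
    A2[r, ] <- mass_full
    b <- rep(0, N); b[r] <- 1
    cvec <- as.numeric(Matrix::solve(Matrix::lu(A2, order = 0L), b))
  } else {
    M <- Matrix::Diagonal(N) - march_dt * op$A
    Mf <- Matrix::lu(M, order = 0L)
    # local-Maxwellian-at-basis-scale initial guess: n0 ~ exp(-U) in mode 0
    cmat <- matrix(0, nv, nx)
    cmat[1, ] <- exp(-(geo$U - min(geo$U)))
    cvec <- B_to_coef(cmat)
    for (it in seq_len(march_steps)) {
      cvec <- as.numeric(Matrix::solve(Mf, cvec))
      cvec <- cvec / sum(mass_full * cvec)
    }
  }
  cvec <- cvec / sum(mass_full * cvec)
  resid_coeff <- as.numeric(op$A %*% cvec)

  dist <- build_grid_distribution(cvec, resid_coeff, op, pot, params, grid)
  dist
}

# assemble the user-facing object from solved coefficients
build_grid_distribution <- function(cvec, resid_coeff, op, pot, params, grid) {
  geo <- op$geo; nx <- op$nx; nv <- op$nv
  B <- coef_to_B(cvec, nx, nv)         # mode x position
  mu <- op$hb$mu; Xi <- op$hb$Xi
  t1 <- Xi %*% mu; t2 <- Xi %*% t1; t3 <- Xi %*% t2
  mom <- function(tk, k) sqrt(geo$s) * geo$s^k * as.numeric(crossprod(tk, B))
  n <- mom(mu, 0); nu <- mom(t1, 1); nv2 <- mom(t2, 2); nv3 <- mom(t3, 3)
  qdot <- geo$zeta * (n - geo$g * nv2)
  Rmat <- coef_to_B(resid_coeff, nx, nv)
  # L1 norm of dP/dt: integrate |dP/dt| pointwise on a xi grid
  xi <- seq(-7, 7, length.out = 241)
  H <- hermite_eval(nv, xi)
  dPdt <- H %*% Rmat                  # values at (xi, X)
  resid_l1 <- sum(t(abs(dPdt)) * (geo$s * (xi[2] - xi[1]))) * geo$dx
  structure(list(
    X = geo$X, dx = geo$dx, s = geo$s, g = geo$g, U = geo$U, F = geo$F,
    zeta = geo$zeta, coef = B, resid_coeff = Rmat,
    n = n, u = nu / n, msv = nv2 / n, m3 = nv3,
    qdot = qdot, sigma_m = geo$g * qdot,
    residual = resid_l1,
    boundary_mass = (n[1] + n[length(n)]) * geo$dx,
    params = params, potential = pot$name, grid = grid,
    hb = op$hb), class = "grid_distribution")
}

#' @export
print.grid_distribution <- function(x, ...) {
  cat(sprintf("<grid_distribution> %s | %d x-points x %d Hermite modes | residual %.2e | boundary mass %.1e\n",
              x$potential, length(x$X), nrow(x$coef), x$residual, x$boundary_mass))
  invisible(x)
}

# pointwise reconstruction of P (and optionally another coefficient field)
# on (X, xi) grid; V = s(X) * xi
kramers_reconstruct <- function(dist, coef = dist$coef,
                                xi = seq(-7, 7, length.out = 241)) {
  H <- hermite_eval(nrow(coef), xi)
  vals <- H %*% coef                    # (xi, X); psi_n = h_n / sqrt(s)
  vals <- sweep(vals, 2, sqrt(dist$s), "/")
  list(xi = xi, P = t(vals),            # (X, xi)
       V = outer(dist$s, xi), dxi = xi[2] - xi[1])
}

#' Phase-space probability currents of a solved distribution
#'
#' Decomposes the Kramers flux into its reversible (streaming) and
#' dissipative parts,
#' \deqn{I_x^R = VP,\quad I_v^R = F(X)P,\quad
#'       I_v^D = -\zeta\,[g(X)VP + \partial_V P],\quad I_x^D = 0,}
#' evaluated pointwise on the reconstruction grid.  The divergence of the
#' total current equals \eqn{-\partial_t P}, which for a solved steady
#' state is the (small) stationarity residual; it is returned as `div` so
#' the discrete identity can be checked directly.  Detailed balance means
#' \eqn{I_v^D \equiv 0}: true for spatially constant `g` only.
#'
#' @param dist a `grid_distribution` from [solve_kramers()].
#' @param xi dimensionless velocity grid (in units of the local basis
#'   scale `s(X)`; the physical velocity at `(i, q)` is `V[i, q] =
#'   s(X_i) xi_q`).
#' @return List with matrices (`length(X)` x `length(xi)`) `P`, `I_x_R`,
#'   `I_v_R`, `I_v_D`, `I_x_D`, `div`, and the grids.
#' @export
kramers_currents <- function(dist, xi = seq(-7, 7, length.out = 241)) {
  rec <- kramers_reconstruct(dist, xi = xi)
  # I_v^D coefficients: -zeta (g_i Vm_i + Dv_i) B_i
  nv <- nrow(dist$coef); nx <- length(dist$X)
  hbXi <- dist$hb$Xi; hbD <- dist$hb$Dxi
  Gc <- matrix(0, nv, nx)
  for (i in seq_len(nx)) {
    Gc[, i] <- -dist$zeta *
      ((dist$g[i] * dist$s[i]) * (hbXi %*% dist$coef[, i]) +
         (hbD %*% dist$coef[, i]) / dist$s[i])
  }
  recG <- kramers_reconstruct(dist, coef = Gc, xi = xi)
  recR <- kramers_reconstruct(dist, coef = dist$resid_coeff, xi = xi)
  list(X = dist$X, xi = xi, V = rec$V, P = rec$P,
       I_x_R = rec$V * rec$P,
       I_v_R = sweep(rec$P, 1, dist$F, "*"),
       I_x_D = 0 * rec$P,
       I_v_D = recG$P,
       div = -recR$P)
}

#' Entropy budget of a phase-space distribution
#'
#' Gibbs entropy \eqn{s = -\int P\log P}, its instantaneous rate
#' \eqn{ds/dt} (from the generator residual), the always-non-negative
#' entropy production rate
#' \deqn{\dot S_{irr} = \zeta\int \frac{[g V P + \partial_V P]^2}{P}\,dX\,dV
#'   \ \ge 0,}
#' and the medium entropy flux
#' \eqn{\dot S_m = \int g(X)\,\dot q(X)\,dX} (exact moment expression).
#' The balance \eqn{ds/dt = \dot S_{irr} + \dot S_m} holds; in a steady
#' state \eqn{ds/dt \approx 0} so \eqn{\dot S_{irr} \approx -\dot S_m}:
#' entropy produced in the system is exported to the active bath, and the
#' generalized Clausius inequality \eqn{\dot S_m \le 0} follows.
#'
#' Cells with `P` below `floor` (relative to the maximum) are dropped from
#' the logarithmic integrals.
#'
#' @param dist a `grid_distribution`.
#' @param xi velocity quadrature grid.
#' @param floor relative floor for log-integrals.
#' @return List `S_gibbs`, `dS_dt`, `S_irr_rate`, `S_m_rate`.
#' @export
kramers_entropy_budget <- function(dist, xi = seq(-7, 7, length.out = 321),
                                   floor = 1e-13) {
  cur <- kramers_currents(dist, xi = xi)
  P <- cur$P
  keep <- P > floor * max(P)
  wx <- dist$dx; dxi <- xi[2] - xi[1]
  wcell <- outer(dist$s, rep(dxi, length(xi))) * wx   # dV dx per cell
  Pk <- P[keep]; wk <- wcell[keep]; logPk <- log(Pk)
  S_g <- -sum(Pk * logPk * wk)
  G <- -cur$I_v_D / dist$zeta                 # g V P + dP/dV
  S_irr <- dist$zeta * sum((G[keep]^2 / Pk) * wk)
  S_m <- sum(dist$g * dist$qdot) * wx
  dS <- -sum((1 + logPk) * (-cur$div[keep]) * wk)
  list(S_gibbs = S_g, dS_dt = dS, S_irr_rate = S_irr, S_m_rate = S_m)
}

#' Mean energy, work and heat rates
#'
#' For the dimensionless phase-space energy \eqn{E = V^2/2 + U(X)}:
#' `E_mean` is its expectation, `dE_dt` its instantaneous rate of change
#' under the generator, `W_rate` the external work rate (zero: only
#' time-independent potentials are supported) and `Q_rate` the total heat
#' rate \eqn{\int\dot q(X)\,dX} absorbed from the active bath.  The first
#' law here reads \eqn{dE/dt = \dot W + \dot Q}; in a steady state both
#' sides vanish even though the local \eqn{\dot q(x)} is sign-varying.
#'
#' @param dist a `grid_distribution` (steady or a [kramers_march()]
#'   snapshot).
#' @return List `E_mean`, `dE_dt`, `W_rate`, `Q_rate`.
#' @export
kramers_energy_rates <- function(dist) {
  mu <- dist$hb$mu; Xi <- dist$hb$Xi
  t2 <- Xi %*% (Xi %*% mu)
  momc <- function(coefs, tk, k)
    sqrt(dist$s) * dist$s^k * as.numeric(crossprod(tk, coefs))
  nE <- momc(dist$coef, t2, 2) / 2 + dist$U * momc(dist$coef, mu, 0)
  E_mean <- sum(nE) * dist$dx
  rE <- momc(dist$resid_coeff, t2, 2) / 2 + dist$U * momc(dist$resid_coeff, mu, 0)
  dE_dt <- sum(rE) * dist$dx
  list(E_mean = E_mean, dE_dt = dE_dt, W_rate = 0,
       Q_rate = sum(dist$qdot) * dist$dx)
}

#' Build a grid distribution from an analytic phase-space density
#'
#' Projects a user-supplied \eqn{P(X, V)} onto the solver basis by
#' quadrature and packages it as a `grid_distribution`, including the
#' generator residual \eqn{\partial_t P} evaluated on it.  This makes it
#' possible to evaluate currents, entropy and energy functionals on exact
#' reference states (global Maxwellians, detailed-balance Boltzmann forms,
#' squeezed transients) independently of the steady-state solve.  Note the
#' position domain is periodic: a state that is not (numerically)
#' periodic on `[-L, L)` will show wrap artifacts in the residual.
#'
#' @param pot,params,grid as in [solve_kramers()].
#' @param Pfun vectorized function `(X, V) -> density` (need not be
#'   normalized; it is renormalized to unit mass).
#' @return A `grid_distribution`.
#' @export
kramers_state <- function(pot, params, grid, Pfun) {
  op <- kramers_operator(pot, params, grid)
  cmat <- project_coefficients(op, Pfun)
  mass_full <- as.vector(outer(sqrt(op$geo$s) * op$geo$dx, op$hb$mu))
  cvec <- B_to_coef(cmat)
  cvec <- cvec / sum(mass_full * cvec)
  resid <- as.numeric(op$A %*% cvec)
  build_grid_distribution(cvec, resid, op, pot, params, grid)
}

# quadrature projection of an (X, V) density onto the Hermite basis
project_coefficients <- function(op, Pfun) {
  geo <- op$geo; nx <- op$nx; nv <- op$nv
  xi <- seq(-9, 9, length.out = 601); dxi <- xi[2] - xi[1]
  H <- hermite_eval(nv, xi)
  cmat <- matrix(0, nv, nx)
  for (i in seq_len(nx)) {
    V <- geo$s[i] * xi
    Pv <- Pfun(rep(geo$X[i], length(V)), V)
    # b_n = int P psi_n dV, psi_n = h_n(xi)/sqrt(s), dV = s dxi
    cmat[, i] <- as.numeric(crossprod(H, Pv)) * sqrt(geo$s[i]) * dxi
  }
  cmat
}

#' Implicit-Euler time marching of the Kramers equation
#'
#' Advances an initial phase-space distribution with the implicit Euler
#' scheme (unconditionally stable; the sparse factorization is reused
#' across steps) and returns snapshots as `grid_distribution`s, e.g. to
#' follow a relaxation transient or to feed [hydro_residuals()] with
#' time-resolved moments.
#'
#' @param pot,params,grid as in [solve_kramers()].
#' @param init either `NULL` (local Maxwellian with Boltzmann weight), a
#'   coefficient matrix, or a function `(X, V) -> density` projected onto
#'   the basis by quadrature.
#' @param dt time step (dimensionless).
#' @param n_steps number of steps.
#' @param record_every snapshot stride.
#' @param renormalize renormalize the mass after every step (default).
#'   The generator conserves mass exactly except for Hermite-truncation
#'   leakage through the populated top modes (below `1e-12` per unit time
#'   on resolved states, larger during sharp transients).
#' @return List with `times` and `snapshots` (list of
#'   `grid_distribution`).
#' @export
kramers_march <- function(pot, params, grid = kramers_grid(), init = NULL,
                          dt = 0.01, n_steps = 100, record_every = 10,
                          renormalize = TRUE) {
  op <- kramers_operator(pot, params, grid)
  geo <- op$geo; nx <- op$nx; nv <- op$nv
  if (is.null(init)) {
    cmat <- matrix(0, nv, nx)
    cmat[1, ] <- exp(-(geo$U - min(geo$U)))
  } else if (is.matrix(init)) {
    cmat <- init
  } else {
    cmat <- project_coefficients(op, init)
  }
  mass_full <- as.vector(outer(sqrt(geo$s) * geo$dx, op$hb$mu))
  cvec <- B_to_coef(cmat)
  cvec <- cvec / sum(mass_full * cvec)
  M <- Matrix::Diagonal(nx * nv) - dt * op$A
  Mf <- Matrix::lu(M, order = 0L)
  snaps <- list(); times <- c()
  for (k in seq_len(n_steps)) {
    cvec <- as.numeric(Matrix::solve(Mf, cvec))
    if (renormalize) cvec <- cvec / sum(mass_full * cvec)
    if (k %% record_every == 0L || k == n_steps) {
      resid <- as.numeric(op$A %*% cvec)
      snaps[[length(snaps) + 1]] <-
        build_grid_distribution(cvec, resid, op, pot, params, grid)
      times <- c(times, k * dt)
    }
  }
  list(times = times, snapshots = snaps)
}

#' Dimensional field profile of a solver steady state
#'
#' Converts the dimensionless solver moments to the dimensional units of
#' the Langevin estimators (`x = l X`, `v = v_T V`), returning a
#' `field_profile`-compatible data.frame: density `n`, `msv`
#' \eqn{= \langle v^2\rangle_x}, `theta`, `qdot`
#' \eqn{= (\Gamma/\tau)n(\theta - \langle v^2\rangle_x)} and `sigma_m`.
#'
#' @param dist a `grid_distribution`.
#' @return data.frame with columns `x`, `n`, `u`, `msv`, `theta`, `gamma`,
#'   `qdot`, `sigma_m`.
#' @export
kramers_profile <- function(dist) {
  p <- dist$params; l <- p$length_scale; vT <- p$v_T
  x <- dist$X * l
  n <- dist$n / l
  msv <- dist$msv * vT^2
  theta <- p$T_b / dist$g
  qdot <- (dist$g / p$tau) * n * (theta - msv)
  data.frame(x = x, n = n, u = dist$u * vT, msv = msv,
             gamma = dist$g, theta = theta,
             qdot = qdot, sigma_m = qdot / theta)
}
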