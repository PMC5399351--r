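#' Local thermodynamic fields from a trajectory ensemble
#'
#' Bins the recorded stationary samples in position and computes per-bin
#' velocity moments:
#' * `n`  -- spatial density (normalized so that \eqn{\int n\,dx = 1});
#' * `u`  -- mean velocity \eqn{u(x)};
#' * `msv` -- raw second moment \eqn{\langle v^2\rangle_x}, the local
#'   kinetic temperature;
#' * `T`  -- central second moment \eqn{T = \langle v^2\rangle_x - u^2};
#' * `j_q` -- heat flux \eqn{j_q = n\,\langle (v-u)^3\rangle_x / 2}
#'   (density-weighted half third central moment);
#' * `theta` -- local bath temperature \eqn{\theta(x) = T_b/\Gamma(x)} at
#'   bin centers;
#' * `qdot`, `sigma_m` -- see [heat_flux_density()] and
#'   [entropy_flux_density()].
#'
#' Standard errors come from the spread of per-trajectory bin means
#' (trajectories are independent by construction, unlike time blocks).
#' Bins with fewer than `min_count` samples, or visited by fewer than two
#' trajectories, are masked (`masked = TRUE`, fields `NA`), never
#' zero-filled.
#'
#' The profile also carries per-trajectory spatial integrals of the heat
#' and entropy flux densities (attributes `qdot_traj`, `sm_traj`), which
#' [thermo_budget()] uses for exact independent-replicate standard errors.
#'
#' @param ens a `trajectory_ensemble` (post burn-in samples only; pass the
#'   config's `burn_in` at simulation time).
#' @param pot,params the [potential()] and [gcn_params()] of the run.
#' @param x_edges bin edges; default `nbins` uniform bins over
#'   `pot$domain_hint`.
#' @param nbins number of bins when `x_edges` is `NULL`.
#' @param min_count mask threshold on per-bin sample count.
#' @return A `field_profile`: a data.frame with one row per bin plus
#'   metadata attributes (`params`, `x_edges`, per-trajectory budget
#'   integrals).
#' @export
estimate_fields <- function(ens, pot, params = ens$params, x_edges = NULL,
                            nbins = 101, min_count = 20) {
  if (ncol(ens$x) < 2) stop("need at least 2 trajectories for standard errors")
  if (is.null(x_edges))
    x_edges <- seq(pot$domain_hint[1], pot$domain_hint[2], length.out = nbins + 1)
  nb <- length(x_edges) - 1
  ntraj <- ncol(ens$x)
  v <- ensemble_velocity(ens, pot)

  x <- as.vector(ens$x); vv <- as.vector(v)
  traj <- rep(seq_len(ntraj), each = nrow(ens$x))
  bin <- findInterval(x, x_edges, rightmost.closed = TRUE)
  inside <- bin >= 1 & bin <= nb
  bin <- bin[inside]; xv <- vv[inside]; traj <- traj[inside]

  # per (bin, trajectory) accumulation of moments
  key <- bin + nb * (traj - 1L)
  cnt <- tabulate(key, nb * ntraj)
  s1 <- rowsum_vec(xv, key, nb * ntraj)
  s2 <- rowsum_vec(xv^2, key, nb * ntraj)
  s3 <- rowsum_vec(xv^3, key, nb * ntraj)
  dim(cnt) <- dim(s1) <- dim(s2) <- dim(s3) <- c(nb, ntraj)

  n_rec <- nrow(ens$x)               # samples per trajectory
  dx <- diff(x_edges)
  counts <- rowSums(cnt)
  mask <- counts < min_count | rowSums(cnt > 0) < 2

  # pooled moments
  u   <- ifelse(counts > 0, rowSums(s1) / counts, NA_real_)
  msv <- ifelse(counts > 0, rowSums(s2) / counts, NA_real_)
  m3  <- ifelse(counts > 0, rowSums(s3) / counts, NA_real_)
  Tc  <- msv - u^2
  mu3c <- m3 - 3 * u * msv + 2 * u^3
  n_total <- sum(counts)
  dens <- counts / n_total / dx
  jq <- dens * mu3c / 2

  # per-trajectory versions for SEs (occupancy-weighted, matching the pooled
  # estimator: each trajectory contributes its mean of the same estimand)
  se_of <- function(num, den = cnt) {
    m <- num / den
    m[den == 0] <- NA
    apply(m, 1, function(r) {
      r <- r[is.finite(r)]
      if (length(r) < 2) return(NA_real_)
      stats::sd(r) / sqrt(length(r))
    })
  }
  se_u <- se_of(s1)
  se_msv <- se_of(s2)
  dens_t <- sweep(cnt, 1, dx, "/") / n_rec  # per-traj density estimate per bin
  se_n <- apply(dens_t, 1, stats::sd) / sqrt(ntraj)

  x_mid <- (x_edges[-1] + x_edges[-length(x_edges)]) / 2
  gam <- suppressWarnings(gamma_factor(pot, x_mid, params))
  theta <- ifelse(gam > 0, params$T_b / gam, NA_real_)

  fp <- data.frame(x = x_mid, counts = counts, masked = mask,
                   n = dens, se_n = se_n,
                   u = u, se_u = se_u,
                   msv = msv, se_msv = se_msv,
                   T = Tc, j_q = jq,
                   gamma = gam, theta = theta,
                   qdot = NA_real_, se_qdot = NA_real_,
                   sigma_m = NA_real_, se_sigma_m = NA_real_)
  fp[mask, c("n", "u", "msv", "T", "j_q")] <- NA_real_

  # per-trajectory spatial integrals: int qdot dx = E[(Gamma(x)/tau)(theta - v^2)]
  # over samples (tower property), and likewise for sigma_m = qdot/theta.
  gx <- suppressWarnings(gamma_factor(pot, x, params))
  ok <- gx > 0
  w_q <- (gx / params$tau) * (params$T_b / gx - vv^2)
  w_s <- w_q * gx / params$T_b                    # divide by theta = T_b/gx
  tr_all <- rep(seq_len(ntraj), each = n_rec)
  qdot_traj <- rowsum_vec(ifelse(ok, w_q, 0), tr_all, ntraj) / n_rec
  sm_traj <- rowsum_vec(ifelse(ok, w_s, 0), tr_all, ntraj) / n_rec

  structure(fp, class = c("field_profile", "data.frame"),
            params = params, x_edges = x_edges, potential = pot$name,
            seed = ens$seed, qdot_traj = qdot_traj, sm_traj = sm_traj)
}

rowsum_vec <- function(x, group, n) {
  out <- numeric(n)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s
  out
}

#' Local heat-flux density
#'
#' Fills the `qdot` column of a profile with
#' \deqn{\dot q(x) = \frac{\Gamma(x)}{\tau}\, n(x)\,
#'   \bigl[\theta(x) - \langle v^2\rangle_x\bigr],}
#' the rate of heat locally exchanged with the active bath (obtained as the
#' first velocity moment of the dissipative part of the Kramers current).
#' Positive values mean the particle is locally colder than the bath and
#' receives heat.  In a stationary state \eqn{\int \dot q\,dx = 0}.
#'
#' @param fp a `field_profile` from [estimate_fields()].
#' @param pot,params model objects (default: those stored on `fp`).
#' @return The profile with `qdot` and `se_qdot` filled.
#' @export
heat_flux_density <- function(fp, pot = NULL, params = attr(fp, "params")) {
  if (any(!fp$masked & !is.na(fp$gamma) & fp$gamma <= 0))
    stop("qdot undefined: Gamma <= 0 on unmasked bins")
  pref <- fp$gamma / params$tau
  fp$qdot <- pref * fp$n * (fp$theta - fp$msv)
  fp$se_qdot <- abs(pref) * sqrt((fp$n * fp$se_msv)^2 +
                                 ((fp$theta - fp$msv) * fp$se_n)^2)
  fp
}

#' Local entropy flux to the medium
#'
#' \deqn{\sigma_m(x) = \dot q(x) / \theta(x):}
#' the heat flux weighted by the inverse local bath temperature.  Its
#' spatial integral is the medium entropy production \eqn{\dot S_m}, which
#' the generalized Clausius inequality bounds by zero from above in any
#' stationary state.
#'
#' @inheritParams heat_flux_density
#' @return The profile with `sigma_m` and `se_sigma_m` filled (computes
#'   `qdot` first if needed).
#' @export
entropy_flux_density <- function(fp, pot = NULL, params = attr(fp, "params")) {
  if (all(is.na(fp$qdot))) fp <- heat_flux_density(fp, pot, params)
  fp$sigma_m <- fp$qdot / fp$theta
  fp$se_sigma_m <- fp$se_qdot / abs(fp$theta)
  fp
}

#' Global heat and entropy budget of a stationary profile
#'
#' Integrates the heat-flux density and the medium entropy flux over
#' position.  When the profile carries per-trajectory integrals (profiles
#' built by [estimate_fields()] do), totals and standard errors are taken
#' as mean and standard error over the independent trajectories -- an exact
#' treatment of the cross-bin correlations; otherwise a trapezoid rule with
#' naive per-bin error propagation is used.
#'
#' In a stationary state the total heat exchanged with the bath vanishes,
#' while the total entropy flux obeys the generalized Clausius inequality
#' \deqn{\dot S_m = \int \frac{\dot q(x)}{\theta(x)}\,dx \le 0.}
#'
#' @param fp a `field_profile` with `qdot`/`sigma_m` filled (they are
#'   computed on the fly if absent).
#' @return A list of class `thermo_budget` with `total_qdot`,
#'   `se_total_qdot`, `total_entropy_flux`, `se_total_entropy_flux`,
#'   z-scores, and the trapezoid values for reference.
#' @export
thermo_budget <- function(fp) {
  if (all(is.na(fp$sigma_m))) fp <- entropy_flux_density(fp)
  ok <- !fp$masked & is.finite(fp$qdot)
  dx <- diff(attr(fp, "x_edges"))
  trap_q <- sum(fp$qdot[ok] * dx[ok])
  trap_s <- sum(fp$sigma_m[ok] * dx[ok])

  qt <- attr(fp, "qdot_traj"); st <- attr(fp, "sm_traj")
  if (!is.null(qt) && length(qt) >= 2) {
    tq <- mean(qt); se_q <- stats::sd(qt) / sqrt(length(qt))
    ts <- mean(st); se_s <- stats::sd(st) / sqrt(length(st))
  } else {
    tq <- trap_q; se_q <- sqrt(sum((fp$se_qdot[ok] * dx[ok])^2))
    ts <- trap_s; se_s <- sqrt(sum((fp$se_sigma_m[ok] * dx[ok])^2))
  }
  structure(list(total_qdot = tq, se_total_qdot = se_q,
                 z_qdot = tq / se_q,
                 total_entropy_flux = ts, se_total_entropy_flux = se_s,
                 z_entropy_flux = ts / se_s,
                 trapezoid_qdot = trap_q, trapezoid_entropy_flux = trap_s,
                 n_traj = if (!is.null(qt)) length(qt) else NA_integer_),
            class = "thermo_budget")
}

#' @export
print.thermo_budget <- function(x, ...) {
  cat(sprintf("<thermo_budget>\n  total heat flux     %+.4e (se %.2e, z = %+.2f)\n",
              x$total_qdot, x$se_total_qdot, x$z_qdot))
  cat(sprintf("  total entropy flux  %+.4e (se %.2e, z = %+.2f)  [Clausius: <= 0]\n",
              x$total_entropy_flux, x$se_total_entropy_flux, x$z_entropy_flux))
  invisible(x)
}

#' Gibbs entropy of the empirical phase-space histogram
#'
#' \eqn{s = -\sum P \log P \,\Delta x \Delta v} over unmasked cells of a 2D
#' (x, v) histogram.  Histogram differential entropies are bias-dominated,
#' so this is intended for trend and steady-state (\eqn{ds/dt = 0}) checks,
#' not absolute values.
#'
#' @param ens a `trajectory_ensemble`.
#' @param pot the run's potential.
#' @param nx,nv histogram resolution.
#' @return Scalar entropy estimate.
#' @export
gibbs_entropy <- function(ens, pot, nx = 61, nv = 61) {
  v <- as.vector(ensemble_velocity(ens, pot)); x <- as.vector(ens$x)
  bx <- seq(min(x), max(x), length.out = nx + 1)
  bv <- seq(min(v), max(v), length.out = nv + 1)
  h <- table(cut(x, bx), cut(v, bv))
  p <- h / sum(h) / (diff(bx)[1] * diff(bv)[1])
  p <- p[p > 0]
  -sum(p * log(p)) * diff(bx)[1] * diff(bv)[1]
}

#' Field profile of an exact phase-space distribution on a grid
#'
#' Computes the same fields as [estimate_fields()] from a gridded
#' \eqn{P(x, v)} by quadrature instead of sampling (standard errors are
#' zero).  Used for closed-form fixtures such as the UCNA local-Maxwellian
#' ansatz, for which the heat flux must vanish identically.
#'
#' @param P matrix `length(x) x length(v)` of phase-space density values.
#' @param x,v grids (uniform spacing assumed).
#' @param pot,params model objects.
#' @return A `field_profile` data.frame (with zero standard errors and the
#'   full-grid `x` as bin centers).
#' @export
grid_profile <- function(P, x, v, pot, params) {
  dv <- v[2] - v[1]; dx <- x[2] - x[1]
  n <- rowSums(P) * dv
  tot <- sum(n) * dx
  n <- n / tot; P <- P / tot
  u <- rowSums(P %*% diag(v)) * dv / pmax(n, .Machine$double.xmin)
  msv <- rowSums(sweep(P, 2, v^2, "*")) * dv / pmax(n, .Machine$double.xmin)
  mu3c <- sapply(seq_along(x), function(i) {
    sum(P[i, ] * (v - u[i])^3) * dv / max(n[i], .Machine$double.xmin)
  })
  gam <- suppressWarnings(gamma_factor(pot, x, params))
  theta <- ifelse(gam > 0, params$T_b / gam, NA_real_)
  mask <- n < 1e-12 * max(n)
  fp <- data.frame(x = x, counts = NA_integer_, masked = mask,
                   n = n, se_n = 0, u = u, se_u = 0, msv = msv, se_msv = 0,
                   T = msv - u^2, j_q = n * mu3c / 2,
                   gamma = gam, theta = theta,
                   qdot = NA_real_, se_qdot = 0,
                   sigma_m = NA_real_, se_sigma_m = 0)
  fp[mask, c("u", "msv", "T", "j_q")] <- NA_real_
  edges <- c(x - dx / 2, x[length(x)] + dx / 2)
  structure(fp, class = c("field_profile", "data.frame"),
            params = params, x_edges = edges, potential = pot$name, seed = NA)
}

#' Hydrodynamic balance residuals
#'
#' The first three velocity moments of the Kramers equation give the
#' balance laws (raw-moment form)
#' \deqn{\partial_t n + \partial_x(nu) = 0,}
#' \deqn{\partial_t(nu) + \partial_x(n\langle v^2\rangle)
#'   = \frac{n f}{\tau\gamma} - \frac{\Gamma}{\tau} nu,}
#' \deqn{\partial_t(n\langle v^2\rangle) + \partial_x m_3
#'   = \frac{2 n u f}{\tau\gamma} - \frac{2\Gamma}{\tau} n\langle v^2\rangle
#'     + \frac{2D}{\tau^2} n,}
#' with \eqn{m_3} the raw third moment (equivalently the density, momentum
#' and kinetic-temperature balances; the temperature form follows by
#' subtracting \eqn{u\times} the momentum balance).  Given profiles at
#' successive times on a common grid, this computes centered
#' finite-difference residuals of the three laws; for exact stationary
#' input all residuals vanish to discretization order.
#'
#' @param fps list of `field_profile`s on a common grid.
#' @param times numeric vector of their times.
#' @param pot,params model objects.
#' @return A list of residual matrices `continuity`, `momentum`, `energy`
#'   (rows: interior time levels; columns: interior bins) and the grids.
#' @export
hydro_residuals <- function(fps, times, pot, params) {
  stopifnot(length(fps) == length(times), length(fps) >= 3)
  xg <- fps[[1]]$x
  for (f in fps) if (!isTRUE(all.equal(f$x, xg))) stop("grid mismatch")
  get <- function(col) t(vapply(fps, function(f) f[[col]], numeric(length(xg))))
  N <- get("n"); U <- get("u"); M2 <- get("msv"); JQ <- get("j_q")
  NU <- N * U; NM2 <- N * M2
  M3 <- 2 * JQ + 3 * U * NM2 - 2 * N * U^3   # raw third moment density
  f_x <- -pot$dw(xg); gam <- suppressWarnings(gamma_factor(pot, xg, params))
  tg <- params$tau * params$gamma

  ddx <- function(M) t(apply(M, 1, function(r) {
    c(NA, (r[-(1:2)] - r[-((length(r) - 1):length(r))]) /
        (xg[-(1:2)] - xg[-((length(xg) - 1):length(xg))]), NA)
  }))
  ddt <- function(M) {
    nt <- nrow(M)
    (M[-(1:2), , drop = FALSE] - M[-((nt - 1):nt), , drop = FALSE]) /
      (times[-(1:2)] - times[-((nt - 1):nt)])
  }
  mid <- function(M) M[-c(1, nrow(M)), , drop = FALSE]

  r_cont <- ddt(N) + mid(ddx(NU))
  r_mom <- ddt(NU) + mid(ddx(NM2)) -
    sweep(mid(N), 2, f_x / tg, "*") + sweep(mid(NU), 2, gam / params$tau, "*")
  r_en <- ddt(NM2) + mid(ddx(M3)) -
    2 * sweep(mid(NU), 2, f_x / tg, "*") +
    2 * sweep(mid(NM2), 2, gam / params$tau, "*") -
    2 * params$D / params$tau^2 * mid(N)
  list(continuity = r_cont, momentum = r_mom, energy = r_en,
       x = xg, times = times[-c(1, length(times))])
}
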