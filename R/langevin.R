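#' Simulation settings for the Langevin integrators
#'
#' @param n_traj number of independent trajectories (>= 1).
#' @param n_steps number of Euler steps after the initial state.
#' @param dt time step.  A warning is emitted when `dt > tau/10` at
#'   simulation time, since the Euler scheme then under-resolves the active
#'   bath correlation.
#' @param burn_in steps discarded before recording starts (must be
#'   `< n_steps`).
#' @param seed integer seed; identical `(seed, config, params)` give
#'   bit-identical ensembles.
#' @param init_x either a scalar (point mass; trajectories all start there,
#'   default 0) or a function `n -> n` positions sampling the initial law.
#' @param record_stride steps between stored samples.  `NULL` picks the
#'   smallest stride with spacing at least `tau/10`, which controls memory
#'   without biasing stationary histograms.
#' @param exact_ou use the exact-in-distribution update for the
#'   Ornstein-Uhlenbeck activity instead of its Euler discretization
#'   (position update stays Euler).  Default `FALSE`: the plain Euler scheme
#'   is the reference integrator.
#' @param blowup_bound abort when any `|x|` exceeds this bound (default
#'   `100 * max(|domain_hint|)` of the potential at run time): with a
#'   confining potential such excursions indicate an unstable step size,
#'   not data.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_traj, n_steps, dt, burn_in = 0, seed = 1,
                       init_x = 0, record_stride = NULL,
                       exact_ou = FALSE, blowup_bound = NULL) {
  stopifnot(n_traj >= 1, n_steps >= 1, dt > 0, burn_in >= 0, burn_in < n_steps)
  structure(list(n_traj = as.integer(n_traj), n_steps = as.integer(n_steps),
                 dt = dt, burn_in = as.integer(burn_in), seed = as.integer(seed),
                 init_x = init_x, record_stride = record_stride,
                 exact_ou = isTRUE(exact_ou), blowup_bound = blowup_bound),
            class = "sim_config")
}

resolve_stride <- function(cfg, params) {
  if (!is.null(cfg$record_stride)) return(as.integer(cfg$record_stride))
  max(1L, as.integer(ceiling(params$tau / 10 / cfg$dt)))
}

init_positions <- function(cfg) {
  if (is.function(cfg$init_x)) cfg$init_x(cfg$n_traj)
  else rep(as.numeric(cfg$init_x), cfg$n_traj)
}

check_dt <- function(cfg, params) {
  if (cfg$dt > params$tau / 10)
    warning(sprintf("dt = %g exceeds tau/10 = %g: the active bath is under-resolved",
                    cfg$dt, params$tau / 10))
}

new_ensemble <- function(times, x, v_or_a, representation, params, cfg) {
  if (nrow(x) == 0)
    stop("no samples recorded: check n_steps, burn_in and record_stride")
  if (anyNA(x) || any(!is.finite(x)) || anyNA(v_or_a) || any(!is.finite(v_or_a)))
    stop("non-finite values in recorded samples (integration blow-up?)")
  structure(list(times = times, x = x, v_or_a = v_or_a,
                 representation = representation,
                 params = params, config = cfg, seed = cfg$seed),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %s | %d trajectories x %d recorded times | seed %d\n",
              x$representation, ncol(x$x), nrow(x$x), x$seed))
  invisible(x)
}

#' Euler-Maruyama simulation of the GCN model, (x, a) representation
#'
#' Integrates
#' \deqn{\dot x = f(x)/\gamma + a,\qquad
#'       \dot a = -a/\tau + (\sqrt D/\tau)\eta(t)}
#' for an ensemble of independent particles.  The activity is initialized
#' from its stationary law \eqn{N(0, D/\tau)}; positions per
#' `config$init_x`.  Recorded matrices have one row per stored time and one
#' column per trajectory.
#'
#' @param pot a [potential()].
#' @param params a [gcn_params()].
#' @param config a [sim_config()].
#' @return A `trajectory_ensemble` with `v_or_a` holding the activity `a`.
#' @seealso [simulate_xv()] for the phase-space representation;
#'   the two agree in all stationary statistics (with `v = f/gamma + a`).
#' @export
simulate_xa <- function(pot, params, config) {
  check_dt(config, params)
  set.seed(config$seed)
  n <- config$n_traj; dt <- config$dt
  tau <- params$tau; D <- params$D; gam <- params$gamma
  stride <- resolve_stride(config, params)
  bound <- config$blowup_bound %||% (100 * max(abs(pot$domain_hint)))

  x <- init_positions(config)
  a <- stats::rnorm(n, 0, sqrt(D / tau))
  if (config$exact_ou) {
    ou_m <- exp(-dt / tau); ou_s <- sqrt(D / tau * (1 - ou_m^2))
  } else {
    sq <- sqrt(2 * D) / tau * sqrt(dt)
  }

  keep <- which(seq_len(config$n_steps) > config$burn_in &
                (seq_len(config$n_steps) - config$burn_in) %% stride == 0L)
  rec <- logical(config$n_steps); rec[keep] <- TRUE
  xs <- matrix(NA_real_, length(keep), n)
  as <- matrix(NA_real_, length(keep), n)
  j <- 0L
  for (k in seq_len(config$n_steps)) {
    x <- x + dt * (-pot$dw(x) / gam + a)
    a <- if (config$exact_ou) ou_m * a + ou_s * stats::rnorm(n)
         else a - dt * a / tau + sq * stats::rnorm(n)
    if (rec[k]) {
      j <- j + 1L
      xs[j, ] <- x; as[j, ] <- a
    }
    if (k %% 2048L == 0L) {
      m <- max(abs(x))
      if (!is.finite(m) || m > bound)
        stop(sprintf("blow-up: |x| exceeded %g at step %d", bound, k))
    }
  }
  times <- config$dt * keep
  new_ensemble(times, xs, as, "xa", params, config)
}

#' Euler-Maruyama simulation, (x, v) phase-space representation
#'
#' Integrates the equivalent second-order form
#' \deqn{\dot x = v,\qquad
#'  \dot v = -\frac{\Gamma(x)}{\tau} v + \frac{f(x)}{\tau\gamma}
#'           + \frac{\sqrt D}{\tau}\eta(t)}
#' with the space-dependent friction \eqn{\Gamma(x) = 1+(\tau/\gamma)w''(x)}.
#' Initial velocities are drawn from \eqn{N(0, D/\tau)} (the flat-potential
#' stationary law).  Stationary statistics agree with [simulate_xa()] within
#' Monte Carlo error.
#'
#' @inheritParams simulate_xa
#' @return A `trajectory_ensemble` with `v_or_a` holding the velocity `v`.
#' @export
simulate_xv <- function(pot, params, config) {
  check_dt(config, params)
  set.seed(config$seed)
  n <- config$n_traj; dt <- config$dt
  tau <- params$tau; D <- params$D; gam <- params$gamma
  stride <- resolve_stride(config, params)
  bound <- config$blowup_bound %||% (100 * max(abs(pot$domain_hint)))
  sq <- sqrt(2 * D) / tau * sqrt(dt)

  x <- init_positions(config)
  v <- stats::rnorm(n, 0, sqrt(D / tau))

  keep <- which(seq_len(config$n_steps) > config$burn_in &
                (seq_len(config$n_steps) - config$burn_in) %% stride == 0L)
  rec <- logical(config$n_steps); rec[keep] <- TRUE
  xs <- matrix(NA_real_, length(keep), n)
  vs <- matrix(NA_real_, length(keep), n)
  j <- 0L
  for (k in seq_len(config$n_steps)) {
    gx <- 1 + (tau / gam) * pot$d2w(x)
    vnew <- v + dt * (-gx * v / tau - pot$dw(x) / (tau * gam)) + sq * stats::rnorm(n)
    x <- x + dt * v
    v <- vnew
    if (rec[k]) {
      j <- j + 1L
      xs[j, ] <- x; vs[j, ] <- v
    }
    if (k %% 2048L == 0L) {
      m <- max(abs(x))
      if (!is.finite(m) || m > bound)
        stop(sprintf("blow-up: |x| exceeded %g at step %d", bound, k))
    }
  }
  times <- config$dt * keep
  new_ensemble(times, xs, vs, "xv", params, config)
}

#' Velocity samples of an ensemble
#'
#' For an `xv` ensemble this is the stored velocity; for an `xa` ensemble
#' the velocity is reconstructed as \eqn{v = f(x)/\gamma + a}.
#'
#' @param ens a `trajectory_ensemble`.
#' @param pot the [potential()] used to generate it (needed for `xa`).
#' @return Matrix of velocities, same shape as `ens$x`.
#' @export
ensemble_velocity <- function(ens, pot) {
  if (ens$representation == "xv") return(ens$v_or_a)
  -pot$dw(ens$x) / ens$params$gamma + ens$v_or_a
}

#' Burn-in adequacy diagnostic
#'
#' Splits the recorded samples into two halves, histograms the positions of
#' each on a common grid, and reports the total-variation distance between
#' the two empirical densities.  A stationary, adequately burned-in
#' ensemble gives a small distance (sampling noise); a transient gives a
#' large one.
#'
#' @param ens a `trajectory_ensemble` with at least 2 recorded times.
#' @param threshold pass/fail threshold on the total-variation distance.
#' @param nbins histogram bins.
#' @return List with `tv` (distance in `[0,1]`), `pass`, `threshold`.
#' @export
stationarity_check <- function(ens, threshold = 0.05, nbins = 41) {
  nt <- nrow(ens$x)
  if (nt < 2) stop("need at least 2 recorded time blocks")
  half <- nt %/% 2
  rng <- range(ens$x)
  brk <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = nbins + 1)
  h1 <- tabulate(findInterval(ens$x[seq_len(half), ], brk), nbins)
  h2 <- tabulate(findInterval(ens$x[(half + 1):nt, ], brk), nbins)
  p1 <- h1 / sum(h1); p2 <- h2 / sum(h2)
  tv <- sum(abs(p1 - p2)) / 2
  list(tv = tv, pass = tv < threshold, threshold = threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
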