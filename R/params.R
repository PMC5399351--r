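#' Model parameters of the Gaussian-colored-noise dynamics
#'
#' The GCN model is the overdamped Langevin pair
#' \deqn{\dot x = f(x)/\gamma + a, \qquad
#'       \dot a = -a/\tau + (\sqrt{D}/\tau)\,\eta(t),}
#' with \eqn{\langle\eta(t)\eta(t')\rangle = 2\delta(t - t')}, so the active
#' bath \eqn{a(t)} is an Ornstein-Uhlenbeck process with stationary variance
#' \eqn{D/\tau} and correlation time \eqn{\tau}.
#'
#' Derived scales stored on the object:
#' * `T_b = D/tau` -- the bath temperature in velocity-squared units;
#' * `v_T = sqrt(D/tau)` -- the active thermal velocity;
#' * `zeta = l/sqrt(D*tau)` -- the inverse Peclet number (persistence length
#'   over the problem length scale `l`), the small-persistence expansion
#'   parameter;
#' * `peclet = 1/zeta`.
#'
#' @param gamma drag coefficient (force x time / length); must be > 0.
#' @param D active diffusivity (length^2 / time); must be > 0.
#' @param tau persistence time of the active force (time); must be > 0.
#' @param length_scale typical length `l` of the external potential, used
#'   only for non-dimensionalization.  Default 1 so that dimensional and
#'   dimensionless runs coincide for unit-parameter setups.
#' @return An object of class `gcn_params`.
#' @examples
#' p <- gcn_params(tau = 0.7)
#' p$T_b            # D/tau = 1/0.7
#' p$zeta * p$peclet  # 1
#' @export
gcn_params <- function(gamma = 1, D = 1, tau, length_scale = 1) {
  stopifnot(is.numeric(gamma), gamma > 0, is.numeric(D), D > 0,
            is.numeric(tau), tau > 0, is.numeric(length_scale), length_scale > 0)
  zeta <- length_scale / sqrt(D * tau)
  structure(list(gamma = gamma, D = D, tau = tau, length_scale = length_scale,
                 T_b = D / tau, v_T = sqrt(D / tau),
                 zeta = zeta, peclet = 1 / zeta),
            class = "gcn_params")
}

#' @export
print.gcn_params <- function(x, ...) {
  cat(sprintf(
    "<gcn_params> gamma=%g D=%g tau=%g l=%g | T_b=%g v_T=%g zeta=%g (Pe=%g)\n",
    x$gamma, x$D, x$tau, x$length_scale, x$T_b, x$v_T, x$zeta, x$peclet))
  invisible(x)
}

#' Friction renormalization Gamma(x)
#'
#' In the position-velocity representation the GCN model acquires a
#' space-dependent friction \eqn{\gamma\,\Gamma(x)/\tau} with
#' \deqn{\Gamma(x) = 1 + (\tau/\gamma)\, w''(x).}
#' \eqn{\Gamma = 1} for any flat (or linear) force-free landscape, and
#' \eqn{\Gamma - 1} is affine in \eqn{\tau}.  Where the curvature is strongly
#' negative \eqn{\Gamma} can turn non-positive; the value is returned as-is
#' with a warning, since the UCNA density and the local bath temperature lose
#' their interpretation there and downstream consumers document their own
#' policy.
#'
#' @param pot a [potential()].
#' @param x positions (vectorized).
#' @param params a [gcn_params()].
#' @return Numeric vector \eqn{\Gamma(x)} (dimensionless).
#' @export
gamma_factor <- function(pot, x, params) {
  g <- 1 + (params$tau / params$gamma) * pot$d2w(x)
  if (any(g <= 0)) {
    warning("Gamma(x) <= 0 at ", sum(g <= 0),
            " point(s): UCNA / local-temperature interpretation invalid there")
  }
  g
}

#' Local temperature of the active bath
#'
#' \deqn{\theta(x) = \frac{D}{\tau\,\Gamma(x)} = \frac{T_b}{\Gamma(x)}}
#' in velocity-squared units.  Defined only where \eqn{\Gamma(x) > 0}
#' (an error is raised otherwise); equals `T_b` exactly for a flat
#' potential, and tends to `T_b` in the small-persistence limit.
#'
#' @inheritParams gamma_factor
#' @return Numeric vector \eqn{\theta(x)}.
#' @export
local_bath_temperature <- function(pot, x, params) {
  g <- suppressWarnings(gamma_factor(pot, x, params))
  if (any(g <= 0)) {
    stop("theta(x) undefined: Gamma(x) <= 0 at ", sum(g <= 0), " point(s)")
  }
  params$T_b / g
}

#' Non-dimensionalization map
#'
#' Rescales position, velocity and time with the potential's length scale
#' `l` and the active thermal velocity `v_T`:
#' \deqn{X = x/l,\quad V = v/v_T,\quad \bar t = t\,v_T/l,\quad
#'       U(X) = w(lX)/(D\gamma),\quad F(X) = -U'(X),}
#' under which the Kramers equation takes its dimensionless form with the
#' single parameter \eqn{\zeta = l/\sqrt{D\tau}} (inverse Peclet number) and
#' friction field \eqn{g(X) = \Gamma(lX) = 1 + U''(X)/\zeta^2}.
#' All maps are exact inverses of one another (round trips are identity to
#' machine precision).
#'
#' @param params a [gcn_params()].
#' @param pot optional [potential()]; when given, the returned list also
#'   contains the dimensionless potential `U` and its derivatives.
#' @return A list of vectorized maps `to_X`, `from_X`, `to_V`, `from_V`,
#'   `to_T`, `from_T`, the value `zeta`, and (with `pot`) functions
#'   `U`, `F`, `g` of the dimensionless position.
#' @export
nondimensionalize <- function(params, pot = NULL) {
  l <- params$length_scale; vT <- params$v_T
  out <- list(
    to_X = function(x) x / l,       from_X = function(X) X * l,
    to_V = function(v) v / vT,      from_V = function(V) V * vT,
    to_T = function(t) t * vT / l,  from_T = function(Tt) Tt * l / vT,
    zeta = params$zeta)
  if (!is.null(pot)) {
    Dg <- params$D * params$gamma
    out$U <- function(X) pot$w(l * X) / Dg
    out$F <- function(X) -pot$dw(l * X) * l / Dg
    out$Upp  <- function(X) pot$d2w(l * X) * l^2 / Dg
    out$Uppp <- function(X) pot$d3w(l * X) * l^3 / Dg
    out$Upppp <- function(X) pot$d4w(l * X) * l^4 / Dg
    out$g <- function(X) 1 + out$Upp(X) / params$zeta^2
  }
  out
}
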