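#' External potentials for the GCN model
#'
#' A `gcn_potential` bundles the external potential \eqn{w(x)} with its
#' derivatives.  The first two derivatives enter the dynamics (force
#' \eqn{f = -w'} and friction renormalization
#' \eqn{\Gamma(x) = 1 + (\tau/\gamma) w''(x)}); the third and fourth enter
#' the small-persistence expansion of the local kinetic temperature.
#'
#' Built-in potentials carry analytic derivatives.  User-supplied potentials
#' may omit any derivative: missing ones are filled in by central differences
#' (step `1e-5 * max(1, |x|)` for `dw`/`d2w`).  The third and fourth
#' derivatives are too noise-prone for chained differencing: they use direct
#' five-point stencils on `w` (steps `5e-3` and `2e-2`), or differences of
#' `d2w` when an analytic second derivative was supplied.
#'
#' @param w vectorized function of position returning the potential.
#' @param dw,d2w,d3w,d4w optional vectorized derivative functions.
#' @param name label used in printing and serialization.
#' @param domain_hint numeric length-2 suggested x-range for grids and
#'   blow-up detection.
#' @return An object of class `gcn_potential`.
#' @examples
#' pot <- pot_double_well()
#' pot$d2w(0)            # -1
#' gamma_factor(pot, 0, gcn_params(tau = 0.7))  # 0.3
#' @export
potential <- function(w, dw = NULL, d2w = NULL, d3w = NULL, d4w = NULL,
                      name = "custom", domain_hint = c(-2.2, 2.2)) {
  stopifnot(is.function(w), length(domain_hint) == 2, domain_hint[1] < domain_hint[2])
  d2w_given <- !is.null(d2w)
  if (is.null(dw))  dw  <- function(x) fd_central(w, x)
  if (is.null(d2w)) d2w <- function(x) fd_central(dw, x)
  # higher derivatives: chaining first-order differences amplifies noise,
  # so use direct wide stencils on w (or on an analytic d2w when supplied)
  if (is.null(d3w)) {
    d3w <- if (d2w_given) function(x) fd_central(d2w, x, h = 1e-5 * pmax(1, abs(x)))
           else function(x) fd_stencil3(w, x)
  }
  if (is.null(d4w)) {
    d4w <- if (d2w_given) function(x) fd_second(d2w, x)
           else function(x) fd_stencil4(w, x)
  }
  structure(list(w = w, dw = dw, d2w = d2w, d3w = d3w, d4w = d4w,
                 name = name, domain_hint = as.numeric(domain_hint)),
            class = "gcn_potential")
}

# central difference, step scaled to |x|
fd_central <- function(f, x, h = 1e-5 * pmax(1, abs(x))) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# second derivative by 3-point stencil
fd_second <- function(f, x, h = 1e-4 * pmax(1, abs(x))) {
  (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

# third derivative: 5-point stencil on f itself, O(h^2)
fd_stencil3 <- function(f, x, h = 5e-3 * pmax(1, abs(x))) {
  (f(x + 2 * h) - 2 * f(x + h) + 2 * f(x - h) - f(x - 2 * h)) / (2 * h^3)
}

# fourth derivative: 5-point stencil on f itself, O(h^2)
fd_stencil4 <- function(f, x, h = 2e-2 * pmax(1, abs(x))) {
  (f(x + 2 * h) - 4 * f(x + h) + 6 * f(x) - 4 * f(x - h) + f(x - 2 * h)) / h^4
}

#' @rdname potential
#' @export
pot_flat <- function() {
  potential(w = function(x) rep(0, length(x)),
            dw = function(x) rep(0, length(x)),
            d2w = function(x) rep(0, length(x)),
            d3w = function(x) rep(0, length(x)),
            d4w = function(x) rep(0, length(x)),
            name = "flat", domain_hint = c(-1, 1))
}

#' @rdname potential
#' @param slope constant force magnitude of the linear potential
#'   \eqn{w(x) = \mathrm{slope}\cdot x}.
#' @export
pot_linear <- function(slope = 1) {
  force(slope)
  potential(w = function(x) slope * x,
            dw = function(x) rep(slope, length(x)),
            d2w = function(x) rep(0, length(x)),
            d3w = function(x) rep(0, length(x)),
            d4w = function(x) rep(0, length(x)),
            name = sprintf("linear(slope=%g)", slope), domain_hint = c(-1, 1))
}

#' @rdname potential
#' @param k spring constant of the harmonic well \eqn{w(x) = k x^2 / 2}.
#' @export
pot_harmonic <- function(k = 1) {
  force(k)
  potential(w = function(x) k * x^2 / 2,
            dw = function(x) k * x,
            d2w = function(x) rep(k, length(x)),
            d3w = function(x) rep(0, length(x)),
            d4w = function(x) rep(0, length(x)),
            name = sprintf("harmonic(k=%g)", k), domain_hint = c(-4, 4))
}

#' @rdname potential
#' @details The double well \eqn{w(x) = x^4/4 - x^2/2} is the bistable
#'   benchmark on which the non-equilibrium signatures of the model (bimodal
#'   density, kinetic-temperature/bath-temperature crossover, negative total
#'   entropy flux) are most visible.
#' @export
pot_double_well <- function() {
  potential(w = function(x) x^4 / 4 - x^2 / 2,
            dw = function(x) x^3 - x,
            d2w = function(x) 3 * x^2 - 1,
            d3w = function(x) 6 * x,
            d4w = function(x) rep(6, length(x)),
            name = "double_well", domain_hint = c(-2.2, 2.2))
}

#' Look up a built-in potential by name
#'
#' Used by the config reader.  `name` is one of `"flat"`, `"linear"`,
#' `"harmonic"`, `"double_well"`; `args` supplies `slope` or `k`.
#'
#' @param name character scalar.
#' @param args named list of parameters for the potential.
#' @return A `gcn_potential`.
#' @export
potential_by_name <- function(name, args = list()) {
  switch(name,
    flat        = pot_flat(),
    linear      = do.call(pot_linear, args),
    harmonic    = do.call(pot_harmonic, args),
    double_well = pot_double_well(),
    stop("unknown potential: ", name)
  )
}

#' @export
print.gcn_potential <- function(x, ...) {
  cat("<gcn_potential>", x$name,
      sprintf("  domain_hint [%g, %g]\n", x$domain_hint[1], x$domain_hint[2]))
  invisible(x)
}
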