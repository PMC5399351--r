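---
title: "Heat, local temperature and entropy in the Gaussian-colored-noise active particle model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heat, local temperature and entropy in the Gaussian-colored-noise active particle model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcntherm)
```

## The model

`gcntherm` studies a minimal model of active matter: a single overdamped
particle in one dimension whose self-propulsion is a Gaussian colored
noise,

$$\dot x = f(x)/\gamma + a, \qquad
  \dot a = -a/\tau + (\sqrt D/\tau)\,\eta(t),
  \qquad \langle\eta(t)\eta(t')\rangle = 2\delta(t-t').$$

The activity $a(t)$ is an Ornstein--Uhlenbeck process with persistence
time $\tau$ and stationary variance $D/\tau$; $f = -w'$ is the force of an
external potential $w$ and $\gamma$ the drag.  For $\tau \to 0$ the model
reduces to a passive Brownian particle; for $\tau > 0$ the driving is
persistent and the system is generically out of equilibrium.  This class
of dynamics is a standard coarse-grained description of self-propelled
colloids and swimming bacteria.

Changing variables to $(x, v)$ with $v = \dot x$ gives an underdamped-looking
dynamics with a *space-dependent friction*,

$$\dot v = -\frac{\Gamma(x)}{\tau}\,v + \frac{f(x)}{\tau\gamma}
  + \frac{\sqrt D}{\tau}\,\eta, \qquad
  \Gamma(x) = 1 + \frac{\tau}{\gamma}\,w''(x),$$

and an associated Kramers (phase-space Fokker--Planck) equation.  The key
thermodynamic object is the **local bath temperature**

$$\theta(x) = \frac{D}{\tau\,\Gamma(x)} = \frac{T_b}{\Gamma(x)},
  \qquad T_b = D/\tau,$$

in velocity-squared units: the active bath behaves as a heat bath whose
temperature varies in space through the curvature of the potential.  Only
for a flat (or linear) landscape is $\Gamma \equiv 1$ and the bath uniform.

From the dissipative part of the Kramers current one obtains the local
heat-flux density and the medium entropy flux,

$$\dot q(x) = \frac{\Gamma(x)}{\tau}\, n(x)\,
  \bigl[\theta(x) - \langle v^2\rangle_x\bigr],
  \qquad \sigma_m(x) = \frac{\dot q(x)}{\theta(x)},$$

with $n$ the density and $\langle v^2\rangle_x$ the local kinetic
temperature.  Splitting the Gibbs-entropy balance into an always
non-negative production $\dot S_{irr}$ and the flux
$\dot S_m = \int \sigma_m\,dx$ yields, in any stationary state, the
**generalized Clausius inequality**

$$\int \frac{\dot q(x)}{\theta(x)}\,dx \;\le\; 0,
  \qquad\text{while}\qquad \int \dot q(x)\,dx = 0 .$$

The total heat vanishes (hot regions compensate cold ones), yet because
$\theta$ is non-uniform the inverse-temperature weighting makes the total
entropy flux strictly negative whenever $\Gamma$ varies — the particle
continuously produces entropy that is exported to the active bath.

## Package architecture: three mutually validating legs

1. **Langevin simulation** (`simulate_xa()`, `simulate_xv()`): vectorized
   Euler--Maruyama ensembles with reproducible seeds, in either the
   $(x,a)$ or the $(x,v)$ representation.  `estimate_fields()` bins
   stationary samples into the local fields above; `thermo_budget()`
   integrates them, with standard errors taken over independent
   trajectories (an exact treatment, since trajectories are iid by
   construction).
2. **Closed-form theory** (`ucna_density()`, `fox_generator()`,
   `msv_expansion()`): the UCNA and Fox small-persistence closures and a
   systematic expansion in the inverse Péclet number
   $\zeta = l/\sqrt{D\tau}$.
3. **Kramers solver** (`solve_kramers()`): an independent deterministic
   solution of the stationary phase-space equation, used as the oracle
   against which both the simulation and the expansion are checked.

## The UCNA and the expansion

The unified colored-noise approximation adiabatically eliminates the
velocity and yields an effective *equilibrium* description with density

$$n_{\rm UCNA}(x) \propto |\Gamma(x)|\,
  \exp\left[-\frac{w + \tfrac{\tau}{2\gamma}(w')^2}{D\gamma}\right],$$

a local-Maxwellian phase-space ansatz with variance exactly $\theta(x)$,
detailed balance, and therefore zero heat flux and zero entropy
production everywhere.  The Fox closure shares the same zero-flux
stationary density (the package computes it by an independent quadrature
route, which doubles as a cross-check).  Both are correct through first
order in $\tau$.

The dimensionless expansion of the stationary Kramers equation in
$1/\zeta$ (a Hermite-moment hierarchy in the velocity) shows where local
equilibrium fails.  Writing $g(X) = 1 + U''(X)/\zeta^2$ for the
dimensionless inverse bath temperature:

$$\langle V^2\rangle_X = \frac{1}{g(X)} - \frac{R(X)}{\zeta^4}
  + O(\zeta^{-6}),
  \qquad R(X) = \tfrac12\left[U''''(X) - U'(X)U'''(X)\right].$$

Through $O(\zeta^{-2})$ the kinetic temperature equals the UCNA bath
temperature; the first deviation appears at $O(\zeta^{-4})$ and vanishes
identically for flat, linear and harmonic potentials — precisely the
cases with constant $g$, where detailed balance is exact.  The sign of

$$\Delta(X) = \frac{1}{g} - \langle V^2\rangle_X = \frac{R(X)}{\zeta^4}$$

sets the direction of the local heat exchange.  For the quartic double
well $U = X^4/4 - X^2/2$,

$$\Delta(X) = \frac{3\,(1 + X^2 - X^4)}{\zeta^4}:$$

positive near the barrier (the particle is colder than the bath and
absorbs heat there) and negative beyond
$X^\ast = \sqrt{(1+\sqrt5)/2} \approx 1.27$ (in the wells it releases
heat).

A structural point the package verifies explicitly: inserting
$\Delta = R/\zeta^4$ into the entropy-flux integral gives an apparent
$\zeta^{-3}$ rate, but the Boltzmann average of $R$ vanishes identically
($\int e^{-U}(U'''' - U'U''')\,dX = 0$ by parts), so the leading
non-zero entropy production scales as $\zeta^{-5}$ — equivalently
$\tau^2$ in dimensional units — the standard small-persistence result
for this family of active models.  `perturbative_entropy_production()`
reproduces this scaling (fitted log–log slope $\approx -5$); its
$\zeta^{-5}$ coefficient is structurally incomplete (the $O(\zeta^{-6})$
piece of $\Delta$ contributes at the same order), so the solver is the
quantitative reference while the formula provides sign and scaling.

## The spectral Kramers solver

The solver discretizes the dimensionless stationary equation with

* **Fourier collocation in $X$** on a periodic domain $[-L, L)$ with an
  odd number of points (the even-count Fourier differentiation matrix has
  a spurious sawtooth null vector that corrupts null-space solves), and
* an **orthonormal Hermite-function basis in $V$** — square-root-Maxwellian
  weighted, so the basis is orthonormal in plain $L^2$ — with an
  $X$-dependent scale $s(X)^2 \propto \theta(X)$ that follows the local
  bath temperature.  The scale variation enters as an analytic,
  antisymmetric $n \pm 2$ ladder coupling.

This combination was chosen over a more conventional finite-volume
(Chang–Cooper) discretization for two structural reasons.  First,
streaming terms are discretely *skew-symmetric* and the collision term
dissipative, so the discrete spectrum cannot develop spurious growing
modes (a Boltzmann-weighted collocation variant we tried first is
numerically unstable at moderate $\zeta$).  Second, for constant $g$ the
discrete steady state satisfies detailed balance to spectral accuracy
($\|I_v^D\|_\infty \sim 10^{-12}$), and at large $\zeta$ the solver error
sits far below the $O(\zeta^{-6})$ remainder of the expansion — both of
which are needed to *resolve* the theory, and neither of which a
first-order upwind scheme can reach (its $O(\Delta x)$ currents would
swamp the signal).  The price is that pointwise positivity is not
structurally enforced: reconstructed densities show negative excursions
at the $10^{-10}$ relative level in far tails, which the tests bound
explicitly instead of clipping.

Moments of the solution (density, $\langle V^2\rangle_X$, heat flux) are
evaluated by exact ladder-operator relations, free of velocity-quadrature
error.  The steady state is obtained by replacing one row of the singular
generator with the mass constraint and solving the sparse system
directly (unknowns ordered position-fastest, giving a banded structure;
an implicit-Euler marching fallback is provided).  Entropy functionals
require pointwise reconstruction and are quadrature-limited: the
steady-state identity $\dot S_{irr} = -\dot S_m$ is verified to
$3\times10^{-7}$ relative at $\tau = 0.2$ but only $\sim 10^{-4}$ at
$\tau = 0.7$, where the velocity distribution is strongly non-Gaussian;
the solver residual itself is $10^{-12}$.

A periodic caveat: a *linear* potential on the periodic domain is a
driven ring (a genuine current-carrying steady state with positive
entropy production), not the detailed-balance case the theory discusses
on the line.  The detailed-balance property of the linear potential is
therefore checked on the analytic Boltzmann-form state via
`kramers_state()`, whose velocity-space functionals are insensitive to
the wrap.

## Study conditions and what the tests show

The showcase experiment is the double well $w = x^4/4 - x^2/2$ with
$\gamma = 1$, $D = 1$, $\tau = 0.7$, integrated with $dt = 10^{-3}\tau$
from $x = 0$.  At desk scale the package uses 256 independent
trajectories and $10^6$ steps after a burn-in of $100\tau$ (the
reference-scale experiment uses 1024 trajectories and $>10^7$ steps; the
desk-scale ensemble reproduces every qualitative signature with standard
errors a few times larger).  Solver grids were fixed by convergence
studies: $97$ collocation points $\times$ $100$ Hermite modes,
$L = 2.8$, for $\tau = 0.7$ (the barrier-top kinetic temperature agrees
with the Langevin estimate to three decimals); $97 \times 40$ for
$\tau = 0.2$ and for the $\zeta \in \{4, 8, 16\}$ expansion
cross-checks.  The velocity-scale safety factor is $\alpha = 1.3$ and
the $|g|$ floor $0.05$; both only matter where $\Gamma$ would vanish.

What passing tests do and do not show: the generator is the model
itself, so the suite validates the *estimators and solvers* against
closed forms and against each other, under Gaussian colored-noise
driving with smooth confining potentials.  It does not probe
interactions, dimensions $> 1$, non-Gaussian propulsion statistics, or
potentials rough on the persistence-length scale — all outside the
model as implemented.

Numerical conventions worth knowing:

* the Euler--Maruyama scheme is the reference integrator (an exact OU
  substep for the activity is available via `exact_ou = TRUE`); its
  $O(dt)$ moment bias at $dt = 10^{-3}\tau$ is below the Monte Carlo
  error of the study conditions (verified by a $dt$-halving test);
* histograms are plain (no kernel smoothing); bins with fewer than 20
  samples or visited by fewer than two trajectories are masked, never
  zero-filled;
* budget standard errors use per-trajectory spatial integrals, which
  capture cross-bin correlations exactly;
* the per-bin Langevin/solver comparison runs ~80 simultaneous z-tests,
  restricted to bins with at least 500 samples (below that the
  across-trajectory standard-error estimate is itself unreliable); the
  acceptance test allows at most 2% of bins beyond 3 SE and none beyond
  4 SE, the usual multiple-comparisons allowance at this scale;
* the config dialect is YAML (round-trippable, see
  `read_run_config()`); profiles serialize to CSV with a commented
  header carrying parameters, seed and units, and budgets to JSON.

## Worked example

```{r example, eval = FALSE}
pot <- pot_double_well()
p   <- gcn_params(gamma = 1, D = 1, tau = 0.7)

# local bath temperature at the barrier: Gamma(0) = 1 - tau = 0.3
local_bath_temperature(pot, 0, p)     # 4.7619

# desk-scale stationary ensemble
cfg <- sim_config(n_traj = 256, n_steps = 1.1e6, dt = 7e-4,
                  burn_in = 1e5, seed = 1)
ens <- simulate_xv(pot, p, cfg)
fp  <- entropy_flux_density(estimate_fields(ens, pot))
thermo_budget(fp)
# total heat flux ~ 0 (|z| < 3); total entropy flux < 0 (z ~ -40)

# the independent solver agrees bin by bin
d  <- solve_kramers(pot, p, kramers_grid(nx = 97, nv = 100, L = 2.8))
kramers_entropy_budget(d)    # S_irr = -S_m ~ 0.26 > 0
```

## Known limitations

* One spatial dimension, non-interacting particles, time-independent
  potentials (no work protocols).
* The solver's entropy functionals are reconstruction-quadrature
  limited, as quantified above; its phase-space density is not
  positivity-enforced.
* The perturbative entropy-production estimate gives sign and scaling,
  not the exact $\zeta^{-5}$ coefficient.
* The finest level of description — a massive particle exchanging heat
  with the molecular solvent — lies below the model's resolution;
  entropy produced there is invisible here by construction.
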