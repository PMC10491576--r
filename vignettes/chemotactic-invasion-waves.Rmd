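---
title: "Chemotactic invasion waves in heterogeneous chemoattractant fields: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemotactic invasion waves: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`chemowave` studies the nondimensional cell-density equation on the unit
interval (a microfluidic chamber of width $L$, scaled to $[0,1]$),

$$u_t + (\alpha(t,x)\,u)_x = D\,u_{xx} + \beta(t,x)\,u(1-u),$$

with zero-flux boundaries $Du_x - \alpha u = 0$ at $x = 0, 1$ and initial
seeding $u(0,x) = u_0(x)$.  Here $\alpha(t,x)$ is the advective velocity a
known chemoattractant gradient induces via Keller–Segel chemotaxis,
$\beta(t,x) \ge 0$ a heterogeneous logistic growth rate (carrying capacity
scaled to 1), and $D \ll 1$ the cell diffusivity, small because undirected
cell motility is weak compared to chemotactic drift.  Because $\alpha$
varies in space and time, the invading cell wave is *not* a translationally
invariant travelling wave: its front position, speed and plateau density
all evolve with the stimulus.

The package provides three layers:

1. **Analytical machinery** — characteristic maps, front trajectories,
   outer densities, and a uniformly valid composite across the moving
   front, with closed forms for a catalogue of flux structures.
2. **Microdevice reductions** — the coupled cell/chemoattractant culture
   model, nondimensionalised to the groups $\Pi_1,\dots,\Pi_4$, and reduced
   to four tractable scenarios in the regime $\Pi_1 \ll 1 \ll \Pi_3$.
3. **A numerical oracle** — a conservative finite-volume solver for the
   full parabolic model (scalar and coupled), against which every
   analytical approximation is validated.

# Outer solution: the method of characteristics

With $D = 0$ the equation is hyperbolic.  Along the characteristic through
$(0, s)$, $dx/dt = \alpha(t, x)$, defining the forward map $x = F(t;s)$
with inverse label map $s = G(t;x)$.  A second family of characteristics
emanates from the $x = 0$ boundary carrying $u = 0$ (the no-flux condition
with $\alpha(t,0) \neq 0$ forces a vanishing boundary density), so the
separating characteristic $x^*(t) = F(t;0)$ is the invasion front: zero
density to its left, and to its right the density obeys, in $r = 1/u$,

$$r' + \big(\beta - h\big) r = \beta, \qquad
  h(\tau;s) = \begin{cases}
    a(\tau) & \alpha = a(t)x + b(t),\\
    f'(F(\tau;s))\,g(\tau) & \alpha = f(x)g(t),
  \end{cases}$$

whose variation-of-constants solution gives the outer density
(`outer_density_general()`) as a nested quadrature of
$p = \beta - h$ and $q = \beta$ along the characteristic.

## Closed-form catalogue

Every structure is parameterised by the cumulative stimulus
$\mathcal{T}(t) = \int_0^t g$, evaluated in closed form when the stimulus
is one of the built-ins (constant, $\cos\omega t$, $1 + \cos\omega t$,
ramp) and by adaptive quadrature otherwise:

| flux | $F(t;s)$ | construction |
|---|---|---|
| $(a_0x+b_0)g(t)$ | $s e^{a_0\mathcal{T}} + b_0\,\mathrm{expm1}(a_0\mathcal{T})/a_0$ | direct |
| $a x + b(t)$, $a$ const | $e^{at}\big(s + \int_0^t b e^{-a\eta}\big)$ | variation of constants |
| $a e^{-\lambda x} g(t)$ | $\frac{1}{\lambda}\ln(a\lambda\mathcal{T} + e^{\lambda s})$ | separable integral |
| $(ae^{-\lambda x}+be^{\lambda x})g(t)$ | arctan form | separable integral |
| $k\sqrt{\lambda}\cosh(\sqrt{\lambda}x)\psi(t)$ | $\mathcal{S} = \tan(k\lambda\mathcal{T}/2)$ form | Gudermannian integral |
| $k\sqrt{\lambda}\sinh(\sqrt{\lambda}x)\psi(t)$ | $\frac{2}{\sqrt\lambda}\,\mathrm{artanh}(e^{k\lambda\mathcal{T}}\tanh\frac{s\sqrt\lambda}{2})$ | log-tanh integral |

Non-catalogue separable fluxes use a monotone bracketed root solve of the
separable relation; fully general fluxes integrate the characteristic ODE
adaptively (tolerance $10^{-10}$), and the inverse map falls back to
*backward* integration from $(t,x)$ — exact by time reversibility, no
bracketing required.

Degenerate limits are handled explicitly: $a_0 \to 0$ uses
`expm1`-based evaluation (exact limit $x^* = b_0\mathcal{T}$ at
$a_0 = 0$), and the linear-case plateau density switches to the limit
$u_0/(1+u_0t)$ for $|a-1| < 10^{-8}$, where the generic expression is
$0/0$.

## Printed-form discrepancies and how they are adjudicated

Three closed forms circulating for these models do not satisfy the
characteristic ODE $dF/dt = \alpha(t, F)$, which we treat as the ground
truth (it *defines* the characteristics).  The package derives all its
maps from the governing equations and keeps the printed variants available
for comparison (`paper_printed_maps()`, `paper_verbatim` arguments); the
finite-difference residual test in the suite is the arbiter:

* **High-nutrient maps** — the circulating $F(t;s)$ lacks a factor
  $e^{k\lambda t}$ on the stimulus integral; its ODE residual is $10^{-3}$
  or larger where the derived map's is below $10^{-7}$.  The derived front
  also changes the published monotonicity claim quantitatively (not
  qualitatively at early times): increasing uptake still slows the wave on
  the tested window.
* **Symmetric-configuration maps** — integrating $1/f$ for
  $f = k\sqrt\lambda\sinh(\sqrt\lambda x)$ yields a log-tanh relation and
  hence an inverse *hyperbolic* tangent; the circulating arctan variant
  fails the residual test.
* **Gradient-configuration closed-form density** — the circulating
  expression raises $\cosh(\sqrt\lambda G)/\cosh(\sqrt\lambda x)$ to the
  exponent $E = (m_0 - k\lambda)/(k\lambda)$; integrating
  $du/d\tau = u(\beta - h)$ along characteristics (and both the quadrature
  form and an independent RK solve) gives the reciprocal ratio.  Since
  $\beta - h = (m_0 - k\lambda)\psi\sinh(\sqrt\lambda F) \ge 0$, the
  density right of the front must exceed $u_0$, which only the derived
  orientation satisfies.  The exponent itself ($E = 9$ at
  $k = 1, m_0 = 1, \lambda = 0.1$) is unaffected.

A related inconsistency concerns the gradient-configuration nutrient
profile $v = \psi(t)\sinh(\sqrt\lambda x)$, which misses the boundary
value $v(1,t) = \psi(t)$ by the factor $\sinh(\sqrt\lambda)$; the coupled
PDE solver relaxes to the boundary-consistent profile
$\psi\sinh(\sqrt\lambda x)/\sinh(\sqrt\lambda)$.  The analytic scenario
keeps the unnormalised profile because every downstream closed form is
built on it; users comparing against the coupled solver should rescale
$\psi$ accordingly.

# Inner layer and the composite solution

Near the front, diffusion re-enters at leading order in a layer of width
$O(D)$.  In front-attached coordinates with a Heaviside initial datum the
layer profile is

$$U(X, \tau) = \tfrac12\left(1 + \mathrm{erf}\tfrac{X}{2\sqrt{\tau}}\right),$$

and the composite (inner + outer − overlap) approximation is, for
$x \ge x^*$,
$\tfrac12 u_{an}(x^*,t)(\mathrm{erf}\frac{x-x^*}{w(t)} - 1) + u_{an}(x,t)$,
with the $+1$ branch and no outer term for $x < x^*$.  Continuity at the
front is automatic because $G(t;x^*(t)) = 0$.

**Layer width (a design choice this package makes differently).**  The
similarity width $w = 2\sqrt{tD}$ assumes the layer diffuses in a locally
uniform velocity field.  But the front rides a velocity gradient: material
separations evolve as $d(\delta x)/dt = \alpha_x\,\delta x$, so the layer
is stretched (compressed) by the Lagrangian factor
$J(t) = \exp\int_0^t \alpha_x(\eta, x^*(\eta))\,d\eta$, giving the
variance

$$\sigma^2(t) = 2D\,J(t)^2\!\int_0^t J(\eta)^{-2}\,d\eta,
  \qquad w = \sqrt{2\sigma^2},$$

which reduces to $2Dt$ when $\alpha_x = 0$.  For the linear flux
$\alpha = 2x + 1$ at $t = 0.4$ the stretch is substantial
($\sigma/\sqrt{2Dt} \approx 1.57$) and the finite-volume oracle shows the
similarity composite missing the layer shape by 11% of the plateau, while
the strain-corrected width tracks it to 0.3%.  `composite_density()`
therefore defaults to `layer = "strain"`, with `layer = "similarity"`
retained for comparison with the classical form.

**Validity limits.**  The composite does not resolve (i) the diffusive
boundary layer at $x = 1$, where the hyperbolic outer solution cannot meet
the no-flux condition — evaluations within the band
`bl_exclusion = max(0.02, 10*sqrt(D*T_max))` of the right edge are flagged,
not suppressed; (ii) the analogous $x = 0$ layer at very small times
($t < D$, flagged `small_time`); and (iii) for oscillatory stimuli, the
*return* of mass accumulated in the $x = 1$ layer once the flux reverses
sign — after the first stimulus half-period the region near $x = 1^-$ is
contaminated by a returning pulse the outer theory cannot represent (the
fig4 fixture's evaluation times stop before this happens; at $t = 0.25$
the measured discrepancy reaches 79% of the plateau).

# Oscillatory plateau dynamics

For $\alpha = (ax+b)\cos\omega t$ the flux divergence is $x$-independent,
so right of the front the density is spatially constant and
$r' + (\beta - a\cos\omega t)r = \beta$, $r(0) = 1/u_0$ (the canonical
form has $\beta = 1$; the $\beta$-generalisation reduces to it and
supports the regime analysis).  `exact_plateau_density()` evaluates the
integrating-factor solution by quadrature; `numeric_plateau_density()` is
the adaptive-RK oracle (relative tolerance $10^{-10}$).  Four leading-order
regimes are implemented (`regime_approximation()`):

* **slow** ($\omega \ll 1$, needs $a < \beta$ for coefficient positivity):
  quasi-steady balance $r \approx \beta/(\beta - a\cos\omega t)$ plus the
  exponentially decaying initial-layer correction, error $O(\omega)$;
* **fast** ($\omega \gg 1$): averaging — the logistic mean multiplied by
  the oscillatory factor $e^{-\frac{a}{\omega}\sin\omega t}$, error
  $O(1/\omega)$;
* **chemotaxis-dominant** ($\beta \ll a$): growth neglected,
  $u \approx u_0 e^{-\frac{a}{\omega}\sin\omega t}$;
* **growth-dominant** ($a \ll \beta$): oscillation neglected, logistic.

Only leading orders are committed to; the RK solution is the acceptance
ground truth, and the suite checks the error *decreases at the stated
rate* as each regime parameter deepens (halving $\omega$ at least halves
the slow-regime error, etc.).

# Microdevice scenarios

The dimensional culture model (live cells $C_n$, chemoattractant $B$,
uptake $W$, growth modulation $M_g$) nondimensionalises with
$C_n = c_{sat}u$, $B = B^*v$, $X = Lx$, $T = t/\alpha_n$ to

$$u_t = \Pi_1 u_{xx} - \Pi_2(v_xu)_x + m(v)u(1-u), \qquad
  v_t = \Pi_3 v_{xx} - \Pi_4 w(v,u),$$

with $\Pi_1 = D/(\alpha_nL^2)$, $\Pi_2 = \chi B^*/(\alpha_nL^2)$,
$\Pi_3 = D_B/(\alpha_nL^2)$, $\Pi_4 = \alpha_Bc_{sat}/(\alpha_nB^*)$, and
channel Dirichlet data $v(0,t)=\psi_1$, $v(1,t)=\psi_2$.  The
death compartment is accepted in the types but ignored by the reductions
(its rate is set to zero), and warnings fire outside the modelling regime
$\Pi_1 < 0.1$, $\Pi_3 > 10$.

In the regime $\Pi_1 \ll 1 \ll \Pi_3$ (and, for the consumption scenarios,
$\Pi_3^{-1} \ll \lambda \ll \Pi_3$) the chemoattractant relaxes on a fast
timescale to a quasi-steady profile and the cell equation collapses onto
the characteristics framework with $\alpha = k v_x$ ($k = \Pi_2$) and
$\beta = m(v)$:

| scenario | $v$ equation | profile | induced flux |
|---|---|---|---|
| weak consumption | $v_{xx}=0$ | $\Delta\psi\,x+\psi_1$ | $k\Delta\psi(t)$ |
| high nutrient | $v_{xx}=\lambda$ | quadratic | $k\lambda x + k(\Delta\psi - \lambda/2)$ |
| low nutrient, gradient | $v_{xx}=\lambda v$ | $\psi\sinh(\sqrt\lambda x)$ | $k\sqrt\lambda\cosh(\sqrt\lambda x)\psi$ |
| low nutrient, symmetric | $v_{xx}=\lambda v$ | $\psi\cosh(\sqrt\lambda x)$ | $k\sqrt\lambda\sinh(\sqrt\lambda x)\psi$ |

The scaled uptake rate is *computed by the scenario*, never supplied
twice: $\lambda = \Pi_4K/\Pi_3$ when uptake saturates (high nutrient,
$w_{pc}\sim1$) and $\lambda = \Pi_4K/(k_m\Pi_3)$ in the Michaelis–Menten
linearisation (low nutrient, $w_{pc}\sim v/k_m$), with $K$ the background
total cell density.  The same symbol $\lambda$ names the exponential-flux
decay rate elsewhere; the code namespaces the two (`lambda_grad` contexts
vs `lambda_uptake`) since they are unrelated quantities.

General low-nutrient boundary data make the characteristic relation a
Riccati equation in $e^x$ with no solution in standard functions; the
package raises a specific error naming the obstruction and pointing to
`solve_coupled()`.  For the symmetric configuration the growth is taken as
$\beta = m(v)$, consistent with the density kernel
$K = m(v) - kv_{xx}$ (statements fixing $\beta \equiv 1$ for this case are
inconsistent with that kernel and with the final density).  The symmetric
front does not detach from the origin ($\alpha(t,0) = 0$, $x^* = 0$), and
the package warns accordingly.

The high-nutrient density admits a small-$\lambda$ closed form
(`high_nutrient_small_lambda()`) — the exponential of a quadratic in
$x - x^*$, with stimulus-specific polynomials $h_1, h_2$ for
$\psi_2 \equiv 1$ and $\psi_2 = t$.  The $h_2$ polynomials carry a
spurious $t^3/6$-type term relative to the exact $\lambda \to 0$ limit,
which is why the expansion is guarded to $\lambda t \le 0.3$ and validated
(to $3\times10^{-3}$) only for $\lambda t \le 0.05$; within that window
the agreement at the front is $\sim10^{-3}$ or better.

Front speeds are always computed as $\alpha(t, x^*(t))$ — consistent with
the characteristic ODE by construction — with the circulating closed-form
speed expressions available under `paper_verbatim = TRUE`.  The
qualitative conclusions are reproduced as booleans by
`front_speed_trend()`: raising uptake slows the high-nutrient wave and
speeds up the gradient-configuration wave.

# The finite-volume PDE oracle

`solve_scalar()` discretises the conservation form on a uniform grid of
cell averages: central second-order diffusion, van Leer slope-limited
upwind advection, boundary fluxes set *identically to zero* so the no-flux
conditions hold discretely — total mass is conserved to time-integrator
tolerance when $\beta \equiv 0$, which the suite asserts at $10^{-6}$.
The semi-discrete system is advanced by `deSolve`'s `lsoda` with a banded
numerical Jacobian (bandwidth 2; relative tolerance $10^{-8}$).  The
limiter is needed because at $D = 10^{-4}$–$10^{-3}$ the cell Péclet
number at affordable grids makes unlimited central advection oscillatory;
van Leer keeps positivity without the $\sim10^4$ cells central differencing
would need.  Defaults are 2000 cells for $D \ge 10^{-3}$ and 4000 below;
the observed convergence order on a smooth test is $\approx 2$.

`solve_coupled()` advances the interleaved $(u_i, v_i)$ state (bandwidth
5) with time-dependent Dirichlet values for $v$ entering through ghost
values, and consumption defaulting to
`uptake_per_cell(v, kinetics) * (K_cells + u)`.  The initial $v$
interpolates the channel values linearly; the fast temporal boundary layer
in which $v$ relaxes to quasi-steady state is not of interest, so coupled
comparisons use $t \ge 5/\Pi_3$.

Cross-validation: the solver was checked against an independent
node-centred central-difference discretisation of the non-conservative
form (agreement $10^{-5}$ at matched resolution) before being used as the
oracle.

# Validation surface and problem sizes

`list_fixtures()` catalogues the nine built-in parameter sets (linear
$a=2,b=1$; oscillatory $a=1,b=3,\omega=10$; exponential $a=2,\lambda=1$,
all at $D=10^{-3}$, $u_0=0.05$; the weak-consumption trio and the three
consumption scenarios at $k=1$, $\lambda=0.1$, $m_0=1$, $D=10^{-4}$ with
stimulus shapes $1$, $1+\cos 10\pi t$, $t$).  `reproduce_figure()`
regenerates each validation figure's data deterministically.

Evaluation times are the package's choice (the configurations fix
parameters, not plot times): the linear case uses $t \in \{0.2,0.4,0.5\}$
(front exits at $t = 0.549$), the exponential case $\{0.25, 0.5\}$, the
oscillatory case $\{0.08, 0.157, 0.22\}$ — within the first stimulus
half-period for the reason given above — and the scenario figures
$\{0.25, 0.5, 0.75\}$.  Composite-vs-PDE comparisons run on 2000-cell
grids (seconds per solve on one CPU) and exclude the declared right
boundary band; the whole suite, including all PDE runs, completes in
under two minutes.

What passing these comparisons shows — and what it does not: the fixtures
exercise heterogeneous, oscillatory and nonlinear-uptake stimuli, but all
with smooth deterministic coefficient fields, constant small seedings
($u_0 = 0.05 \ll 1$, on which several closed forms rely at $O(u_0^2)$),
and a one-dimensional geometry.  Real microdevice data add measurement
noise, nonuniform seeding and 2D effects that are outside this model
class.

# Numerical conventions

Quadrature is adaptive Gauss–Kronrod at absolute tolerance $10^{-10}$ and
relative $10^{-9}$ throughout; scenario densities use a fixed
characteristic grid with fourth-order cumulative Simpson integration
(grid chosen to resolve the fastest built-in stimulus, $\omega = 10\pi$,
with $>25$ points per period), which matches the adaptive nested
quadrature to $10^{-8}$ at a fraction of the cost.  The error function is
evaluated through the normal CDF identity.  All evaluators are
deterministic: no randomness exists anywhere in the package, so outputs
carry a determinism statement instead of a seed.  Characteristic crossing
(shock formation) is outside the studied regimes and raises an error
rather than being resolved.
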