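# Uniformly valid composite solution across the moving wavefront.
#
# Within the O(D) transition layer travelling with the front the dominant
# balance is diffusion vs. relative advection; with a Heaviside initial
# datum the rescaled layer profile is the erf kernel.  Matching it to the
# outer characteristic solution gives a composite approximation valid on
# the whole domain except a thin band at the right boundary (a classical
# unresolved boundary layer) and at x = 0 for very small times.

#' Inner transition-layer profile
#'
#' \deqn{U(X, \tau) = \tfrac12\left(1 + \mathrm{erf}\!\left(
#'   \frac{X}{2\sqrt{\tau}}\right)\right),}
#' the similarity solution of the layer diffusion equation with Heaviside
#' initial datum.  `U(0, tau) = 1/2`, and `U` increases monotonically from 0
#' to 1 in `X`.
#'
#' @param X Inner coordinate (x - x*(t)) / delta, vectorised.
#' @param tau Inner time, `> 0`; `tau <= 0` returns the Heaviside limit with
#'   a warning.
#' @export
inner_profile <- function(X, tau) {
  if (tau <= 0) {
    warning("tau <= 0: returning the Heaviside limit profile")
    return(ifelse(X > 0, 1, ifelse(X < 0, 0, 0.5)))
  }
  0.5 * (1 + .erf(X / (2 * sqrt(tau))))
}

#' Default right-boundary exclusion band
#'
#' The analytical solution loses accuracy in a thin band at `x = 1` where
#' the unresolved diffusive boundary layer lives.  The default band width is
#' `max(0.02, 10 * sqrt(D * T_max))`, ten nominal layer widths.
#'
#' @param D Diffusion coefficient.
#' @param T_max Time horizon.
#' @export
bl_exclusion_default <- function(D, T_max) max(0.02, 10 * sqrt(D * T_max))

#' Composite (inner + outer) cell density
#'
#' Uniformly valid approximation across the moving front:
#' \deqn{u(x,t) \sim \begin{cases}
#'  \tfrac12 u_{an}(x^*(t),t)\left(\mathrm{erf}\frac{x - x^*(t)}{2\sqrt{tD}}
#'    + 1\right), & x < x^*(t),\\
#'  \tfrac12 u_{an}(x^*(t),t)\left(\mathrm{erf}\frac{x - x^*(t)}{2\sqrt{tD}}
#'    - 1\right) + u_{an}(x,t), & x \ge x^*(t),
#' \end{cases}}
#' continuous at the front by construction (`G(t; x*(t)) = 0`).  The erf
#' argument is evaluated directly in outer variables, avoiding catastrophic
#' cancellation between the inner scalings.
#'
#' At `t = 0` the composite returns `u0(x) * 1{x > 0}` (the layer's
#' Heaviside initial datum).  Evaluations with `t < D` carry a `small_time`
#' attribute: the analogous `x = 0` small-time boundary layer is not
#' modelled.  Positions inside the right-boundary exclusion band are still
#' evaluated but flagged via the `boundary_layer` attribute.
#'
#' @param problem A `chemo_problem` with `D > 0`.
#' @param t Time (scalar, `>= 0`).
#' @param x Position(s).
#' @param bl_exclusion Width of the right-boundary band where accuracy is
#'   disclaimed; default [bl_exclusion_default()].
#' @param outer Optional function `(t, x) -> u_an` overriding the outer
#'   density evaluator (used by scenario reductions to plug in case
#'   formulas); defaults to [outer_density_general()].
#' @param layer Transition-layer width model.  `"strain"` (default)
#'   accounts for the advective strain \eqn{\alpha_x} stretching or
#'   compressing the layer as it rides the front: the erf variance is
#'   \eqn{\sigma^2(t) = 2D J(t)^2 \int_0^t J(\eta)^{-2} d\eta} with
#'   \eqn{J(t) = \exp(\int_0^t \alpha_x(\eta, x^*(\eta)) d\eta)} the
#'   Lagrangian stretch factor.  `"similarity"` is the pure-diffusion
#'   similarity width \eqn{2\sqrt{tD}} (to which the strain width reduces
#'   when \eqn{\alpha_x = 0}); it is retained for comparison but
#'   underestimates (overestimates) the true layer width once
#'   \eqn{\alpha_x t \gtrsim 1} (\eqn{\lesssim -1}); see the methods
#'   vignette for the quantitative comparison against the PDE oracle.
#' @return Density values with attributes `boundary_layer` (logical vector)
#'   and `small_time` (logical).
#' @export
composite_density <- function(problem, t, x, bl_exclusion = NULL,
                              outer = NULL,
                              layer = c("strain", "similarity")) {
  layer <- match.arg(layer)
  stopifnot(inherits(problem, "chemo_problem"), .is_scalar_number(t), t >= 0)
  D <- problem$D
  if (D <= 0) stop("composite density requires D > 0")
  if (is.null(bl_exclusion)) {
    bl_exclusion <- bl_exclusion_default(D, problem$T_max)
  }
  if (is.null(outer)) {
    outer <- function(tt, xx) outer_density_general(problem, tt, xx)
  }
  if (t == 0) {
    u <- problem$u0(x) * as.numeric(x > 0)
    attr(u, "boundary_layer") <- x > 1 - bl_exclusion
    attr(u, "small_time") <- TRUE
    return(u)
  }
  xs <- forward_map(problem$flux, t, 0)
  u_front <- outer(t, xs)
  width <- if (layer == "similarity") {
    2 * sqrt(t * D)
  } else {
    sqrt(2 * .strain_layer_var(problem$flux, t, D))
  }
  inner <- 0.5 * u_front * (.erf((x - xs) / width) + 1)
  u <- inner
  right <- x >= xs
  if (any(right)) {
    u[right] <- inner[right] - u_front + outer(t, x[right])
  }
  u <- pmax(u, 0)
  attr(u, "boundary_layer") <- x > 1 - bl_exclusion
  attr(u, "small_time") <- t < D
  u
}

# Lagrangian layer variance sigma^2(t) = 2 D J(t)^2 int_0^t J(eta)^-2 deta,
# J(t) = exp(int_0^t alpha_x(eta, x*(eta)) deta): the width of a diffusing
# profile advected with the front under spatially varying velocity.
.strain_layer_var <- function(flux, t, D) {
  Aint <- function(tt) {
    if (tt == 0) return(0)
    .quad(function(e) flux$alpha_x(e, forward_map(flux, e, 0)), 0, tt,
          rel.tol = 1e-8, abs.tol = 1e-10)
  }
  J2inv <- function(e) exp(-2 * Aint(e))
  2 * D * exp(2 * Aint(t)) * .quad(J2inv, 0, t, rel.tol = 1e-8,
                                   abs.tol = 1e-10)
}
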