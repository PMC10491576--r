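# Characteristic maps, front trajectories and outer densities.
#
# With D = 0 the transport equation is hyperbolic; along the characteristic
# through (0, s),
#   dx/dt = alpha(t, x),  x(0) = s,
# which defines the forward map x = F(t; s).  Its inverse in s, s = G(t; x),
# recovers the initial label of the characteristic through (t, x).  The
# invading front is the s = 0 characteristic, x*(t) = F(t; 0): to its left
# only the trivial (zero-density) boundary characteristics live, to its
# right the density follows a linear ODE in r = 1/u along characteristics.

# ---------------------------------------------------------------------------
# Closed-form map catalogue

# Returns list(F = function(t, s), G = function(t, x)) for flux fields whose
# structure admits closed forms, or NULL when integration is required.
# Both maps are exact inverses of one another by construction.
.closed_maps <- function(flux) {
  cat <- flux$catalogue
  if (is.null(cat)) return(NULL)
  Tfun <- flux$Tfun

  if (cat$kind == "affine") {
    a0 <- cat$a0; b0 <- cat$b0
    Ff <- function(t, s) {
      Tt <- Tfun(t)
      if (a0 == 0) s + b0 * Tt
      else s * exp(a0 * Tt) + b0 * expm1(a0 * Tt) / a0
    }
    Gf <- function(t, x) {
      Tt <- Tfun(t)
      if (a0 == 0) x - b0 * Tt
      else x * exp(-a0 * Tt) + b0 * expm1(-a0 * Tt) / a0
    }
    return(list(F = Ff, G = Gf))
  }

  if (cat$kind == "linear_aconst") {
    # alpha = a x + b(t), a constant: F = e^{at}(s + int_0^t b e^{-a eta}).
    a0 <- cat$a_const; bfun <- flux$b
    Ib <- function(t) {
      if (t == 0) return(0)
      .quad(function(e) bfun(e) * exp(-a0 * e), 0, t)
    }
    Ff <- function(t, s) exp(a0 * t) * (s + Ib(t))
    Gf <- function(t, x) x * exp(-a0 * t) - Ib(t)
    return(list(F = Ff, G = Gf))
  }

  if (cat$kind == "exp2" && cat$b == 0) {
    a <- cat$a; la <- cat$lambda
    Ff <- function(t, s) {
      arg <- a * la * Tfun(t) + exp(la * s)
      if (arg <= 0) stop("characteristic map undefined: nonpositive log argument")
      log(arg) / la
    }
    Gf <- function(t, x) {
      arg <- exp(la * x) - a * la * Tfun(t)
      if (arg <= 0) {
        stop("inverse map undefined at (t, x): point lies left of the front")
      }
      log(arg) / la
    }
    return(list(F = Ff, G = Gf))
  }

  if (cat$kind == "exp2") {
    # alpha = (a e^{-lx} + b e^{lx}) g(t), a,b > 0: arctan closed form.
    a <- cat$a; b <- cat$b; la <- cat$lambda
    if (a <= 0 || b <= 0) return(NULL)
    c0 <- sqrt(a * b)
    theta <- function(x) atan(sqrt(b / a) * exp(la * x))
    inv_theta <- function(th) {
      if (th <= 0 || th >= pi / 2) {
        stop("characteristic escaped: angle outside (0, pi/2)")
      }
      log(sqrt(a / b) * tan(th)) / la
    }
    Ff <- function(t, s) inv_theta(theta(s) + c0 * la * Tfun(t))
    Gf <- function(t, x) inv_theta(theta(x) - c0 * la * Tfun(t))
    return(list(F = Ff, G = Gf))
  }

  if (cat$kind == "cosh_grad") {
    # f = k sqrt(l) cosh(sqrt(l) x): S(t) = tan(k l T(t)/2) parameterisation.
    k <- cat$k; la <- cat$lambda; sl <- sqrt(la)
    Sfun <- function(t) {
      arg <- k * la * Tfun(t) / 2
      if (abs(arg) >= pi / 2) stop("front blow-up: |k lambda T(t)/2| >= pi/2")
      tan(arg)
    }
    Ff <- function(t, s) {
      S <- Sfun(t); E <- exp(-s * sl)
      den <- E - S
      if (den <= 0) stop("characteristic escaped to +infinity")
      log((1 + E * S) / den) / sl
    }
    Gf <- function(t, x) {
      S <- Sfun(t); E <- exp(-x * sl)
      num <- 1 - E * S
      if (num <= 0) stop("inverse map undefined: point lies left of the front")
      log(num / (E + S)) / sl
    }
    return(list(F = Ff, G = Gf, S = Sfun))
  }

  if (cat$kind == "sinh_sym") {
    # f = k sqrt(l) sinh(sqrt(l) x).  Integrating 1/f gives log(tanh), so the
    # exact maps use the inverse hyperbolic tangent (see the methods
    # vignette for the printed arctan variant kept for comparison).
    k <- cat$k; la <- cat$lambda; sl <- sqrt(la)
    Ff <- function(t, s) {
      w <- exp(k * la * Tfun(t)) * tanh(s * sl / 2)
      if (w >= 1) stop("characteristic escaped to +infinity")
      2 * atanh(w) / sl
    }
    Gf <- function(t, x) {
      w <- exp(-k * la * Tfun(t)) * tanh(x * sl / 2)
      2 * atanh(w) / sl
    }
    return(list(F = Ff, G = Gf))
  }

  NULL
}

# General linear a(t), b(t): quadrature implementation of the variation-of-
# constants forward map and its inverse.
.linear_quadrature_maps <- function(flux) {
  afun <- flux$a; bfun <- flux$b
  A <- function(t) if (t == 0) 0 else .quad(afun, 0, t)
  Ib <- function(t) {
    if (t == 0) return(0)
    .quad(function(e) bfun(e) * exp(-A(e)), 0, t)
  }
  list(F = function(t, s) exp(A(t)) * (s + Ib(t)),
       G = function(t, x) x * exp(-A(t)) - Ib(t))
}

# ---------------------------------------------------------------------------
# ODE fallbacks

# Integrate dx/dt = alpha(t, x) from (t0, x0) to times `times` (monotone,
# increasing or decreasing).  Returns positions at `times`.
.ode_characteristic <- function(flux, x0, t0, t1) {
  if (t1 == t0) return(x0)
  alpha <- flux$alpha
  sol <- deSolve::ode(y = c(x = x0), times = c(t0, t1),
                      func = function(t, y, p) list(alpha(t, y[1])),
                      rtol = 1e-10, atol = 1e-12, method = "lsoda")
  unname(sol[nrow(sol), "x"])
}

# Bracketed root-solve of Eq.-(9) type relations int_s^x dz/f = T(t) for the
# separable structure without a catalogue entry.
.separable_root_forward <- function(flux, t, s) {
  f <- flux$f
  target <- flux$Tfun(t)
  if (target == 0) return(s)
  phi <- function(x) .quad(function(z) 1 / f(z), s, x)
  # expand the bracket in the direction of motion
  dir <- sign(target) * sign(f(s))
  if (dir == 0) stop("f(s) = 0: characteristic is stationary")
  step <- 0.1
  lo <- s; hi <- s + dir * step
  val <- phi(hi) - target
  n_try <- 0
  while (sign(val) == sign(phi(lo) - target) && n_try < 60) {
    lo <- hi; hi <- hi + dir * step; step <- step * 1.5
    val <- phi(hi) - target
    n_try <- n_try + 1
    if (abs(hi) > 50) stop("root-solve bracket failure in forward map")
  }
  if (n_try >= 60) stop("root-solve bracket failure in forward map")
  stats::uniroot(function(x) phi(x) - target, lower = min(lo, hi),
                 upper = max(lo, hi), tol = 1e-12)$root
}

# ---------------------------------------------------------------------------
# Public operations

#' Forward characteristic map F(t; s)
#'
#' Position at time `t` of the characteristic that started at `x = s`,
#' i.e. the solution of \eqn{dx/dt = \alpha(t, x)}, \eqn{x(0) = s}.  Closed
#' forms are used for the built-in flux catalogue (affine, exponential,
#' hyperbolic profiles); the generic separable case uses a monotone
#' bracketed root-solve of the separable characteristic relation, and the
#' fully general case integrates the characteristic ODE adaptively
#' (tolerance `1e-10`).
#'
#' @param flux A `chemo_flux`.
#' @param t Time (scalar).
#' @param s Initial label(s) in `[0, 1]` (vectorised).
#' @return Position(s) `x = F(t; s)`.
#' @export
forward_map <- function(flux, t, s) {
  stopifnot(inherits(flux, "chemo_flux"), .is_scalar_number(t))
  maps <- .closed_maps(flux)
  one <- function(si) {
    if (t == 0) return(si)
    if (!is.null(maps)) return(maps$F(t, si))
    if (flux$structure == "linear_in_x") {
      return(.linear_quadrature_maps(flux)$F(t, si))
    }
    if (flux$structure == "separable") {
      return(.separable_root_forward(flux, t, si))
    }
    .ode_characteristic(flux, si, 0, t)
  }
  vapply(s, one, numeric(1))
}

#' Inverse characteristic map G(t; x)
#'
#' Initial label `s` of the (first-family) characteristic through `(t, x)`.
#' Closed forms invert `F` exactly where available; the fallback integrates
#' the characteristic ODE backwards in time from `(t, x)` to `t = 0`, which
#' is the exact inverse by time-reversibility.  Points strictly left of the
#' front `x*(t)` belong to the second (boundary) characteristic family,
#' where the density is identically zero; there `G` is undefined and an
#' error is signalled.
#'
#' @inheritParams forward_map
#' @param x Position(s), must satisfy `x >= x*(t)`.
#' @return Label(s) `s = G(t; x)`.
#' @export
inverse_map <- function(flux, t, x) {
  stopifnot(inherits(flux, "chemo_flux"), .is_scalar_number(t))
  maps <- .closed_maps(flux)
  one <- function(xi) {
    if (t == 0) return(xi)
    if (!is.null(maps)) {
      s <- maps$G(t, xi)
    } else if (flux$structure == "linear_in_x") {
      s <- .linear_quadrature_maps(flux)$G(t, xi)
    } else {
      s <- .ode_characteristic(flux, xi, t, 0)
    }
    s
  }
  s <- vapply(x, one, numeric(1))
  if (any(s < -1e-8)) {
    stop("x < x*(t): point lies in the second characteristic family ",
         "(zero-density region); the inverse map is undefined there")
  }
  s
}

#' Characteristic map object
#'
#' Bundles the forward map, inverse map and cumulative stimulus of a flux
#' field.
#'
#' @inheritParams forward_map
#' @return List with elements `F(t, s)`, `G(t, x)`, `Tfun`, `mode`
#'   (`"closed_form"` or `"numeric"`) and `s_range`.
#' @export
characteristic_map <- function(flux) {
  maps <- .closed_maps(flux)
  mode <- if (!is.null(maps)) "closed_form" else "numeric"
  structure(list(F = function(t, s) forward_map(flux, t, s),
                 G = function(t, x) inverse_map(flux, t, x),
                 Tfun = flux$Tfun, mode = mode, s_range = c(0, 1)),
            class = "chemo_charmap")
}

#' Front trajectory x*(t)
#'
#' The invading wavefront is the characteristic emanating from the origin:
#' \eqn{x^*(t) = F(t; 0)}.  Its speed is evaluated as
#' \eqn{\alpha(t, x^*(t))} — the characteristic ODE itself — rather than by
#' differentiating printed case formulas, so the speed is consistent with
#' the map by construction.
#'
#' @inheritParams forward_map
#' @param T_max Horizon over which to search for the domain exit time.
#' @return List with `x_star(t)`, `speed(t)` (both vectorised over `t`) and
#'   `exit_time` (smallest `t` with `x*(t) >= 1`, or `NA` if the front stays
#'   inside the domain up to `T_max`).
#' @export
front <- function(flux, T_max = 1) {
  stopifnot(inherits(flux, "chemo_flux"))
  a00 <- flux$alpha(0, 0)
  if (abs(a00) < 1e-14 && abs(flux$alpha(min(1e-3, T_max / 10), 0)) < 1e-14) {
    warning("alpha(t, 0) = 0 near t = 0: the front does not detach from ",
            "the origin (x*(t) = 0)")
  }
  x_star <- function(t) vapply(t, function(ti) forward_map(flux, ti, 0),
                               numeric(1))
  speed <- function(t) vapply(t, function(ti) {
    flux$alpha(ti, forward_map(flux, ti, 0))
  }, numeric(1))
  exit_time <- NA_real_
  tg <- seq(0, T_max, length.out = 65)
  xg <- tryCatch(x_star(tg), error = function(e) NULL)
  if (is.null(xg)) {
    # map blow-up inside the horizon: locate the exit by bisection on
    # evaluability + crossing
    ok <- vapply(tg, function(ti) {
      !inherits(tryCatch(forward_map(flux, ti, 0), error = identity),
                "error")
    }, logical(1))
    tg <- tg[ok]; xg <- x_star(tg)
  }
  if (length(xg) && any(xg >= 1)) {
    i <- which(xg >= 1)[1]
    if (i == 1) {
      exit_time <- 0
    } else {
      exit_time <- stats::uniroot(function(ti) x_star(ti) - 1,
                                  lower = tg[i - 1], upper = tg[i],
                                  tol = 1e-12)$root
    }
  }
  structure(list(x_star = x_star, speed = speed, exit_time = exit_time,
                 T_max = T_max),
            class = "chemo_front")
}

# ---------------------------------------------------------------------------
# Outer densities

# h(eta; s): the flux-divergence coefficient along the characteristic.
# linear:    h = a(eta)
# separable: h = f'(F(eta; s)) g(eta)
# general:   h = alpha_x(eta, F(eta; s))
.h_along <- function(flux, path) {
  if (flux$structure == "linear_in_x") {
    function(eta) flux$a(eta)
  } else if (flux$structure == "separable") {
    function(eta) flux$fprime(path(eta)) * flux$g(eta)
  } else {
    function(eta) flux$alpha_x(eta, path(eta))
  }
}

# Characteristic path eta -> F(eta; s) as a cheap function: closed form when
# available, otherwise one dense ODE solve + spline.
.char_path <- function(flux, s, t) {
  maps <- .closed_maps(flux)
  if (!is.null(maps)) return(function(eta) maps$F(eta, s))
  if (flux$structure == "linear_in_x") {
    lm <- .linear_quadrature_maps(flux)
    return(function(eta) lm$F(eta, s))
  }
  if (t == 0) return(function(eta) rep_len(s, length(eta)))
  times <- seq(0, t, length.out = 401)
  sol <- deSolve::ode(y = c(x = s), times = times,
                      func = function(tt, y, p) list(flux$alpha(tt, y[1])),
                      rtol = 1e-10, atol = 1e-12, method = "lsoda")
  stats::splinefun(sol[, "time"], sol[, "x"], method = "natural")
}

#' Outer cell density (characteristic quadrature form)
#'
#' Evaluates the small-diffusion outer density right of the front by
#' quadrature along the characteristic through `(t, x)`:
#' \deqn{u(x,t) = \frac{u_0(s)\, e^{\int_0^t p}}{1 + u_0(s)\int_0^t q\,
#'   e^{\int_0^\eta p}\, d\eta}, \quad s = G(t;x),}
#' with \eqn{p = \beta - h}, \eqn{q = \beta} and \eqn{h} the flux divergence
#' along the characteristic.  Left of the front (`x < x*(t)`) the density is
#' identically zero (second characteristic family).
#'
#' @param problem A `chemo_problem`.
#' @param t Time (scalar).
#' @param x Position(s) (vectorised).
#' @return Density value(s); a negative result aborts, as it signals an
#'   implementation defect rather than a model property.
#' @export
outer_density_general <- function(problem, t, x) {
  stopifnot(inherits(problem, "chemo_problem"), .is_scalar_number(t))
  flux <- problem$flux
  beta <- problem$growth$beta
  if (t == 0) return(problem$u0(x))
  xs <- forward_map(flux, t, 0)
  one <- function(xi) {
    if (xi < xs - 1e-12) return(0)
    s <- inverse_map(flux, t, max(xi, xs))
    path <- .char_path(flux, s, t)
    h <- .h_along(flux, path)
    p <- function(eta) beta(eta, path(eta)) - h(eta)
    q <- function(eta) beta(eta, path(eta))
    Pint <- function(eta) if (eta == 0) 0 else .quad(p, 0, eta)
    num <- problem$u0(s) * exp(Pint(t))
    den <- 1 + problem$u0(s) * .quad(function(eta) q(eta) * exp(Pint(eta)), 0, t)
    num / den
  }
  u <- vapply(x, one, numeric(1))
  if (any(u < 0)) stop("negative outer density: implementation defect")
  u
}

#' Outer density, special separable closed form
#'
#' For a time-independent separable flux (\eqn{\alpha = f(x)}), unit growth
#' and small uniform seeding the outer density collapses to
#' \deqn{u(x,t) = u_0(G(t;x))\, e^{t}\, f(G(t;x)) / f(x),}
#' accurate to \eqn{O(u_0^2)} relative to [outer_density_general()].
#'
#' @param flux A time-independent separable `chemo_flux`.
#' @param u0 Initial density (number or function of `x`).
#' @inheritParams outer_density_general
#' @export
outer_density_separable_special <- function(flux, u0, t, x) {
  stopifnot(inherits(flux, "chemo_flux"))
  if (flux$structure != "separable") {
    stop("the special form requires a separable flux")
  }
  if (abs(flux$g(0.123) - 1) > 1e-12 || abs(flux$g(0.71) - 1) > 1e-12) {
    stop("the special form requires a time-independent flux (g = 1)")
  }
  u0f <- if (.is_scalar_number(u0)) {
    if (u0 > 0.1) warning("u0 > 0.1: O(u0^2) error of the special form may be large")
    local({ v <- u0; function(x) rep_len(v, length(x)) })
  } else u0
  vapply(x, function(xi) {
    s <- inverse_map(flux, t, xi)
    fx <- flux$f(xi)
    if (fx == 0) stop("f(x) = 0 at the evaluation point")
    u0f(s) * exp(t) * flux$f(s) / fx
  }, numeric(1))
}

#' Plateau density for the linear flux case
#'
#' For \eqn{\alpha = (a x + b)} (time-independent), \eqn{\beta \equiv 1} and
#' uniform seeding the outer density is spatially constant right of the
#' front:
#' \deqn{u(t) = \frac{u_0 (a-1) e^{-(a-1)t}}{a - 1 + u_0(1 - e^{-(a-1)t})},}
#' with the limit \eqn{u_0/(1 + u_0 t)} as \eqn{a \to 1} (the printed form
#' is 0/0 there; the series switch happens at `|a - 1| < 1e-8`).
#'
#' @param a Slope of the linear flux.
#' @param u0 Uniform initial density.
#' @param t Time(s).
#' @export
plateau_density_linear <- function(a, u0, t) {
  if (abs(a - 1) < 1e-8) return(u0 / (1 + u0 * t))
  am1 <- a - 1
  u0 * am1 * exp(-am1 * t) / (am1 + u0 * (1 - exp(-am1 * t)))
}

#' Singularity bound for the single-source exponential case
#'
#' For \eqn{\alpha = a e^{-\lambda x} g(t)} the closed-form outer density has
#' denominator \eqn{1 - a\lambda\mathcal{T}(t) e^{-\lambda x}}.  This
#' function returns its minimum over a grid of `x >= x*(t)` together with
#' the analytic lower bound \eqn{1/(1 + a\lambda\mathcal{T}(t))}, which is
#' strictly positive: the density never blows up right of the front.
#'
#' @param a,lambda Exponential flux parameters (`b = 0` case).
#' @param t Time.
#' @param g Temporal stimulus (default constant 1).
#' @param n_grid Number of grid points for the minimisation.
#' @return List with `min_value`, `bound` and `x_at_min`.
#' @export
no_singularity_check <- function(a, lambda, t, g = NULL, n_grid = 401) {
  flux <- flux_exponential(a, lambda, b = 0, g = g)
  Tt <- flux$Tfun(t)
  xs <- forward_map(flux, t, 0)
  xg <- seq(xs, xs + 2, length.out = n_grid)
  vals <- 1 - a * lambda * Tt * exp(-lambda * xg)
  i <- which.min(vals)
  list(min_value = vals[i], bound = 1 / (1 + a * lambda * Tt),
       x_at_min = xg[i])
}
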