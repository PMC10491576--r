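# Flux, growth and stimulus fields.
#
# The chemotactic flux coefficient alpha(t, x) enters the cell transport
# equation
#   u_t + (alpha(t,x) u)_x = D u_xx + beta(t,x) u (1 - u)
# as the advection velocity induced by the chemoattractant gradient.  Its
# structure (linear in x, separable in space/time, or fully general)
# determines how much closed-form machinery is available downstream, so flux
# objects carry a structural tag alongside the generic evaluator.

# ---------------------------------------------------------------------------
# Temporal stimuli g(t) and their cumulative integral

#' Temporal stimulus functions with known antiderivatives
#'
#' Builders for the temporal modulation \eqn{g(t)} of a chemotactic flux (or
#' the channel stimulus \eqn{\psi(t)} of a microdevice scenario).  Each
#' returns an ordinary function of time carrying an `antiderivative`
#' attribute, which [cumulative_stimulus()] uses to evaluate
#' \eqn{\mathcal{T}(t)=\int_0^t g(\eta)\,d\eta} in closed form instead of by
#' quadrature.
#'
#' @param value,omega Constant level, respectively angular frequency.
#' @return A vectorised function of `t` with attribute `"antiderivative"`.
#' @examples
#' g <- stimulus_cos(10)
#' cumulative_stimulus(g, pi / 20)  # sin(pi/2)/10 = 0.1
#' @export
stimulus_constant <- function(value = 1) {
  force(value)
  structure(function(t) rep_len(value, length(t)),
            antiderivative = function(t) value * t,
            stimulus = sprintf("constant(%g)", value))
}

#' @rdname stimulus_constant
#' @export
stimulus_cos <- function(omega) {
  force(omega)
  structure(function(t) cos(omega * t),
            antiderivative = function(t) sin(omega * t) / omega,
            stimulus = sprintf("cos(%g t)", omega))
}

#' @rdname stimulus_constant
#' @export
stimulus_one_plus_cos <- function(omega = 10 * pi) {
  force(omega)
  structure(function(t) 1 + cos(omega * t),
            antiderivative = function(t) t + sin(omega * t) / omega,
            stimulus = sprintf("1+cos(%g t)", omega))
}

#' @rdname stimulus_constant
#' @export
stimulus_ramp <- function() {
  structure(function(t) t,
            antiderivative = function(t) t^2 / 2,
            stimulus = "ramp t")
}

#' Cumulative stimulus T(t)
#'
#' Evaluates \eqn{\mathcal{T}(t) = \int_0^t g(\eta)\, d\eta}, the cumulative
#' temporal stimulus that parameterises every closed-form characteristic map.
#' A closed form is used when `g` carries an `antiderivative` attribute (as
#' the [stimulus_constant()] family does); otherwise adaptive quadrature with
#' absolute tolerance `1e-10` is used.
#'
#' @param g Temporal stimulus function (or a single number for a constant
#'   stimulus).
#' @param t Time(s), must be `>= 0`.
#' @return `T(t)`, vectorised over `t`.
#' @export
cumulative_stimulus <- function(g, t) {
  if (any(t < 0)) stop("'t' must be nonnegative")
  Tfun <- make_cumulative_stimulus(g)
  Tfun(t)
}

#' @rdname cumulative_stimulus
#' @return `make_cumulative_stimulus` returns the function
#'   \eqn{t \mapsto \mathcal{T}(t)} itself, with a `method` attribute that is
#'   either `"closed_form"` or `"adaptive_quadrature"`.
#' @export
make_cumulative_stimulus <- function(g) {
  g <- .as_fun1(g, "g")
  anti <- attr(g, "antiderivative")
  if (is.function(anti)) {
    Tfun <- function(t) anti(t) - anti(0)
    method <- "closed_form"
  } else {
    Tfun <- function(t) {
      vapply(t, function(ti) {
        if (ti == 0) 0 else .quad(g, 0, ti, rel.tol = 1e-10, abs.tol = 1e-10)
      }, numeric(1))
    }
    method <- "adaptive_quadrature"
  }
  structure(Tfun, method = method, class = c("chemo_stimulus_integral", "function"))
}

# ---------------------------------------------------------------------------
# Flux fields

#' Construct a chemotactic flux field
#'
#' Creates a `chemo_flux` object representing the chemotactic advective
#' velocity \eqn{\alpha(t,x)}.  Three structures are supported:
#'
#' * `"linear_in_x"`: \eqn{\alpha = a(t)x + b(t)}.  When `a` and `b` are
#'   constants times a common temporal stimulus `g`, i.e.
#'   \eqn{\alpha=(a_0 x + b_0) g(t)}, the characteristic maps have closed
#'   forms in terms of the cumulative stimulus.
#' * `"separable"`: \eqn{\alpha = f(x) g(t)}.  Built-in spatial profiles
#'   (exponential, hyperbolic cosine/sine) unlock closed-form maps; see
#'   [flux_exponential()], [flux_cosh_gradient()], [flux_sinh_symmetric()].
#' * `"general"`: arbitrary \eqn{\alpha(t,x)}; characteristics are obtained
#'   by adaptive ODE integration.
#'
#' `alpha_x` (the spatial derivative, needed by the density equations) is
#' taken analytically where the structure provides it; otherwise a central
#' finite difference with step `1e-6` is used and flagged via the
#' `alpha_x_is_fd` field so accuracy-sensitive code can refuse it.
#' Coefficient functions must be pure (deterministic, side-effect free) so
#' characteristic integration is reproducible.
#'
#' @param structure One of `"linear_in_x"`, `"separable"`, `"general"`.
#' @param a,b Slope and offset for the linear structure: single numbers
#'   (optionally with a shared temporal stimulus `g`) or functions of `t`.
#' @param f,fprime Spatial factor and its derivative for the separable
#'   structure.
#' @param g Temporal stimulus function (default constant 1).
#' @param alpha,alpha_x Evaluators for the general structure.
#' @return A `chemo_flux` object; evaluate it with `field$alpha(t, x)`.
#' @examples
#' fl <- make_flux("linear_in_x", a = 2, b = 1)
#' fl$alpha(0.3, 0.5)  # 2*0.5 + 1 = 2
#' @export
make_flux <- function(structure = c("linear_in_x", "separable", "general"),
                      a = NULL, b = NULL, f = NULL, fprime = NULL,
                      g = NULL, alpha = NULL, alpha_x = NULL) {
  structure <- match.arg(structure)
  switch(structure,
         linear_in_x = flux_linear(a = a, b = b, g = g),
         separable   = flux_separable(f = f, g = g, fprime = fprime),
         general     = flux_general(alpha = alpha, alpha_x = alpha_x))
}

.new_flux <- function(structure, alpha_fn, alpha_x_fn,
                      alpha_x_is_fd = FALSE, extra = list()) {
  obj <- c(list(structure = structure, alpha = alpha_fn,
                alpha_x = alpha_x_fn, alpha_x_is_fd = alpha_x_is_fd),
           extra)
  class(obj) <- "chemo_flux"
  obj
}

#' @export
print.chemo_flux <- function(x, ...) {
  cat("<chemo_flux> structure:", x$structure,
      if (!is.null(x$catalogue)) paste0("(catalogue: ", x$catalogue$kind, ")"),
      "\n")
  invisible(x)
}

#' Linear-in-x flux field
#'
#' \eqn{\alpha(t,x) = a(t)x + b(t)}.  With scalar `a`, `b` and a stimulus
#' `g`, this is the catalogue form \eqn{(a_0 x + b_0)g(t)} whose forward map
#' is \eqn{F(t;s) = \frac{1}{a_0}[(a_0 s + b_0)e^{a_0\mathcal{T}(t)} - b_0]}.
#'
#' @inheritParams make_flux
#' @export
flux_linear <- function(a, b, g = NULL) {
  if (is.null(a) || is.null(b)) stop("linear flux requires 'a' and 'b'")
  if (.is_scalar_number(a) && .is_scalar_number(b)) {
    gfun <- if (is.null(g)) stimulus_constant(1) else .as_fun1(g, "g")
    Tfun <- make_cumulative_stimulus(gfun)
    a0 <- a; b0 <- b
    alpha <- function(t, x) (a0 * x + b0) * gfun(t)
    alpha_x <- function(t, x) rep_len(a0 * gfun(t), length(x))
    return(.new_flux("linear_in_x", alpha, alpha_x, extra = list(
      a = function(t) a0 * gfun(t),
      b = function(t) b0 * gfun(t),
      g = gfun, Tfun = Tfun,
      catalogue = list(kind = "affine", a0 = a0, b0 = b0))))
  }
  if (!is.null(g)) {
    stop("a separate 'g' is only supported with scalar 'a' and 'b'; ",
         "fold the stimulus into a(t) and b(t) otherwise")
  }
  afun <- .as_fun1(a, "a"); bfun <- .as_fun1(b, "b")
  alpha <- function(t, x) afun(t) * x + bfun(t)
  alpha_x <- function(t, x) rep_len(afun(t), length(x))
  .new_flux("linear_in_x", alpha, alpha_x,
            extra = list(a = afun, b = bfun, catalogue = NULL))
}

#' Separable flux field
#'
#' \eqn{\alpha(t,x) = f(x) g(t)}.  If `fprime` is not supplied it is
#' replaced by a central finite difference (step `1e-6`) and the field is
#' flagged `alpha_x_is_fd = TRUE`.
#'
#' @inheritParams make_flux
#' @param catalogue Internal: structural tag for built-in spatial profiles.
#' @export
flux_separable <- function(f, g = NULL, fprime = NULL, catalogue = NULL) {
  .stopifnot_callable(f, "f")
  gfun <- if (is.null(g)) stimulus_constant(1) else .as_fun1(g, "g")
  Tfun <- make_cumulative_stimulus(gfun)
  fd <- is.null(fprime)
  if (fd) {
    fprime <- function(x) (f(x + 1e-6) - f(x - 1e-6)) / 2e-6
  }
  alpha <- function(t, x) f(x) * gfun(t)
  alpha_x <- function(t, x) fprime(x) * gfun(t)
  .new_flux("separable", alpha, alpha_x, alpha_x_is_fd = fd,
            extra = list(f = f, fprime = fprime, g = gfun, Tfun = Tfun,
                         catalogue = catalogue))
}

#' Exponential-gradient flux field
#'
#' \eqn{\alpha(t,x) = (a e^{-\lambda x} + b e^{\lambda x})\,g(t)}, the
#' separable profile generated by diffusion from localised chemoattractant
#' sources.  For `b = 0` the characteristic maps reduce to
#' \eqn{F(t;s)=\frac{1}{\lambda}\ln(a\lambda\mathcal{T}(t)+e^{\lambda s})}.
#'
#' @param a,b Source amplitudes (`b = 0` gives the single-source profile).
#' @param lambda Spatial decay rate (`lambda_grad`), > 0.
#' @inheritParams make_flux
#' @export
flux_exponential <- function(a, lambda, b = 0, g = NULL) {
  stopifnot(.is_scalar_number(a), .is_scalar_number(lambda), lambda > 0,
            .is_scalar_number(b))
  f <- function(x) a * exp(-lambda * x) + b * exp(lambda * x)
  fp <- function(x) -a * lambda * exp(-lambda * x) + b * lambda * exp(lambda * x)
  flux_separable(f, g, fp,
                 catalogue = list(kind = "exp2", a = a, b = b, lambda = lambda))
}

#' Hyperbolic flux fields of the low-nutrient microdevice scenarios
#'
#' `flux_cosh_gradient()` builds
#' \eqn{\alpha(t,x) = k\sqrt{\lambda}\cosh(\sqrt{\lambda}x)\,\psi(t)}, the
#' flux induced by the gradient configuration \eqn{v=\psi(t)\sinh(\sqrt\lambda x)}
#' of the nutrient field; `flux_sinh_symmetric()` builds
#' \eqn{\alpha(t,x) = k\sqrt{\lambda}\sinh(\sqrt{\lambda}x)\,\psi(t)} for the
#' symmetric configuration \eqn{v=\psi(t)\cosh(\sqrt\lambda x)}.
#'
#' @param k Chemotaxis strength.
#' @param lambda Scaled uptake rate (`lambda_uptake`), > 0.
#' @param psi Channel stimulus \eqn{\psi(t)} (default constant 1).
#' @export
flux_cosh_gradient <- function(k, lambda, psi = NULL) {
  stopifnot(.is_scalar_number(k), .is_scalar_number(lambda), lambda > 0)
  sl <- sqrt(lambda)
  f <- function(x) k * sl * cosh(sl * x)
  fp <- function(x) k * lambda * sinh(sl * x)
  flux_separable(f, psi, fp,
                 catalogue = list(kind = "cosh_grad", k = k, lambda = lambda))
}

#' @rdname flux_cosh_gradient
#' @export
flux_sinh_symmetric <- function(k, lambda, psi = NULL) {
  stopifnot(.is_scalar_number(k), .is_scalar_number(lambda), lambda > 0)
  sl <- sqrt(lambda)
  f <- function(x) k * sl * sinh(sl * x)
  fp <- function(x) k * lambda * cosh(sl * x)
  flux_separable(f, psi, fp,
                 catalogue = list(kind = "sinh_sym", k = k, lambda = lambda))
}

#' General flux field
#'
#' Arbitrary \eqn{\alpha(t,x)}; characteristics fall back to adaptive ODE
#' integration.  Supply `alpha_x` analytically where possible: the finite
#' difference fallback is flagged and refused by accuracy-critical code.
#'
#' @inheritParams make_flux
#' @export
flux_general <- function(alpha, alpha_x = NULL) {
  .stopifnot_callable(alpha, "alpha")
  fd <- is.null(alpha_x)
  if (fd) {
    alpha_x <- function(t, x) (alpha(t, x + 1e-6) - alpha(t, x - 1e-6)) / 2e-6
  }
  .new_flux("general", alpha, alpha_x, alpha_x_is_fd = fd)
}

# Linear flux with constant slope a_const and general offset b(t):
# alpha = a_const * x + b(t).  This is the high-nutrient scenario structure
# and keeps Eq.-(8)-type closed forms with T(t) replaced by t.
flux_linear_aconst <- function(a_const, b) {
  stopifnot(.is_scalar_number(a_const))
  bfun <- .as_fun1(b, "b")
  alpha <- function(t, x) a_const * x + bfun(t)
  alpha_x <- function(t, x) rep_len(a_const, length(x))
  .new_flux("linear_in_x", alpha, alpha_x, extra = list(
    a = function(t) rep_len(a_const, length(t)), b = bfun,
    catalogue = list(kind = "linear_aconst", a_const = a_const)))
}

# ---------------------------------------------------------------------------
# Growth fields and model problems

#' Growth modulation field
#'
#' The per-capita logistic growth rate \eqn{\beta(t,x) \ge 0}, optionally
#' derived from a nutrient-modulation function \eqn{m(v)} (with the linear
#' special case \eqn{m(v) = m_0 v} used throughout the microdevice
#' scenarios).
#'
#' @param beta Function `(t, x) -> rate` or a single nonnegative number.
#' @param m Optional modulation function of the nondimensional nutrient `v`.
#' @param m0 Optional scalar for the linear modulation `m(v) = m0 * v`.
#' @export
growth_field <- function(beta = 1, m = NULL, m0 = NULL) {
  if (.is_scalar_number(beta)) {
    if (beta < 0) stop("constant growth rate must be >= 0")
    b0 <- beta
    bfun <- function(t, x) rep_len(b0, length(x))
    constant <- b0
  } else {
    .stopifnot_callable(beta, "beta")
    bfun <- beta
    constant <- NULL
  }
  if (!is.null(m0) && is.null(m)) {
    m <- local({ m0l <- m0; function(v) m0l * v })
  }
  structure(list(beta = bfun, m = m, m0 = m0, constant = constant),
            class = "chemo_growth")
}

#' @rdname growth_field
#' @export
growth_constant <- function(beta = 1) growth_field(beta = beta)

#' Model problem for the chemotactic invasion equation
#'
#' Bundles the nondimensional diffusion coefficient `D`, a flux field, a
#' growth field, the initial density and the time horizon into one object
#' consumed by the analytical machinery and the PDE solver.  The spatial
#' domain is fixed to `[0, 1]` (the nondimensionalised chamber width).
#'
#' @param flux A `chemo_flux`.
#' @param growth A `chemo_growth` (default: constant rate 1).
#' @param u0 Initial density: a function of `x` with values in `[0, 1]`, or
#'   a single number for a uniform seeding.
#' @param D Nondimensional diffusion coefficient, `>= 0` (`0` selects the
#'   hyperbolic limit used by the outer solution).
#' @param T_max Time horizon.
#' @export
model_problem <- function(flux, growth = growth_constant(), u0 = 0.05,
                          D = 1e-3, T_max = 1) {
  stopifnot(inherits(flux, "chemo_flux"), inherits(growth, "chemo_growth"),
            .is_scalar_number(D), D >= 0, .is_scalar_number(T_max), T_max > 0)
  u0_constant <- NULL
  if (.is_scalar_number(u0)) {
    if (u0 < 0 || u0 > 1) stop("constant u0 must lie in [0, 1]")
    u0_constant <- u0
    u0v <- u0
    u0 <- function(x) rep_len(u0v, length(x))
  } else {
    .stopifnot_callable(u0, "u0")
    probe <- u0(seq(0, 1, length.out = 101))
    if (any(probe < -1e-12 | probe > 1 + 1e-12)) {
      stop("u0(x) must lie in [0, 1] on the domain")
    }
  }
  structure(list(flux = flux, growth = growth, u0 = u0,
                 u0_constant = u0_constant, D = D, T_max = T_max),
            class = "chemo_problem")
}

#' @export
print.chemo_problem <- function(x, ...) {
  cat("<chemo_problem> D =", x$D, " T_max =", x$T_max,
      " flux:", x$flux$structure, "\n")
  invisible(x)
}
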