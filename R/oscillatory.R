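# Plateau density under oscillating linear gradients.
#
# When alpha = (a x + b) cos(omega t) the flux divergence a cos(omega t) is
# x-independent, so right of the front the density is spatially constant
# ("the plateau") and r = 1/u obeys the linear ODE
#   r' + (beta - a cos(omega t)) r = beta,   r(0) = 1/u0.
# The module solves this exactly (integrating factor + quadrature),
# numerically (adaptive RK, the oracle) and in four asymptotic regimes.

#' Oscillatory plateau problem
#'
#' @param a Oscillation amplitude of the chemotactic flux divergence.
#' @param omega Angular frequency of the stimulus.
#' @param beta Constant growth rate (the canonical plateau equation has
#'   `beta = 1`; the generalisation `r' + (beta - a cos(omega t)) r = beta`
#'   reduces to it and supports the regime analysis).
#' @param u0 Initial plateau density, `> 0`.
#' @export
oscillatory_problem <- function(a, omega, beta = 1, u0 = 0.05) {
  stopifnot(.is_scalar_number(a), .is_scalar_number(omega), omega != 0,
            .is_scalar_number(beta), beta >= 0,
            .is_scalar_number(u0), u0 > 0)
  structure(list(a = a, omega = omega, beta = beta, u0 = u0),
            class = "chemo_oscillatory")
}

#' Exact plateau density (integrating factor)
#'
#' \deqn{r(t) = e^{-\beta t + \frac{a}{\omega}\sin\omega t}\left[
#'   \frac{1}{u_0} + \int_0^t \beta\, e^{\beta\eta -
#'   \frac{a}{\omega}\sin\omega\eta}\, d\eta\right], \quad u = 1/r,}
#' with the integral evaluated by adaptive quadrature.  For `a = 0` this is
#' the logistic solution.
#'
#' @param prob An [oscillatory_problem()].
#' @param t Time(s), `>= 0`.
#' @export
exact_plateau_density <- function(prob, t) {
  stopifnot(inherits(prob, "chemo_oscillatory"))
  if (any(t < 0)) stop("'t' must be nonnegative")
  a <- prob$a; om <- prob$omega; be <- prob$beta; u0 <- prob$u0
  vapply(t, function(ti) {
    if (ti == 0) return(u0)
    I <- .quad(function(e) be * exp(be * e - (a / om) * sin(om * e)), 0, ti)
    r <- exp(-be * ti + (a / om) * sin(om * ti)) * (1 / u0 + I)
    1 / r
  }, numeric(1))
}

#' Numerical plateau density (adaptive Runge-Kutta oracle)
#'
#' Solves the plateau equation for `r = 1/u` with `deSolve` at relative
#' tolerance `1e-10`.  This is the ground-truth oracle against which the
#' exact quadrature form and the regime approximations are validated.
#'
#' @inheritParams exact_plateau_density
#' @param t_grid Increasing vector of output times starting at values
#'   `>= 0`.
#' @return A data.frame with columns `t` and `u`.
#' @export
numeric_plateau_density <- function(prob, t_grid) {
  stopifnot(inherits(prob, "chemo_oscillatory"), !is.unsorted(t_grid))
  a <- prob$a; om <- prob$omega; be <- prob$beta
  times <- unique(c(0, t_grid))
  sol <- deSolve::ode(y = c(r = 1 / prob$u0), times = times,
                      func = function(t, y, p) {
                        list(be - (be - a * cos(om * t)) * y[1])
                      },
                      rtol = 1e-10, atol = 1e-12, method = "lsoda")
  u <- 1 / sol[, "r"]
  data.frame(t = sol[, "time"], u = u)[match(t_grid, sol[, "time"]), ,
                                       drop = FALSE]
}

#' Asymptotic regime approximations of the plateau density
#'
#' Leading-order approximations in four parameter regimes:
#'
#' * `slow` (\eqn{\omega \ll 1}, requires `a < beta`): quasi-steady balance
#'   \eqn{r \approx \beta/(\beta - a\cos\omega t)} plus the exponentially
#'   decaying initial-layer correction so the initial condition is met.
#' * `fast` (\eqn{\omega \gg 1}): averaging — logistic mean plus the
#'   \eqn{e^{-\frac{a}{\omega}\sin\omega t}} oscillatory correction factor.
#' * `chemotaxis_dominant` (\eqn{\beta \ll a}): growth neglected,
#'   \eqn{u \approx u_0 e^{-\frac{a}{\omega}\sin\omega t}}.
#' * `growth_dominant` (\eqn{a \ll \beta}): oscillation neglected, logistic
#'   growth.
#'
#' A warning is issued when the regime's parameter ordering does not hold.
#'
#' @inheritParams exact_plateau_density
#' @param regime One of `"slow"`, `"fast"`, `"chemotaxis_dominant"`,
#'   `"growth_dominant"`.
#' @export
regime_approximation <- function(prob,
                                 regime = c("slow", "fast",
                                            "chemotaxis_dominant",
                                            "growth_dominant"),
                                 t) {
  stopifnot(inherits(prob, "chemo_oscillatory"))
  regime <- match.arg(regime)
  a <- prob$a; om <- prob$omega; be <- prob$beta; u0 <- prob$u0
  check <- switch(regime,
                  slow = abs(om) < 1,
                  fast = abs(om) > 1,
                  chemotaxis_dominant = be < abs(a),
                  growth_dominant = abs(a) < be)
  if (!check) {
    warning("parameter ordering for regime '", regime, "' does not hold")
  }
  switch(regime,
         slow = {
           if (a >= be) {
             stop("slow regime requires a < beta: the quasi-steady ",
                  "coefficient beta - a*cos(omega t) changes sign otherwise")
           }
           r_qs <- be / (be - a * cos(om * t))
           transient <- (1 / u0 - be / (be - a)) *
             exp(-be * t + (a / om) * sin(om * t))
           1 / (r_qs + transient)
         },
         fast = {
           # averaged r-equation gives the logistic mean; the O(1)
           # oscillatory integrating factor is reinstated multiplicatively
           u_log <- 1 / (1 + (1 / u0 - 1) * exp(-be * t))
           u_log * exp(-(a / om) * sin(om * t))
         },
         chemotaxis_dominant = u0 * exp(-(a / om) * sin(om * t)),
         growth_dominant = {
           u0 * exp(be * t) / (1 + u0 * (exp(be * t) - 1))
         })
}

#' Maximum regime-approximation error against the RK oracle
#'
#' Convenience used in regime-convergence studies: the maximum absolute
#' difference between [regime_approximation()] and
#' [numeric_plateau_density()] on a time grid.
#'
#' @inheritParams regime_approximation
#' @param t_grid Evaluation grid.
#' @export
regime_error <- function(prob, regime, t_grid) {
  num <- numeric_plateau_density(prob, t_grid)$u
  app <- regime_approximation(prob, regime, t_grid)
  max(abs(num - app))
}
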