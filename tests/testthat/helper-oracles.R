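# Independent oracles used across the suite.  These deliberately bypass the
# package's own map machinery: characteristic trajectories are integrated
# directly with an adaptive solver at tight tolerance.

# Front position by direct integration of dx/dt = alpha(t, x), x(0) = s.
rk_characteristic <- function(flux, t, s = 0, rtol = 1e-12) {
  if (t == 0) return(s)
  sol <- deSolve::ode(y = c(x = s), times = c(0, t),
                      func = function(tt, y, p) list(flux$alpha(tt, y[1])),
                      rtol = rtol, atol = 1e-14)
  unname(sol[nrow(sol), "x"])
}

# Density along a characteristic: RK on the coupled (x, u) system
#   dx/dt = alpha,  du/dt = u * (beta(t,x)(1-u) - alpha_x(t,x)).
rk_char_density <- function(flux, beta, u0, s, t, rtol = 1e-12) {
  sol <- deSolve::ode(y = c(x = s, u = u0), times = c(0, t),
                      func = function(tt, y, p) {
                        list(c(flux$alpha(tt, y[1]),
                               y[2] * (beta(tt, y[1]) * (1 - y[2]) -
                                         flux$alpha_x(tt, y[1]))))
                      }, rtol = rtol, atol = 1e-14)
  unname(sol[nrow(sol), "u"])
}

# Central finite-difference residual of the characteristic ODE for a map
# F(t; s): |dF/dt - alpha(t, F(t; s))|.
map_residual <- function(Ffun, flux, t, s, h = 1e-5) {
  dF <- (Ffun(t + h, s) - Ffun(t - h, s)) / (2 * h)
  abs(dF - flux$alpha(t, Ffun(t, s)))
}

# The built-in closed-form flux catalogue exercised by the map tests.
builtin_flux_cases <- function() {
  list(
    linear_const = flux_linear(2, 1),
    linear_cos = flux_linear(1, 3, g = stimulus_cos(10)),
    linear_a0 = flux_linear(0, 1),
    exp_single = flux_exponential(2, 1),
    exp_double = flux_exponential(1.5, 1, b = 0.4),
    cosh_gradient = flux_cosh_gradient(1, 0.1),
    sinh_symmetric = flux_sinh_symmetric(1, 0.1),
    high_nutrient = flux_linear_aconst_test(0.1, function(t) 1 - 0.05)
  )
}

# expose the internal constructor for tests
flux_linear_aconst_test <- function(a_const, b) {
  chemowave:::flux_linear_aconst(a_const, b)
}

# time grid on which each case's maps stay within the domain of validity
case_time_grid <- function(name) {
  switch(name,
         exp_double = seq(0.02, 0.3, length.out = 8),
         seq(0.05, 0.75, length.out = 8))
}
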