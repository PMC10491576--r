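# Finite-volume PDE oracle: conservation, limits, convergence, coupling.

test_that("zero-flux scheme conserves mass exactly when growth is off", {
  pr <- model_problem(flux_linear(2, 1), growth_field(0), u0 = 0.05,
                      D = 1e-3, T_max = 0.5)
  sol <- solve_scalar(pr, t_out = c(0.2, 0.4), n_cells = 300)
  expect_lt(max(abs(sol$mass - sol$mass[1])) / sol$mass[1], 1e-6)
  expect_gt(min(sol$u), -1e-10)
})

test_that("without advection the solution is the uniform logistic curve", {
  pr <- model_problem(flux_linear(0, 0), growth_constant(1), u0 = 0.05,
                      D = 1e-3, T_max = 1)
  sol <- solve_scalar(pr, t_out = 1, n_cells = 100)
  expected <- 0.05 * exp(1) / (1 + 0.05 * (exp(1) - 1))
  expect_lt(max(abs(sol$u[2, ] - expected)), 1e-6)
})

test_that("spatial convergence order is second order on a smooth problem", {
  pr <- model_problem(flux_separable(function(x) x * (1 - x),
                                     fprime = function(x) 1 - 2 * x),
                      growth_constant(1),
                      u0 = function(x) 0.3 + 0.2 * cos(pi * x),
                      D = 1e-2, T_max = 0.5)
  coarsen <- function(u, factor) {
    colMeans(matrix(u, nrow = factor))
  }
  sols <- lapply(c(100, 200, 400), function(n) {
    solve_scalar(pr, t_out = 0.5, n_cells = n, rtol = 1e-10,
                 atol = 1e-12)$u[2, ]
  })
  e1 <- max(abs(sols[[1]] - coarsen(sols[[2]], 2)))
  e2 <- max(abs(coarsen(sols[[2]], 2) - coarsen(sols[[3]], 4)))
  order <- log2(e1 / e2)
  expect_gt(order, 1.7); expect_lt(order, 2.2)
})

test_that("coupled solver: unconsumed chemoattractant relaxes to the linear
           profile", {
  md <- nondim_model(Pi1 = 1e-3, Pi2 = 1, Pi3 = 100, Pi4 = 0, m0 = 1,
                     psi1 = 0, psi2 = 1, K_cells = 1, u0 = 0.05)
  sol <- solve_coupled(md, t_out = 0.3, n_cells = 200)
  expect_lt(max(abs(sol$v[2, ] - sol$x)), 1e-8)
})

test_that("coupled solver relaxes v to the scenario steady profiles", {
  lam <- 0.1
  # high nutrient: saturated uptake, v -> quadratic with v_xx = lambda
  mh <- nondim_model(Pi1 = 1e-3, Pi2 = 1, Pi3 = 100, Pi4 = lam * 100,
                     m0 = 1, psi1 = 0, psi2 = 1, K_cells = 1, u0 = 0.05)
  sh <- solve_coupled(mh, t_out = 0.3, n_cells = 200,
                      consumption = function(v, u) rep(1, length(v)))
  vq <- 0.5 * lam * sh$x^2 + (1 - 0.5 * lam) * sh$x
  expect_lt(max(abs(sh$v[2, ] - vq)) / max(vq), 0.01)

  # low nutrient, linearised uptake: v -> sinh profile. The boundary
  # condition v(1) = psi forces the 1/sinh(sqrt(lambda)) normalisation that
  # the verbatim analytic profile omits.
  ml <- nondim_model(Pi1 = 1e-3, Pi2 = 1, Pi3 = 100, Pi4 = lam * 100,
                     m0 = 1, psi1 = 0, psi2 = 1, K_cells = 1, u0 = 0.05)
  slo <- solve_coupled(ml, t_out = 0.3, n_cells = 200,
                       consumption = function(v, u) v)
  v_norm <- sinh(sqrt(lam) * slo$x) / sinh(sqrt(lam))
  v_verbatim <- sinh(sqrt(lam) * slo$x)
  expect_lt(max(abs(slo$v[2, ] - v_norm)), 1e-3)
  expect_gt(max(abs(slo$v[2, ] - v_verbatim)), 0.5)
})

test_that("comparison report: exact zero on identical inputs, front located
           within grid resolution", {
  pr <- fixture("fig4_oscillatory")
  sol <- solve_scalar(pr, t_out = c(0.08, 0.157), n_cells = 1000)
  self <- compare_solutions(function(t, x) {
    approx(sol$x, sol$u[which(abs(sol$t - t) < 1e-12), ], xout = x,
           rule = 2)$y
  }, sol, exclusion_band = 0.2)
  expect_true(all(self$linf == 0))

  fr <- front(pr$flux, T_max = pr$T_max)
  rep <- compare_solutions(function(t, x) {
    as.numeric(composite_density(pr, t, x))
  }, sol, exclusion_band = 0.2, front = fr,
  front_plateau = function(t) outer_density_general(pr, t, fr$x_star(t)))
  dx <- 1 / 1000
  for (i in which(rep$t > 0)) {
    expect_lt(rep$front_err[i], 2 * dx + 2 * sqrt(rep$t[i] * pr$D))
  }
  expect_error(compare_solutions(function(t, x) 0 * x, sol,
                                 exclusion_band = 1.5), "empty")
})
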