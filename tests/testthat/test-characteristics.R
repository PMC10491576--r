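# Characteristic maps: frozen examples, round trips, ODE residuals, fronts
# and outer densities.

test_that("forward map matches frozen values and identities", {
  fl <- flux_linear(2, 1)
  # closed form (e^{0.4} - 1)/2, cross-checked against adaptive RK
  expect_equal(forward_map(fl, 0.2, 0), (exp(0.4) - 1) / 2, tolerance = 1e-12)
  expect_lt(abs(forward_map(fl, 0.2, 0) - rk_characteristic(fl, 0.2)), 1e-9)
  expect_identical(forward_map(fl, 0, 0.37), 0.37)
  # oscillatory front formula x*(t) = (b/a)(e^{a sin(wt)/w} - 1)
  fo <- flux_linear(1, 3, g = stimulus_cos(10))
  for (ti in c(0.1, 0.3, 0.6)) {
    expect_equal(forward_map(fo, ti, 0), 3 * (exp(sin(10 * ti) / 10) - 1),
                 tolerance = 1e-12)
  }
})

test_that("inverse map matches printed exponential form and round-trips", {
  fe <- flux_exponential(2, 1)
  for (ti in c(0.2, 0.5)) {
    for (xi in c(0.8, 1)) {
      expect_equal(inverse_map(fe, ti, xi), log(exp(xi) - 2 * ti),
                   tolerance = 1e-12)
    }
  }
  expect_identical(inverse_map(fe, 0, 0.6), 0.6)
  fl <- flux_linear(2, 1)
  expect_lt(abs(inverse_map(fl, 0.2, (exp(0.4) - 1) / 2)), 1e-12)
  # left of the front: second family, density zero, inverse undefined
  expect_error(inverse_map(fe, 0.5, 0.1), "second")
})

test_that("round trip G(t; F(t; s)) = s on a 20x20 grid for every case", {
  for (nm in names(builtin_flux_cases())) {
    fl <- builtin_flux_cases()[[nm]]
    tg <- case_time_grid(nm)
    sg <- seq(0, 1, length.out = 20)
    for (ti in tg[seq(1, length(tg), by = 2)]) {
      xs <- forward_map(fl, ti, sg)
      back <- inverse_map(fl, ti, xs)
      expect_lt(max(abs(back - sg)), 1e-9, label = paste("roundtrip", nm))
    }
  }
})

test_that("closed-form maps satisfy the characteristic ODE dF/dt = alpha", {
  for (nm in names(builtin_flux_cases())) {
    fl <- builtin_flux_cases()[[nm]]
    Ffun <- function(t, s) forward_map(fl, t, s)
    for (ti in case_time_grid(nm)[c(2, 5)]) {
      for (si in c(0, 0.4, 0.9)) {
        expect_lt(map_residual(Ffun, fl, ti, si), 1e-7,
                  label = paste("residual", nm, ti, si))
      }
    }
  }
})

test_that("printed high-nutrient and symmetric map variants fail the ODE
           residual that the derived maps satisfy", {
  # high-nutrient: alpha = k*lambda*x + k*(dpsi - lambda/2)
  k <- 1; lambda <- 0.3
  fl <- flux_linear_aconst_test(k * lambda, function(t) k * (1 - lambda / 2))
  printed <- paper_printed_maps("high_nutrient", k, lambda,
                                delta_psi = function(t) rep(1, length(t)))
  res_derived <- map_residual(function(t, s) forward_map(fl, t, s),
                              fl, 0.5, 0.3)
  res_printed <- map_residual(printed$F, fl, 0.5, 0.3)
  expect_lt(res_derived, 1e-7)
  expect_gt(res_printed, 1e-3)   # the missing e^{k lambda t} factor

  # symmetric configuration: arctan (printed) vs artanh (derived)
  fs <- flux_sinh_symmetric(1, 0.4)
  printed_s <- paper_printed_maps("low_nutrient_symmetric", 1, 0.4)
  res_derived_s <- map_residual(function(t, s) forward_map(fs, t, s),
                                fs, 0.5, 0.6)
  res_printed_s <- map_residual(printed_s$F, fs, 0.5, 0.6)
  expect_lt(res_derived_s, 1e-7)
  expect_gt(res_printed_s, 1e-4)
})

test_that("even-stimulus symmetry G(t; x) = F(-t; x)", {
  for (fl in list(flux_linear(2, 1), flux_linear(1, 3, g = stimulus_cos(10)),
                  flux_exponential(2, 1))) {
    for (ti in c(0.15, 0.4)) {
      # evaluation points right of the front by construction
      for (xi in forward_map(fl, ti, c(0.1, 0.6))) {
        expect_lt(abs(inverse_map(fl, ti, xi) - forward_map(fl, -ti, xi)),
                  1e-9)
      }
    }
  }
})

test_that("front trajectory: formulas, speed consistency, exit time", {
  fl <- flux_linear(2, 1)
  fr <- front(fl, T_max = 1)
  tg <- seq(0, 0.5, by = 0.1)
  expect_equal(fr$x_star(tg), 0.5 * (exp(2 * tg) - 1), tolerance = 1e-10)
  expect_identical(fr$x_star(0), 0)
  # speed equals alpha evaluated on the front
  expect_equal(fr$speed(0.3), fl$alpha(0.3, fr$x_star(0.3)))
  expect_equal(fr$exit_time, log(3) / 2, tolerance = 1e-9)

  # exponential single-source front x* = log(1 + a*lambda*t)/lambda
  fe <- flux_exponential(2, 1)
  fre <- front(fe, T_max = 1)
  expect_equal(fre$x_star(0.5), log(2), tolerance = 1e-12)

  # stationary flux at the origin warns
  expect_warning(front(flux_sinh_symmetric(1, 0.1), T_max = 1),
                 "does not detach")
})

test_that("front agrees with adaptive RK integration for every case", {
  for (nm in names(builtin_flux_cases())) {
    fl <- builtin_flux_cases()[[nm]]
    for (ti in case_time_grid(nm)[c(3, 7)]) {
      expect_lt(abs(forward_map(fl, ti, 0) - rk_characteristic(fl, ti)),
                1e-8, label = paste("front oracle", nm))
    }
  }
})

test_that("outer density: linear plateau closed form vs quadrature", {
  fl <- flux_linear(2, 1)
  pr <- model_problem(fl, growth_constant(1), u0 = 0.05, D = 1e-3, T_max = 1.2)
  # frozen: u(t=1) = u0 (a-1) e^{-(a-1)} / (a-1 + u0(1 - e^{-(a-1)}))
  expect_equal(plateau_density_linear(2, 0.05, 1), 0.0178304, tolerance = 1e-5)
  for (ti in c(0.3, 0.7, 1)) {
    xr <- forward_map(fl, ti, 0.2)   # a point right of the front
    expect_lt(abs(outer_density_general(pr, ti, xr) -
                    plateau_density_linear(2, 0.05, ti)), 1e-7)
  }
  # t = 0 returns the initial condition; left of the front returns 0
  expect_equal(outer_density_general(pr, 0, c(0.2, 0.9)), c(0.05, 0.05))
  expect_identical(outer_density_general(pr, 0.5, 0.1), 0)
})

test_that("outer density quadrature matches the RK density oracle", {
  fe <- flux_exponential(2, 1)
  pr <- model_problem(fe, growth_constant(1), u0 = 0.05, D = 1e-3, T_max = 1)
  for (ti in c(0.25, 0.5)) {
    for (xi in c(0.8, 1)) {
      s <- inverse_map(fe, ti, xi)
      expect_lt(abs(outer_density_general(pr, ti, xi) -
                      rk_char_density(fe, function(t, x) 1, 0.05, s, ti)),
                1e-8)
    }
  }
})

test_that("special separable form: frozen value and O(u0^2) error scaling", {
  fe <- flux_exponential(2, 1)
  # frozen printed form u0 e^t / (1 - a lambda t e^{-lambda x})
  expect_equal(outer_density_separable_special(fe, 0.05, 0.5, 1),
               0.05 * exp(0.5) / (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(outer_density_separable_special(fe, 0.05, 0, 0.7), 0.05)

  # halving u0 quarters the gap to the exact quadrature density
  err_for <- function(u0) {
    pr <- model_problem(fe, growth_constant(1), u0 = u0, D = 1e-3, T_max = 1)
    abs(outer_density_separable_special(fe, u0, 0.4, 0.9) -
          outer_density_general(pr, 0.4, 0.9))
  }
  ratio <- err_for(0.05) / err_for(0.025)
  expect_gt(ratio, 3); expect_lt(ratio, 5)
  expect_warning(outer_density_separable_special(fe, 0.2, 0.1, 0.9), "u0")
})

test_that("degenerate linear limits are finite and correct", {
  # a -> 0: front x* = b * T(t)
  f0 <- flux_linear(0, 1)
  expect_equal(forward_map(f0, 0.4, 0), 0.4)
  ftiny <- flux_linear(1e-12, 1)
  expect_equal(forward_map(ftiny, 0.4, 0), 0.4, tolerance = 1e-10)
  # a -> 1 plateau density limit u0/(1 + u0 t)
  expect_equal(plateau_density_linear(1, 0.05, 2), 0.05 / 1.1)
  expect_equal(plateau_density_linear(1 + 1e-10, 0.05, 2), 0.05 / 1.1,
               tolerance = 1e-8)
})

test_that("exponential case has no singularity right of the front", {
  expect_identical(no_singularity_check(2, 1, 0)$min_value, 1)
  for (ti in c(0.5, 1)) {
    chk <- no_singularity_check(2, 1, ti)
    expect_gte(chk$min_value + 1e-12, chk$bound)
    expect_gt(chk$bound, 0)
  }
  expect_equal(no_singularity_check(2, 1, 0.5)$bound, 0.5)
  expect_equal(no_singularity_check(2, 1, 1)$bound, 1 / 3)
})

test_that("general (non-catalogue) fluxes fall back to ODE integration", {
  fg <- flux_general(function(t, x) (2 * x + 1) * exp(-t),
                     alpha_x = function(t, x) 2 * exp(-t))
  # same flux through the general-linear quadrature path
  fl <- flux_linear(a = function(t) 2 * exp(-t), b = function(t) exp(-t))
  for (ti in c(0.3, 0.6)) {
    expect_lt(abs(forward_map(fg, ti, 0.2) - forward_map(fl, ti, 0.2)), 1e-8)
    xi <- forward_map(fg, ti, 0.2)
    expect_lt(abs(inverse_map(fg, ti, xi) - 0.2), 1e-8)
  }
})
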