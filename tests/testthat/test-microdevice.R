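# Microdevice model: nondimensionalisation, kinetics, scenario reductions.

make_dim <- function(L = 1) {
  dimensional_model(D = 1e-5, chi = 1e-3, D_B = 1, alpha_n = 0.02,
                    alpha_B = 1e-4, c_sat = 1e3, B_star = 0.2, L = L,
                    W = function(B, C) 0)
}

test_that("dimensionless groups: definitions, scaling law, round trip", {
  d <- dimensional_model(D = 0.02 * 4, chi = 1, D_B = 1, alpha_n = 0.02,
                         alpha_B = 1, c_sat = 1, B_star = 1, L = 2)
  nd <- suppressWarnings(nondimensionalise(d))
  expect_equal(nd$Pi1, 1)   # D = alpha_n L^2 by construction

  nd1 <- suppressWarnings(nondimensionalise(make_dim(L = 1)))
  nd2 <- suppressWarnings(nondimensionalise(make_dim(L = 2)))
  expect_equal(nd2$Pi1, nd1$Pi1 / 4)
  expect_equal(nd2$Pi2, nd1$Pi2 / 4)
  expect_equal(nd2$Pi3, nd1$Pi3 / 4)
  expect_equal(nd2$Pi4, nd1$Pi4)

  d0 <- make_dim()
  back <- suppressWarnings(redimensionalise(nondimensionalise(d0)))
  for (nm in c("D", "chi", "D_B", "alpha_n", "alpha_B", "c_sat", "B_star",
               "L")) {
    expect_equal(back[[nm]], d0[[nm]], label = nm)
  }
})

test_that("uptake kinetics: half saturation, monotonicity, limits", {
  mm <- michaelis_menten(k_m = 1)
  expect_identical(uptake_per_cell(1, mm), 0.5)
  expect_equal(uptake_per_cell(3, mm), 0.75)
  hi <- hill_kinetics(k_H = 0.7, n = 3)
  expect_equal(uptake_per_cell(0.7, hi), 0.5)
  v <- seq(0, 20, by = 0.1)
  for (kin in list(mm, hi)) {
    w <- uptake_per_cell(v, kin)
    expect_true(all(diff(w) > 0))
    expect_identical(w[1], 0)
    expect_lt(abs(uptake_per_cell(1e8, kin) - 1), 1e-6)
  }
})

test_that("scenario nutrient profiles solve their equations and boundary
           data, and the induced flux is k * v_x", {
  fxs <- list(weak = fixture("fig7_weak_constant"),
              high = fixture("fig9_high_nutrient"),
              grad = fixture("fig10_low_gradient"),
              sym = suppressWarnings(fixture("fig10_low_symmetric")))
  h <- 1e-4
  xg <- seq(0.1, 0.9, by = 0.2)
  for (nm in names(fxs)) {
    red <- fxs[[nm]]
    v <- function(x) red$v_profile(0.3, x)
    vxx <- (v(xg + h) - 2 * v(xg) + v(xg - h)) / h^2
    rhs <- switch(nm, weak = 0 * xg, high = red$lambda + 0 * xg,
                  grad = red$lambda * v(xg), sym = red$lambda * v(xg))
    expect_lt(max(abs(vxx - rhs)), 1e-5, label = paste("v_xx", nm))
    # induced flux alpha = k v_x by central differences
    vx <- (v(xg + h) - v(xg - h)) / (2 * h)
    expect_lt(max(abs(red$flux$alpha(0.3, xg) - red$k * vx)), 1e-6,
              label = paste("alpha", nm))
  }
  # boundary data
  expect_equal(fxs$weak$v_profile(0.3, c(0, 1)), c(0, 1))
  expect_equal(fxs$high$v_profile(0.3, c(0, 1)), c(0, 1))
  expect_equal(fxs$grad$v_profile(0.3, 0), 0)
  # gradient profile is kept verbatim: v(1) = psi * sinh(sqrt(lambda))
  expect_equal(fxs$grad$v_profile(0.3, 1), sinh(sqrt(0.1)))
})

test_that("scenario lambda comes from the dimensionless groups", {
  m <- nondim_model(Pi1 = 1e-4, Pi2 = 1, Pi3 = 100, Pi4 = 10, m0 = 1,
                    kinetics = michaelis_menten(k_m = 2), psi1 = 0, psi2 = 1,
                    K_cells = 1, u0 = 0.05)
  expect_equal(reduce_scenario(m, "high_nutrient")$lambda, 10 * 1 / 100)
  expect_equal(reduce_scenario(m, "low_nutrient_gradient")$lambda,
               10 * 1 / (2 * 100))
  expect_warning(
    reduce_scenario(nondim_model(Pi3 = 100, Pi4 = 0.5, u0 = 0.05),
                    "high_nutrient"),
    "ordering")
})

test_that("weak consumption: front and frozen worked example", {
  red <- fixture("fig7_weak_constant")
  expect_equal(red$front$x_star(c(0.2, 0.5)), c(0.2, 0.5), tolerance = 1e-10)
  # frozen: I = x*(x - x*/2) = 0.105; u = u0 e^I / (1 + u0(e^I - 1))
  u <- scenario_density(red, 0.3, 0.5)
  expect_equal(u, 0.0552298, tolerance = 1e-6)
  expect_equal(scenario_density(red, 0.3, 0.5, form = "closed_form"), u,
               tolerance = 1e-9)
  expect_identical(scenario_density(red, 0.3, 0.1), 0)
  expect_equal(scenario_density(red, 0, 0.4), 0.05)
})

test_that("scenario quadrature densities match the RK characteristic oracle", {
  cases <- list(
    grad = fixture("fig10_low_gradient"),
    sym = suppressWarnings(fixture("fig10_low_symmetric")),
    high = fixture("fig9_high_nutrient"))
  for (nm in names(cases)) {
    red <- cases[[nm]]
    beta <- red$growth$beta
    for (xi in c(0.55, 0.85)) {   # right of every scenario front at t = 0.5
      s <- inverse_map(red$flux, 0.5, xi)
      # the oracle integrates the transport equation itself; the printed
      # low-nutrient density forms differ from it at O(u0^2) through the
      # K-kernel weighting of the saturation term
      u_rk <- rk_char_density(red$flux, beta, 0.05, s, 0.5)
      u_qd <- scenario_density(red, 0.5, xi)
      expect_lt(abs(u_qd - u_rk), 5e-4, label = paste(nm, xi))
    }
  }
})

test_that("low-nutrient closed forms: derived orientation agrees with the
           quadrature to O(u0^2); the printed gradient form does not", {
  g <- fixture("fig10_low_gradient")
  xg <- c(0.3, 0.6, 0.9)
  uq <- scenario_density(g, 0.5, xg)
  ucl <- scenario_density(g, 0.5, xg, form = "closed_form")
  upr <- scenario_density(g, 0.5, xg, form = "closed_form",
                          paper_verbatim = TRUE)
  expect_lt(max(abs(ucl - uq)), 2.5e-3)
  expect_gt(max(abs(upr - uq)), 5e-3)

  s <- suppressWarnings(fixture("fig10_low_symmetric"))
  us <- scenario_density(s, 0.5, xg)
  uscl <- scenario_density(s, 0.5, xg, form = "closed_form")
  expect_lt(max(abs(uscl - us)), 2.5e-3)
})

test_that("gradient configuration constants: exponent and tangent scale", {
  g <- fixture("fig10_low_gradient")
  expect_identical(g$closed_form_exponent, 9)
  expect_identical(g$S_tan_denominator, 20)
  for (ti in c(0.5, 1, 2)) {
    expect_equal(g$S(ti), tan(ti / 20), tolerance = 1e-12)
  }
})

.hn <- function(l) {
  m <- nondim_model(Pi1 = 1e-4, Pi2 = 1, Pi3 = 100, Pi4 = l * 100, m0 = 1,
                    psi1 = 0, psi2 = 1, K_cells = 1, u0 = 0.05)
  reduce_scenario(m, "high_nutrient")
}

test_that("high-nutrient limit: converges to weak consumption as lambda -> 0", {
  weak <- fixture("fig7_weak_constant")
  tg <- c(0.25, 0.5)
  rate <- vapply(c(0.1, 0.05, 0.025), function(l) {
    red <- .hn(l)
    dx <- max(abs(red$front$x_star(tg) - weak$front$x_star(tg)))
    du <- abs(scenario_density(red, 0.5, 0.7) -
                scenario_density(weak, 0.5, 0.7))
    max(dx, du) / l
  }, numeric(1))
  # difference / lambda stays bounded (constant within a factor ~2)
  expect_lt(max(rate) / min(rate), 2)
  expect_lt(max(rate), 1)
})

test_that("small-lambda expansion tracks the high-nutrient quadrature", {
  lam <- 0.1
  for (kind in c("constant_one", "ramp_t")) {
    psi2 <- if (kind == "constant_one") stimulus_constant(1) else
      stimulus_ramp()
    m <- nondim_model(Pi1 = 1e-4, Pi2 = 1, Pi3 = 100, Pi4 = lam * 100,
                      m0 = 1, psi1 = 0, psi2 = psi2, u0 = 0.05)
    red <- reduce_scenario(m, "high_nutrient")
    for (ti in c(0.3, 0.5)) {   # lambda * t <= 0.05
      xs <- red$front$x_star(ti)
      for (xi in xs + c(0, 0.05)) {
        expect_lt(abs(high_nutrient_small_lambda(ti, xi, kind, lam) -
                        scenario_density(red, ti, xi)), 3e-3,
                  label = paste(kind, ti))
      }
    }
  }
  expect_warning(high_nutrient_small_lambda(4, 0.5, "constant_one", 0.1),
                 "validity")
})

test_that("front speeds: characteristic consistency and uptake trends", {
  g <- fixture("fig10_low_gradient")
  # printed gradient speed sqrt(l) psi / cos(k l T) equals alpha(t, x*)
  for (ti in c(0.3, 0.8)) {
    expect_equal(front_speed(g, ti), front_speed(g, ti, paper_verbatim = TRUE),
                 tolerance = 1e-10)
  }
  h <- fixture("fig9_high_nutrient")
  # at t = 0 the printed and derived high-nutrient speeds coincide
  expect_equal(front_speed(h, 0), front_speed(h, 0, paper_verbatim = TRUE),
               tolerance = 1e-10)
  # increasing uptake slows the high-nutrient wave, speeds up the gradient one
  expect_true(front_speed_trend("high_nutrient"))
  expect_true(front_speed_trend("low_nutrient_gradient"))
})

test_that("unsupported low-nutrient boundary data raise the Riccati error", {
  m <- nondim_model(Pi1 = 1e-4, Pi2 = 1, Pi3 = 100, Pi4 = 10, m0 = 1,
                    psi1 = 0.3, psi2 = 1, u0 = 0.05)
  expect_error(reduce_scenario(m, "low_nutrient_gradient"), "Riccati")
  expect_error(reduce_scenario(m, "low_nutrient_symmetric"), "Riccati")
})
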