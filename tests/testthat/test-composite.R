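# Composite inner/outer solution across the moving front.

test_that("inner profile: values, limits and monotonicity", {
  expect_identical(inner_profile(0, 1), 0.5)
  expect_equal(inner_profile(2, 1), 0.9213504, tolerance = 1e-7)
  expect_equal(inner_profile(1e6, 1), 1)
  expect_equal(inner_profile(-1e6, 1), 0)
  X <- seq(-4, 4, by = 0.1)
  expect_true(all(diff(inner_profile(X, 0.7)) >= 0))
  expect_warning(u <- inner_profile(c(-1, 0, 1), 0), "Heaviside")
  expect_equal(u, c(0, 0.5, 1))
})

test_that("composite density is continuous at the front", {
  pr <- fixture("fig3_linear")
  for (ly in c("strain", "similarity")) {
    for (ti in c(0.2, 0.4)) {
      xs <- forward_map(pr$flux, ti, 0)
      eps <- 1e-9
      vals <- composite_density(pr, ti, c(xs - eps, xs, xs + eps), layer = ly)
      expect_lt(max(abs(diff(as.numeric(vals)))), 1e-6)
    }
  }
})

test_that("composite matches the tails on either side of the layer", {
  pr <- fixture("fig3_linear")
  ti <- 0.4
  xs <- forward_map(pr$flux, ti, 0)
  # far behind the front: essentially zero (erf tail bound)
  expect_lt(composite_density(pr, ti, xs - 0.2, layer = "similarity"), 1e-6)
  # far ahead: the outer density
  ua <- outer_density_general(pr, ti, xs + 0.2)
  expect_lt(abs(composite_density(pr, ti, xs + 0.2, layer = "similarity") - ua),
            1e-6)
})

test_that("layer width scales like sqrt(D)", {
  # width of the band where the composite transitions from 10% to 90% of
  # the front value, compared across two diffusivities
  width_for <- function(D, layer) {
    pr <- model_problem(flux_linear(2, 1), growth_constant(1), u0 = 0.05,
                        D = D, T_max = 0.5)
    ti <- 0.3
    xs <- forward_map(pr$flux, ti, 0)
    up <- outer_density_general(pr, ti, xs)
    # right of the front the outer density is the plateau, so the composite
    # passes monotonically from 0 to up through the erf layer alone
    xg <- seq(xs - 0.4, xs + 0.4, length.out = 4001)
    u <- as.numeric(composite_density(pr, ti, xg, layer = layer))
    inside <- xg[u >= 0.1 * up & u <= 0.9 * up]
    diff(range(inside))
  }
  for (ly in c("similarity", "strain")) {
    ratio <- width_for(4e-3, ly) / width_for(1e-3, ly)
    expect_gt(ratio, 2 * 0.8); expect_lt(ratio, 2 * 1.2)
  }
})

test_that("composite at t = 0 is the Heaviside-cut initial condition", {
  pr <- fixture("fig3_linear")
  u <- composite_density(pr, 0, c(0, 0.3, 0.9))
  expect_equal(as.numeric(u), c(0, 0.05, 0.05))
  expect_true(attr(u, "small_time"))
})

test_that("boundary-layer and small-time evaluations are flagged", {
  pr <- fixture("fig3_linear")
  excl <- bl_exclusion_default(pr$D, pr$T_max)
  u <- composite_density(pr, 0.3, c(0.5, 1 - excl / 2))
  expect_identical(attr(u, "boundary_layer"), c(FALSE, TRUE))
  expect_false(attr(u, "small_time"))
  u2 <- composite_density(pr, pr$D / 2, 0.5)
  expect_true(attr(u2, "small_time"))
  expect_equal(bl_exclusion_default(1e-4, 1), 0.1)
  expect_equal(bl_exclusion_default(1e-6, 0.1), 0.02)
})

test_that("strain-corrected width reduces to the similarity width without
           strain and tracks the stretched layer with it", {
  # alpha_x = 0: both widths identical
  pr0 <- model_problem(flux_linear(0, 1), growth_constant(1), u0 = 0.05,
                       D = 1e-3, T_max = 0.5)
  xg <- seq(0, 0.8, by = 0.01)
  u_sim <- composite_density(pr0, 0.3, xg, layer = "similarity")
  u_str <- composite_density(pr0, 0.3, xg, layer = "strain")
  expect_lt(max(abs(u_sim - u_str)), 1e-10)
  # alpha_x = a > 0: strain variance is (D/a)(e^{2at} - 1) > 2Dt
  v <- chemowave:::.strain_layer_var(flux_linear(2, 1), 0.4, 1e-3)
  expect_equal(v, (1e-3 / 2) * (exp(1.6) - 1), tolerance = 1e-6)
  expect_gt(v, 2 * 1e-3 * 0.4)
})
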