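# Catalogue of the exemplar parameter sets used throughout the package's
# validation figures.  Each fixture records the parameters, the builder for
# the corresponding problem or scenario, and the evaluation times used by
# reproduce_figure().

.fixture_list <- function() {
  list(
    fig3_linear = list(
      description = "linear flux alpha = 2x + 1, constant stimulus",
      params = list(a = 2, b = 1, D = 1e-3, u0 = 0.05, beta = 1),
      times = c(0.2, 0.4, 0.5),
      build = function(p = list()) {
        par <- utils::modifyList(list(a = 2, b = 1, D = 1e-3, u0 = 0.05),
                                 p)
        model_problem(flux_linear(par$a, par$b), growth_constant(1),
                      u0 = par$u0, D = par$D, T_max = 0.55)
      }),
    fig4_oscillatory = list(
      description = "linear flux with oscillatory stimulus g = cos(10 t)",
      params = list(a = 1, b = 3, omega = 10, D = 1e-3, u0 = 0.05, beta = 1),
      times = c(0.08, 0.157, 0.22),
      build = function(p = list()) {
        par <- utils::modifyList(list(a = 1, b = 3, omega = 10, D = 1e-3,
                                      u0 = 0.05), p)
        model_problem(flux_linear(par$a, par$b, g = stimulus_cos(par$omega)),
                      growth_constant(1), u0 = par$u0, D = par$D,
                      T_max = 0.25)
      }),
    fig6_exponential = list(
      description = "exponential flux alpha = 2 exp(-x)",
      params = list(a = 2, lambda = 1, b = 0, D = 1e-3, u0 = 0.05, beta = 1),
      times = c(0.25, 0.5),
      build = function(p = list()) {
        par <- utils::modifyList(list(a = 2, lambda = 1, b = 0, D = 1e-3,
                                      u0 = 0.05), p)
        model_problem(flux_exponential(par$a, par$lambda, b = par$b),
                      growth_constant(1), u0 = par$u0, D = par$D,
                      T_max = 0.8)
      }),
    fig7_weak_constant = list(
      description = "weak consumption, psi2 = 1",
      params = list(k = 1, m0 = 1, D = 1e-4, u0 = 0.05, psi2 = "constant"),
      times = c(0.25, 0.5, 0.75),
      scenario = "weak_consumption",
      build = function(p = list()) {
        .scenario_fixture("weak_consumption", stimulus_constant(1), p)
      }),
    fig7_weak_oscillatory = list(
      description = "weak consumption, psi2 = 1 + cos(10 pi t)",
      params = list(k = 1, m0 = 1, D = 1e-4, u0 = 0.05,
                    psi2 = "1+cos", omega = 10 * pi),
      times = c(0.25, 0.5, 0.75),
      scenario = "weak_consumption",
      build = function(p = list()) {
        .scenario_fixture("weak_consumption", stimulus_one_plus_cos(10 * pi),
                          p)
      }),
    fig7_weak_ramp = list(
      description = "weak consumption, psi2 = t",
      params = list(k = 1, m0 = 1, D = 1e-4, u0 = 0.05, psi2 = "ramp"),
      times = c(0.25, 0.5, 0.75),
      scenario = "weak_consumption",
      build = function(p = list()) {
        .scenario_fixture("weak_consumption", stimulus_ramp(), p)
      }),
    fig9_high_nutrient = list(
      description = "high-nutrient consumption, quadratic nutrient profile",
      params = list(k = 1, lambda = 0.1, m0 = 1, D = 1e-4, u0 = 0.05,
                    psi2 = "constant"),
      times = c(0.25, 0.5, 0.75),
      scenario = "high_nutrient",
      build = function(p = list()) {
        .scenario_fixture("high_nutrient", stimulus_constant(1), p)
      }),
    fig10_low_gradient = list(
      description = "low-nutrient gradient configuration, sinh profile",
      params = list(k = 1, lambda = 0.1, m0 = 1, D = 1e-4, u0 = 0.05,
                    psi2 = "constant"),
      times = c(0.25, 0.5, 0.75),
      scenario = "low_nutrient_gradient",
      build = function(p = list()) {
        .scenario_fixture("low_nutrient_gradient", stimulus_constant(1), p)
      }),
    fig10_low_symmetric = list(
      description = "low-nutrient symmetric configuration, cosh profile",
      params = list(k = 1, lambda = 0.1, m0 = 1, D = 1e-4, u0 = 0.05,
                    psi = "constant"),
      times = c(0.25, 0.5, 0.75),
      scenario = "low_nutrient_symmetric",
      build = function(p = list()) {
        .scenario_fixture("low_nutrient_symmetric", stimulus_constant(1), p)
      })
  )
}

.scenario_fixture <- function(scenario, psi2, p = list()) {
  par <- utils::modifyList(list(k = 1, lambda = 0.1, m0 = 1, u0 = 0.05,
                                Pi1 = 1e-4, Pi3 = 100), p)
  psi1 <- if (scenario == "low_nutrient_symmetric") psi2 else 0
  # Pi4 chosen so the scenario's own lambda formula reproduces par$lambda
  Pi4 <- if (scenario == "low_nutrient_gradient" ||
             scenario == "low_nutrient_symmetric" ||
             scenario == "high_nutrient") par$lambda * par$Pi3 else 10
  model <- nondim_model(Pi1 = par$Pi1, Pi2 = par$k, Pi3 = par$Pi3, Pi4 = Pi4,
                        m0 = par$m0, kinetics = michaelis_menten(k_m = 1),
                        psi1 = psi1, psi2 = psi2, K_cells = 1, u0 = par$u0)
  reduce_scenario(model, scenario)
}

#' List the built-in fixture cases
#'
#' Named catalogue of every exemplar parameter set the package's validation
#' figures use (linear, oscillatory-linear and exponential flux fields,
#' three weak-consumption stimulus shapes, and the three consumption
#' scenarios).
#'
#' @return A data.frame with columns `name`, `description` and `scenario`
#'   (empty string for the plain flux cases); the full fixture objects are
#'   available via [fixture()].
#' @export
list_fixtures <- function() {
  fx <- .fixture_list()
  data.frame(name = names(fx),
             description = vapply(fx, `[[`, character(1), "description"),
             scenario = vapply(fx, function(f) {
               if (is.null(f$scenario)) "" else f$scenario
             }, character(1)),
             row.names = NULL)
}

#' @rdname list_fixtures
#' @param name Fixture name as listed by [list_fixtures()].
#' @param params Named list of parameter overrides.
#' @return `fixture()` returns the built object: a `chemo_problem` for the
#'   flux cases, a `chemo_scenario` for the microdevice cases, together
#'   with the fixture metadata in attributes `times` and `params`.
#' @export
fixture <- function(name, params = list()) {
  fx <- .fixture_list()
  if (!name %in% names(fx)) {
    stop("unknown fixture '", name, "'; see list_fixtures()")
  }
  f <- fx[[name]]
  obj <- f$build(params)
  attr(obj, "times") <- f$times
  attr(obj, "params") <- utils::modifyList(f$params, params)
  attr(obj, "fixture_name") <- name
  obj
}
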