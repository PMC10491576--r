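# Configuration, figure reproduction and output plumbing for the
# command-line workbench (inst/cli/chemowave).

#' Read a model configuration file
#'
#' Parses a YAML or JSON configuration into a `chemo_problem`.  Recognised
#' keys: `flux.structure` (`linear`, `linear_oscillatory`, `exponential`,
#' or one of the named scenario cases), `flux.params` (named constants
#' `a`, `b`, `omega`, `lambda`, `k`), `growth` (`constant` value or `m0`),
#' `u0`, `D`, `T_max`.  Named cases (`weak_consumption`, `high_nutrient`,
#' `low_nutrient_gradient`, `low_nutrient_symmetric`) return a
#' `chemo_scenario` instead.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  config_to_object(cfg)
}

#' @rdname read_config
#' @param cfg Configuration list (already parsed).
#' @export
config_to_object <- function(cfg) {
  structure_tag <- cfg$flux$structure
  if (is.null(structure_tag)) stop("config lacks flux.structure")
  p <- cfg$flux$params
  u0 <- if (is.null(cfg$u0)) 0.05 else cfg$u0
  D <- if (is.null(cfg$D)) 1e-3 else cfg$D
  T_max <- if (is.null(cfg$T_max)) 1 else cfg$T_max
  scen <- c("weak_consumption", "high_nutrient", "low_nutrient_gradient",
            "low_nutrient_symmetric")
  if (structure_tag %in% scen) {
    psi2 <- .psi_from_config(cfg$flux$psi2, default = stimulus_constant(1))
    par <- list(k = p$k %||% 1, lambda = p$lambda %||% 0.1,
                m0 = cfg$growth$m0 %||% 1, u0 = u0, Pi1 = D)
    return(.scenario_fixture(structure_tag, psi2, par))
  }
  flux <- switch(structure_tag,
                 linear = flux_linear(p$a, p$b),
                 linear_oscillatory = flux_linear(p$a, p$b,
                                                  g = stimulus_cos(p$omega)),
                 exponential = flux_exponential(p$a, p$lambda,
                                                b = p$b %||% 0),
                 stop("unknown flux.structure '", structure_tag, "'"))
  growth <- if (!is.null(cfg$growth$constant)) {
    growth_constant(cfg$growth$constant)
  } else growth_constant(1)
  model_problem(flux, growth, u0 = u0, D = D, T_max = T_max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a fixture configuration
#'
#' Writes the parameter map of a fixture to YAML so runs are reproducible
#' from configuration alone; [read_config()] round-trips it.
#'
#' @param name Fixture name.
#' @param path Output path (`.yaml`).
#' @export
write_fixture_config <- function(name, path) {
  fx <- .fixture_list()[[name]]
  if (is.null(fx)) stop("unknown fixture '", name, "'")
  par <- fx$params
  scen <- fx$scenario
  cfg <- if (is.null(scen)) {
    structure_tag <- switch(name,
                            fig3_linear = "linear",
                            fig4_oscillatory = "linear_oscillatory",
                            fig6_exponential = "exponential")
    list(flux = list(structure = structure_tag,
                     params = par[intersect(names(par),
                                            c("a", "b", "omega", "lambda"))]),
         growth = list(constant = par$beta %||% 1),
         u0 = par$u0, D = par$D, T_max = max(fx$times) + 0.05)
  } else {
    list(flux = list(structure = scen,
                     params = par[intersect(names(par), c("k", "lambda"))],
                     psi2 = par$psi2 %||% "constant"),
         growth = list(m0 = par$m0), u0 = par$u0, D = par$D)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

.psi_from_config <- function(tag, default) {
  if (is.null(tag)) return(default)
  switch(tag,
         constant = stimulus_constant(1),
         "1+cos" = stimulus_one_plus_cos(10 * pi),
         ramp = stimulus_ramp(),
         stop("unknown psi shape '", tag, "'"))
}

# Run metadata attached to every CSV/JSON output.
.run_metadata <- function(extra = list()) {
  c(list(package = "chemowave",
         version = as.character(utils::packageVersion("chemowave")),
         deterministic = "all evaluators are deterministic; no seeds used",
         quad_rel_tol = 1e-9, quad_abs_tol = 1e-10),
    extra)
}

#' Write a results table with run metadata
#'
#' CSV with `#`-prefixed metadata header lines (parameters, tolerances,
#' package version) and 12-significant-digit numerics, plus an optional
#' JSON twin.
#'
#' @param df Data frame of results.
#' @param path Output CSV path.
#' @param meta Named list of extra metadata.
#' @param json Also write `<path>.json` with data and metadata.
#' @export
write_results <- function(df, path, meta = list(), json = FALSE) {
  md <- .run_metadata(meta)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(md)) {
    writeLines(sprintf("# %s: %s", nm, paste(format(md[[nm]]), collapse = " ")),
               con)
  }
  dfo <- df
  num <- vapply(dfo, is.numeric, logical(1))
  dfo[num] <- lapply(dfo[num], function(z) signif(z, 12))
  utils::write.csv(dfo, con, row.names = FALSE)
  if (json) {
    jsonlite::write_json(list(metadata = md, data = df),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Reproduce a validation figure
#'
#' Recomputes the data behind one of the package's validation figures and
#' writes it as CSV (and optionally a PNG plot):
#'
#' * `fig3`, `fig4`, `fig6`: composite analytical profiles against the full
#'   PDE solution for the linear, oscillatory-linear and exponential flux
#'   cases.
#' * `fig5`: the four oscillatory-plateau regime panels (approximation vs
#'   adaptive-RK solution).
#' * `fig7`, `fig9`, `fig10`: the three stimulus shapes of the
#'   weak-consumption, high-nutrient and low-nutrient-gradient scenarios
#'   (front trajectory and analytical profiles, with a `D = 1e-4`
#'   composite transition layer).
#'
#' All outputs are deterministic given the solver tolerances.
#'
#' @param name One of `"fig3"`, `"fig4"`, `"fig5"`, `"fig6"`, `"fig7"`,
#'   `"fig9"`, `"fig10"`.
#' @param out_dir Output directory (created if needed).
#' @param n_cells PDE grid size override (`fig3/4/6` only).
#' @param plot Also write a PNG.
#' @return Invisibly, the data frame written to CSV.
#' @export
reproduce_figure <- function(name, out_dir = ".", n_cells = NULL,
                             plot = FALSE) {
  known <- c("fig3", "fig4", "fig5", "fig6", "fig7", "fig9", "fig10")
  if (!name %in% known) stop("unknown figure '", name, "'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, paste0(name, ".csv"))

  if (name %in% c("fig3", "fig4", "fig6")) {
    fxname <- c(fig3 = "fig3_linear", fig4 = "fig4_oscillatory",
                fig6 = "fig6_exponential")[[name]]
    prob <- fixture(fxname)
    times <- attr(prob, "times")
    sol <- solve_scalar(prob, t_out = times, n_cells = n_cells)
    xg <- sol$x[seq(1, length(sol$x), length.out = 401)]
    rows <- lapply(times, function(ti) {
      i <- which(abs(sol$t - ti) < 1e-12)
      ua <- composite_density(prob, ti, xg)
      un <- approx(sol$x, sol$u[i, ], xout = xg)$y
      data.frame(t = ti, x = xg, u_analytic = as.numeric(ua),
                 u_numeric = un,
                 boundary_layer = attr(ua, "boundary_layer"))
    })
    df <- do.call(rbind, rows)
    write_results(df, csv, meta = attr(prob, "params"))
    if (plot) .plot_profiles(df, file.path(out_dir, paste0(name, ".png")))
    return(invisible(df))
  }

  if (name == "fig5") {
    panels <- list(
      slow = oscillatory_problem(a = 0.5, omega = 0.05, beta = 1, u0 = 0.05),
      fast = oscillatory_problem(a = 1, omega = 10, beta = 1, u0 = 0.05),
      chemotaxis_dominant = oscillatory_problem(a = 1, omega = 10,
                                                beta = 0.05, u0 = 0.5),
      growth_dominant = oscillatory_problem(a = 0.05, omega = 10, beta = 1,
                                            u0 = 0.05))
    df <- do.call(rbind, lapply(names(panels), function(rg) {
      pr <- panels[[rg]]
      tg <- seq(0, if (rg == "slow") 4 * pi / pr$omega else 5,
                length.out = 301)
      data.frame(regime = rg, t = tg,
                 u_exact = exact_plateau_density(pr, tg),
                 u_numeric = numeric_plateau_density(pr, tg)$u,
                 u_regime = regime_approximation(pr, rg, tg))
    }))
    write_results(df, csv)
    if (plot) .plot_regimes(df, file.path(out_dir, paste0(name, ".png")))
    return(invisible(df))
  }

  # scenario figures: three stimulus shapes each
  scen_fix <- switch(name,
                     fig7 = c("fig7_weak_constant", "fig7_weak_oscillatory",
                              "fig7_weak_ramp"),
                     fig9 = "fig9_high_nutrient",
                     fig10 = "fig10_low_gradient")
  shapes <- if (name == "fig7") {
    list(constant = NULL)  # shape encoded in the fixture name
  } else {
    list(constant = stimulus_constant(1),
         oscillatory = stimulus_one_plus_cos(10 * pi),
         ramp = stimulus_ramp())
  }
  rows <- list()
  if (name == "fig7") {
    for (fx in scen_fix) {
      red <- fixture(fx)
      rows[[fx]] <- .scenario_rows(red, attr(red, "times"),
                                   sub("fig7_weak_", "", fx))
    }
  } else {
    base_fix <- scen_fix
    for (sh in names(shapes)) {
      scen <- .fixture_list()[[base_fix]]$scenario
      red <- .scenario_fixture(scen, shapes[[sh]], list())
      rows[[sh]] <- .scenario_rows(red, c(0.25, 0.5, 0.75), sh)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  write_results(df, csv)
  if (plot) .plot_profiles(df, file.path(out_dir, paste0(name, ".png")))
  invisible(df)
}

.scenario_rows <- function(red, times, shape) {
  xg <- seq(0, 1, length.out = 151)
  # the closed forms hold for any stimulus shape when m(v) = m0*v; only the
  # high-nutrient case needs the quadrature form
  form <- if (red$scenario == "high_nutrient") "quadrature" else "closed_form"
  do.call(rbind, lapply(times, function(ti) {
    ua <- scenario_density(red, ti, xg, form = form)
    uc <- composite_density(red$problem, ti, xg,
                            outer = function(tt, xx) {
                              scenario_density(red, tt, xx, form = form)
                            })
    data.frame(shape = shape, t = ti, x = xg,
               v = red$v_profile(ti, xg),
               u_analytic = as.numeric(ua), u_composite = as.numeric(uc),
               x_star = red$front$x_star(ti))
  }))
}

.plot_profiles <- function(df, png_path) {
  grDevices::png(png_path, width = 900, height = 600)
  on.exit(grDevices::dev.off())
  times <- unique(df$t)
  cols <- grDevices::hcl.colors(length(times), "Dark 2")
  ucol <- if ("u_numeric" %in% names(df)) "u_numeric" else "u_composite"
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, max(df$u_analytic,
                                                       df[[ucol]],
                                                       na.rm = TRUE)),
                 xlab = "x", ylab = "u", main = "analytic vs numeric")
  for (i in seq_along(times)) {
    d <- df[df$t == times[i], ]
    graphics::lines(d$x, d$u_analytic, col = cols[i], lwd = 2)
    graphics::lines(d$x, d[[ucol]], col = cols[i], lty = 2)
  }
  graphics::legend("topleft", legend = paste("t =", times), col = cols,
                   lwd = 2)
}

.plot_regimes <- function(df, png_path) {
  grDevices::png(png_path, width = 900, height = 700)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(2, 2))
  on.exit(graphics::par(op), add = TRUE)
  for (rg in unique(df$regime)) {
    d <- df[df$regime == rg, ]
    graphics::plot(d$t, d$u_numeric, type = "l", lwd = 2, xlab = "t",
                   ylab = "u", main = rg)
    graphics::lines(d$t, d$u_regime, col = "red", lty = 2, lwd = 2)
  }
}
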