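# Finite-volume method-of-lines solver for the full parabolic model.
#
# The scheme is conservative: cell-average unknowns on a uniform grid,
# central second-order diffusion, van Leer slope-limited upwind advection,
# and boundary fluxes set identically to zero, so the no-flux boundary
# conditions hold discretely and total mass is conserved exactly (up to
# time-integration tolerance) when growth is switched off.  Time stepping
# is adaptive stiff integration (lsoda) with a banded Jacobian.

# van Leer (harmonic) limited slope from the two one-sided differences.
.vl_slope <- function(dm, dp) {
  s <- dm * dp
  out <- numeric(length(dm))
  pos <- s > 0
  out[pos] <- 2 * s[pos] / (dm[pos] + dp[pos])
  out
}

# Upwind face values with limited linear reconstruction.
# u: cell averages (n), vel: face velocities (n-1 interior faces).
.face_values <- function(u, vel) {
  n <- length(u)
  dm <- c(0, diff(u))            # u_i - u_{i-1}
  dp <- c(diff(u), 0)            # u_{i+1} - u_i
  sl <- .vl_slope(dm, dp)        # limited slope per cell (times dx scale-free)
  uf <- numeric(n - 1)
  up <- vel >= 0
  i <- seq_len(n - 1)
  uf[up] <- u[i[up]] + 0.5 * sl[i[up]]
  dn <- !up
  uf[dn] <- u[i[dn] + 1] - 0.5 * sl[i[dn] + 1]
  uf
}

#' Solve the scalar chemotactic invasion equation numerically
#'
#' Conservative finite-volume semi-discretisation of
#' \deqn{u_t + (\alpha(t,x)u)_x = D u_{xx} + \beta(t,x)u(1-u)}
#' on `[0, 1]` with zero-flux boundaries, advanced by an adaptive stiff
#' integrator (relative tolerance `1e-8`).  This is the validation oracle
#' for every analytical approximation in the package.
#'
#' @param problem A `chemo_problem` with `D > 0`.
#' @param t_out Output times (the initial time 0 is always included).
#' @param n_cells Number of cells; default 2000, raised to 4000 when
#'   `D < 1e-3` (accuracy/runtime trade-off documented in the methods
#'   vignette).
#' @param rtol,atol Time-integration tolerances.
#' @return A `chemo_grid`: list with `x` (cell centres), `t`, `u`
#'   (time-by-space matrix), `v = NULL`, `mass` (cellwise integral of `u`
#'   per output time) and `scheme_info`.
#' @export
solve_scalar <- function(problem, t_out, n_cells = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(problem, "chemo_problem"))
  D <- problem$D
  if (D <= 0) stop("solve_scalar requires D > 0")
  if (is.null(n_cells)) n_cells <- if (D < 1e-3) 4000L else 2000L
  if (n_cells < 50) stop("n_cells must be >= 50")
  n <- as.integer(n_cells)
  dx <- 1 / n
  xc <- (seq_len(n) - 0.5) * dx
  xf <- seq_len(n - 1) * dx          # interior faces
  alpha <- problem$flux$alpha
  beta <- problem$growth$beta
  u0 <- problem$u0(xc)

  rhs <- function(t, y, p) {
    vel <- alpha(t, xf)
    uf <- .face_values(y, vel)
    flux <- vel * uf - D * diff(y) / dx       # interior face fluxes
    flux <- c(0, flux, 0)                     # zero-flux boundaries
    dudt <- -diff(flux) / dx + beta(t, xc) * y * (1 - y)
    list(dudt)
  }

  times <- unique(sort(c(0, t_out)))
  sol <- deSolve::ode(y = u0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", jactype = "bandint",
                      bandup = 2, banddown = 2, rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (nrow(sol) < length(times)) stop("stiff integration failed to reach all output times")
  u <- unname(sol[, -1, drop = FALSE])
  if (min(u) < -1e-8) {
    warning("negative densities beyond tolerance: min u = ", min(u))
  }
  structure(list(x = xc, t = sol[, 1], u = u, v = NULL,
                 mass = rowSums(u) * dx,
                 scheme_info = list(n_cells = n, dx = dx, rtol = rtol,
                                    atol = atol, limiter = "van Leer")),
            class = "chemo_grid")
}

#' Solve the coupled cell/chemoattractant system numerically
#'
#' Method-of-lines solution of
#' \deqn{u_t = \Pi_1 u_{xx} - \Pi_2(v_x u)_x + m(v)u(1-u), \qquad
#'       v_t = \Pi_3 v_{xx} - \Pi_4 w(v, u),}
#' with zero cell flux and time-dependent Dirichlet chemoattractant values
#' \eqn{v(0,t) = \psi_1(t)}, \eqn{v(1,t) = \psi_2(t)}.  Consumption defaults
#' to the per-cell kinetics times the total cell density
#' (`K_cells + u`).  The initial `v` interpolates the channel values
#' linearly: the fast temporal boundary layer in which `v` relaxes to its
#' quasi-steady profile is not of interest and comparisons should use
#' `t >= 5/Pi3`.
#'
#' @param model A `chemo_nondim`.
#' @param t_out Output times.
#' @param n_cells Number of cells (default 400; the `v` dynamics are smooth
#'   and fast-relaxing).
#' @param u0 Initial cell density (number or function; default from the
#'   model).
#' @param consumption Optional override `w(v, u)`; default
#'   `uptake_per_cell(v, kinetics) * (K_cells + u)`.
#' @param rtol,atol Integration tolerances.
#' @return A `chemo_grid` with both `u` and `v` matrices.
#' @export
solve_coupled <- function(model, t_out, n_cells = 400, u0 = NULL,
                          consumption = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "chemo_nondim"))
  n <- as.integer(n_cells)
  dx <- 1 / n
  xc <- (seq_len(n) - 0.5) * dx
  xf <- seq_len(n - 1) * dx
  Pi1 <- model$Pi1; Pi2 <- model$Pi2; Pi3 <- model$Pi3; Pi4 <- model$Pi4
  m <- model$m
  psi1 <- model$psi1; psi2 <- model$psi2
  if (is.null(consumption)) {
    kin <- model$kinetics; K <- model$K_cells
    consumption <- function(v, u) uptake_per_cell(pmax(v, 0), kin) * (K + u)
  }
  if (is.null(u0)) u0 <- model$u0
  u0v <- if (is.function(u0)) u0(xc) else rep_len(u0, n)
  v0 <- psi1(0) + (psi2(0) - psi1(0)) * xc

  iu <- seq(1, 2 * n, by = 2)   # interleaved state for a banded Jacobian
  iv <- seq(2, 2 * n, by = 2)

  rhs <- function(t, y, p) {
    u <- y[iu]; v <- y[iv]
    p1 <- psi1(t); p2 <- psi2(t)
    # chemoattractant: central diffusion with Dirichlet face values
    vx_faces <- diff(v) / dx
    flux_v <- c(-Pi3 * (v[1] - p1) / (dx / 2),
                -Pi3 * vx_faces,
                -Pi3 * (p2 - v[n]) / (dx / 2))
    dv <- -diff(flux_v) / dx - Pi4 * consumption(v, u)
    # cells: advective velocity Pi2 * v_x at faces, zero-flux boundaries
    vel <- Pi2 * vx_faces
    uf <- .face_values(u, vel)
    flux_u <- vel * uf - Pi1 * diff(u) / dx
    flux_u <- c(0, flux_u, 0)
    du <- -diff(flux_u) / dx + m(v) * u * (1 - u)
    dy <- numeric(2 * n)
    dy[iu] <- du; dy[iv] <- dv
    list(dy)
  }

  y0 <- numeric(2 * n)
  y0[iu] <- u0v; y0[iv] <- v0
  times <- unique(sort(c(0, t_out)))
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", jactype = "bandint",
                      bandup = 5, banddown = 5, rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (nrow(sol) < length(times)) stop("stiff integration failed to reach all output times")
  u <- unname(sol[, 1 + iu, drop = FALSE])
  v <- unname(sol[, 1 + iv, drop = FALSE])
  structure(list(x = xc, t = sol[, 1], u = u, v = v,
                 mass = rowSums(u) * dx,
                 scheme_info = list(n_cells = n, dx = dx, rtol = rtol,
                                    atol = atol, limiter = "van Leer")),
            class = "chemo_grid")
}

#' @export
print.chemo_grid <- function(x, ...) {
  cat("<chemo_grid>", length(x$x), "cells,", length(x$t), "output times",
      if (!is.null(x$v)) "(coupled u, v)", "\n")
  invisible(x)
}

#' Compare an analytical evaluator against a numerical grid solution
#'
#' Per output time, the maximum (L-infinity) and root-mean-square (L2)
#' differences between `analytic(t, x)` and the grid solution over
#' `x` in `[0, 1 - exclusion_band]` (the right-boundary band, where the
#' analytical solution deliberately loses accuracy, is excluded).  When a
#' front trajectory is supplied, the front-location error is also reported:
#' the numerical front is located as the first upward crossing of half the
#' analytical front-plateau value.
#'
#' @param analytic Function `(t, x) -> u` (vectorised in `x`).
#' @param numeric_sol A `chemo_grid` from [solve_scalar()].
#' @param exclusion_band Width of the excluded right-boundary band.
#' @param front Optional `chemo_front` for front-location errors.
#' @param front_plateau Optional function `t -> u_an(x*(t), t)` giving the
#'   analytical plateau value at the front (required for front errors).
#' @return A data.frame with one row per output time: `t`, `linf`, `l2`,
#'   `max_u` (scale of the solution) and `front_err` (NA when not
#'   requested).
#' @export
compare_solutions <- function(analytic, numeric_sol, exclusion_band = 0.02,
                              front = NULL, front_plateau = NULL) {
  stopifnot(inherits(numeric_sol, "chemo_grid"))
  keep <- numeric_sol$x <= 1 - exclusion_band
  if (!any(keep)) stop("empty comparison region")
  xk <- numeric_sol$x[keep]
  out <- lapply(seq_along(numeric_sol$t), function(i) {
    ti <- numeric_sol$t[i]
    un <- numeric_sol$u[i, keep]
    ua <- analytic(ti, xk)
    err <- un - ua
    fe <- NA_real_
    if (!is.null(front) && !is.null(front_plateau) && ti > 0) {
      xs <- front$x_star(ti)
      half <- 0.5 * front_plateau(ti)
      above <- un >= half
      if (any(above) && !all(above)) {
        j <- which(above)[1]
        xnum <- if (j == 1) xk[1] else {
          # linear interpolation of the crossing
          x0 <- xk[j - 1]; x1 <- xk[j]
          u0 <- un[j - 1]; u1 <- un[j]
          x0 + (half - u0) * (x1 - x0) / (u1 - u0)
        }
        fe <- abs(xnum - xs)
      }
    }
    data.frame(t = ti, linf = max(abs(err)), l2 = sqrt(mean(err^2)),
               max_u = max(un), front_err = fe)
  })
  do.call(rbind, out)
}
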