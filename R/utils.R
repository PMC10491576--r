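# Internal numerical helpers shared across modules.

# Adaptive Gauss-Kronrod quadrature with the package-wide tolerances.
# `f` need not be vectorised; it is wrapped so stats::integrate always
# receives a vectorised integrand.
.quad <- function(f, lower, upper, rel.tol = 1e-9, abs.tol = 1e-10) {
  if (lower == upper) return(0)
  res <- stats::integrate(function(z) vapply(z, f, numeric(1)),
                          lower, upper,
                          rel.tol = rel.tol, abs.tol = abs.tol,
                          stop.on.error = FALSE)
  if (!res$message %in% c("OK", "roundoff error was detected")) {
    stop("quadrature failed: ", res$message)
  }
  res$value
}

# Error function via the exact normal-CDF identity (base R has no erf).
.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

.is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Turn a numeric constant into a constant function of one variable,
# leave functions untouched.
.as_fun1 <- function(x, name = deparse(substitute(x))) {
  if (is.function(x)) return(x)
  if (.is_scalar_number(x)) {
    force(x)
    return(structure(function(t) rep_len(x, length(t)),
                     antiderivative = function(t) x * t))
  }
  stop("'", name, "' must be a function or a single finite number")
}

.stopifnot_callable <- function(x, name) {
  if (!is.function(x)) stop("'", name, "' must be a function")
  invisible(TRUE)
}

# Cumulative composite-Simpson integral of samples y on a uniform grid of
# spacing h (fourth-order; odd indices via the Newton 3/8-type end rule).
.cumsimp <- function(y, h) {
  n <- length(y)
  I <- numeric(n)
  if (n < 3) {
    if (n == 2) I[2] <- h * (y[1] + y[2]) / 2
    return(I)
  }
  ev <- seq(3, n, by = 2)
  for (k in ev) I[k] <- I[k - 2] + h / 3 * (y[k - 2] + 4 * y[k - 1] + y[k])
  I[2] <- h / 12 * (5 * y[1] + 8 * y[2] - y[3])
  od <- seq(4, n, by = 2)
  for (k in od) I[k] <- I[k - 1] + h / 12 * (-y[k - 2] + 8 * y[k - 1] + 5 * y[k])
  I
}
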