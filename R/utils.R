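# Shared numerical helpers: quadrature weights, finite-difference
# derivatives and grid inner products.  Everything works on an arbitrary
# strictly increasing grid; no uniform spacing is assumed anywhere.

#' Trapezoidal quadrature weights for a grid
#' @param times strictly increasing numeric vector
#' @return weights w such that sum(w * f) approximates the integral of f
#' @keywords internal
trapz_weights <- function(times) {
  n <- length(times)
  if (n < 2L) return(rep(0, n))
  d <- diff(times)
  w <- numeric(n)
  w[1L] <- d[1L] / 2
  w[n] <- d[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (d[-(n - 1L)] + d[-1L]) / 2
  w
}

#' Trapezoidal integral of sampled values
#' @keywords internal
trapz <- function(times, values) sum(trapz_weights(times) * values)

#' Finite-difference derivative: central in the interior, one-sided at the
#' boundaries.  First-order accurate at the ends, second-order inside.
#' @keywords internal
fd_gradient <- function(values, times) {
  n <- length(values)
  stopifnot(n >= 3L, length(times) == n)
  g <- numeric(n)
  g[1L] <- (values[2L] - values[1L]) / (times[2L] - times[1L])
  g[n] <- (values[n] - values[n - 1L]) / (times[n] - times[n - 1L])
  g[2:(n - 1L)] <- (values[3:n] - values[1:(n - 2L)]) /
    (times[3:n] - times[1:(n - 2L)])
  g
}

#' L2 inner product of two functions sampled on a common grid
#' @keywords internal
grid_inner <- function(times, f, g) sum(trapz_weights(times) * f * g)

#' L2 norm on a grid
#' @keywords internal
grid_norm <- function(times, f) sqrt(max(0, grid_inner(times, f, f)))

`%||%` <- function(a, b) if (is.null(a)) b else a
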