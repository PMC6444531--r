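# Square-root slope function (SRSF) representation.
#
# q(t) = sign(f'(t)) * sqrt(|f'(t)|).  Under this transform the elastic
# distance between curves becomes a plain L2 distance that is invariant to
# simultaneous warping, which is what makes shape-preserving alignment a
# shortest-path problem.  The curve is recovered from (q, f(0)) by
# f(t) = f(0) + integral_0^t q|q| ds.

#' SRSF transform of a curve
#'
#' @param values curve values sampled on `times`.
#' @param times sampling grid (at least 3 points).
#' @return list of class `srsf_curve`: `times`, `q`, `f0`.
#' @export
srsf_transform <- function(values, times) {
  check_grid(times)
  if (anyNA(values) || any(!is.finite(values))) stop("curve contains NA/Inf")
  if (length(values) != length(times)) stop("values/times length mismatch")
  df <- fd_gradient(values, times)
  structure(list(times = as.numeric(times),
                 q = sign(df) * sqrt(abs(df)),
                 f0 = values[1L]),
            class = "srsf_curve")
}

#' Inverse SRSF transform
#'
#' Cumulative trapezoidal integration of q|q| plus the stored initial value.
#'
#' @param sq an `srsf_curve`.
#' @return curve values on the grid of `sq`.
#' @export
srsf_inverse <- function(sq) {
  stopifnot(inherits(sq, "srsf_curve"))
  integrand <- sq$q * abs(sq$q)
  sq$f0 + cumtrapz(sq$times, integrand)
}

# cumulative trapezoid, first element 0
cumtrapz <- function(times, values) {
  n <- length(times)
  c(0, cumsum(diff(times) * (values[-n] + values[-1L]) / 2))
}
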