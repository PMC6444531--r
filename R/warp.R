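# Warping functions and the geometry of their space.
#
# A warp gamma is a monotone map of [0,1] onto itself with fixed endpoints;
# it encodes the phase (x-axis) deformation of a curve.  Its SRSF
# psi = sqrt(gamma') has unit L2 norm, so the set of warps is (a subset of)
# the unit sphere in L2.  Averaging and linearisation therefore use sphere
# geometry: geodesic distance arccos<psi1, psi2>, the log map into a tangent
# space, the exponential map back, and the intrinsic (Karcher) mean.

#' Construct a warping function
#'
#' @param gamma values of the warp on `times`; must start at 0, end at 1 and
#'   be non-decreasing.
#' @param times unit grid on [0, 1].
#' @param psi optional precomputed SRSF of the warp (used by [exp_map()],
#'   where psi is known analytically and more accurate than
#'   re-differentiating gamma); renormalised to unit norm.
#' @return object of class `warp_fun` with fields `times`, `gamma`, `psi`
#'   (the unit-norm SRSF of the warp).
#' @export
warp_fun <- function(gamma, times, psi = NULL) {
  check_grid(times)
  gamma <- as.numeric(gamma)
  if (length(gamma) != length(times)) stop("gamma/times length mismatch")
  if (abs(gamma[1L]) > 1e-8 || abs(gamma[length(gamma)] - 1) > 1e-8)
    stop("a warp must map 0 to 0 and 1 to 1")
  if (any(diff(gamma) < -1e-10)) stop("a warp must be non-decreasing")
  gamma[1L] <- 0
  gamma[length(gamma)] <- 1
  gamma <- cummax(gamma)
  if (is.null(psi)) {
    psi <- warp_to_psi(gamma, times)
  } else {
    psi <- pmax(as.numeric(psi), 0)
    nrm <- grid_norm(times, psi)
    if (nrm < 1e-12) stop("degenerate psi supplied")
    psi <- psi / nrm
  }
  structure(list(times = as.numeric(times), gamma = gamma, psi = psi),
            class = "warp_fun")
}

#' @export
print.warp_fun <- function(x, ...) {
  d <- warp_distance(identity_warp(x$times), x)
  cat("Warping function on", length(x$times), "grid points;",
      "geodesic distance from identity:", format(d, digits = 4), "\n")
  invisible(x)
}

#' The identity warp on a grid
#' @param times unit grid.
#' @return a `warp_fun` with gamma(t) = t.
#' @export
identity_warp <- function(times) warp_fun(times, times)

# psi = sqrt(gamma'), renormalised to unit L2 norm on the grid (the
# discrete derivative makes ||psi|| only approximately 1).
warp_to_psi <- function(gamma, times) {
  dg <- fd_gradient(gamma, times)
  dg[dg < 0] <- 0
  psi <- sqrt(dg)
  nrm <- grid_norm(times, psi)
  if (nrm < 1e-12) stop("degenerate warp: zero derivative everywhere")
  psi / nrm
}

# gamma(t) = int_0^t psi^2, renormalised so gamma(1) = 1; the supplied psi
# (clipped, renormalised) is kept on the result rather than recomputed from
# the discrete gamma, which keeps sphere operations numerically consistent
psi_to_warp <- function(psi, times, warn_negative = TRUE) {
  if (any(psi < 0)) {
    if (warn_negative)
      warning("psi has negative values; clipping to restore monotonicity")
    psi <- pmax(psi, 0)
  }
  g <- cumtrapz(times, psi^2)
  total <- g[length(g)]
  if (total <= 0) stop("degenerate psi: zero total mass")
  warp_fun(g / total, times, psi = psi)
}

#' Invert a warping function
#'
#' Numerically inverts gamma by swapping axes and re-interpolating onto the
#' grid; small plateaus are broken by a monotone jitter before inversion.
#'
#' @param w a `warp_fun`.
#' @return the inverse warp as a `warp_fun`.
#' @export
invert_warp <- function(w) {
  g <- w$gamma
  t <- w$times
  # ensure strict monotonicity for approx()
  eps <- 1e-10 * seq_along(g)
  gs <- cummax(g + eps)
  gs <- (gs - gs[1L]) / (gs[length(gs)] - gs[1L])
  inv <- stats::approx(x = gs, y = t, xout = t, rule = 2)$y
  inv[1L] <- 0
  inv[length(inv)] <- 1
  warp_fun(cummax(inv), t)
}

#' Apply a warp to a curve
#'
#' Evaluates the curve at gamma(t) by linear interpolation, i.e. returns
#' the composition (values o gamma) on the grid.
#'
#' @param values curve values on the warp's grid.
#' @param w a `warp_fun`.
#' @return warped curve values.
#' @export
apply_warp <- function(values, w) {
  stats::approx(x = w$times, y = values, xout = w$gamma, rule = 2)$y
}

#' Geodesic distance between two warps
#'
#' arccos of the inner product of the psi representations: the arc length
#' between the two points on the unit sphere.
#'
#' @param w1,w2 `warp_fun` objects on a common grid.
#' @return non-negative scalar, at most pi.
#' @export
warp_distance <- function(w1, w2) {
  ip <- grid_inner(w1$times, w1$psi, w2$psi)
  acos(min(1, max(-1, ip)))
}

#' Log map on the sphere of warps
#'
#' Maps `point` into the tangent space at `base`; the returned vector's norm
#' equals the geodesic distance and it is orthogonal to the base's psi.
#'
#' @param base,point `warp_fun` objects on a common grid.
#' @return object of class `warp_tangent` with fields `times`, `v`, `base`.
#' @export
log_map <- function(base, point) {
  if (!isTRUE(all.equal(base$times, point$times)))
    stop("warps must share a grid")
  ip <- min(1, max(-1, grid_inner(base$times, base$psi, point$psi)))
  theta <- acos(ip)
  if (theta > pi - 1e-8)
    stop("antipodal warps: log map undefined")
  v <- if (theta < 1e-12) {
    numeric(length(base$psi))
  } else {
    (theta / sin(theta)) * (point$psi - ip * base$psi)
  }
  structure(list(times = base$times, v = v, base = base),
            class = "warp_tangent")
}

#' Exponential map on the sphere of warps
#'
#' Follows the geodesic from `base` in direction `v` for arc length ||v||
#' and converts the reached psi back into a warp.  If the reached psi dips
#' below zero (monotonicity loss) it is clipped and the warp renormalised.
#'
#' @param base a `warp_fun`.
#' @param v a `warp_tangent` based at `base`, or a plain numeric vector in
#'   that tangent space.
#' @param warn_negative warn when monotonicity repair triggers.
#' @return a `warp_fun`.
#' @export
exp_map <- function(base, v, warn_negative = TRUE) {
  vv <- if (inherits(v, "warp_tangent")) v$v else as.numeric(v)
  nrm <- grid_norm(base$times, vv)
  if (nrm < 1e-12) return(base)
  psi_new <- cos(nrm) * base$psi + sin(nrm) * vv / nrm
  psi_to_warp(psi_new, base$times, warn_negative = warn_negative)
}

#' Karcher (Frechet) mean of warping functions
#'
#' The intrinsic mean on the sphere: repeatedly log-map all warps to the
#' tangent space at the current estimate, average, and exponentiate the mean
#' tangent back, until the update norm falls below `tol`.
#'
#' @param warps list of `warp_fun` objects on a common grid.
#' @param tol convergence tolerance on the mean tangent norm.
#' @param max_iter iteration cap.
#' @return a `warp_fun`.
#' @export
karcher_mean_warps <- function(warps, tol = 1e-8, max_iter = 50L) {
  stopifnot(length(warps) >= 1L)
  if (length(warps) == 1L) return(warps[[1L]])
  times <- warps[[1L]]$times
  mu <- warps[[1L]]
  spread <- max(vapply(warps, function(w) warp_distance(warps[[1L]], w),
                       numeric(1L)))
  if (spread > pi / 2)
    warning("warps span more than a hemisphere; Karcher mean may not be unique")
  for (it in seq_len(max_iter)) {
    vs <- vapply(warps, function(w) log_map(mu, w)$v, numeric(length(times)))
    vbar <- rowMeans(vs)
    step <- grid_norm(times, vbar)
    if (step < tol) break
    mu <- exp_map(mu, vbar, warn_negative = FALSE)
  }
  mu
}

#' Frechet functional of a candidate warp
#'
#' Sum of squared geodesic distances from `w` to each warp in `warps`;
#' the quantity the Karcher mean minimises.
#'
#' @param w candidate `warp_fun`.
#' @param warps list of `warp_fun`.
#' @return non-negative scalar.
#' @export
frechet_functional <- function(w, warps) {
  sum(vapply(warps, function(x) warp_distance(w, x)^2, numeric(1L)))
}
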