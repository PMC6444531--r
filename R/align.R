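# Elastic alignment of curve sets on the unit grid.

#' Align one SRSF curve onto another
#'
#' Finds the warping function minimising
#' \eqn{\|q_1 - (q_2 \circ \gamma)\sqrt{\dot\gamma}\|_{L^2}} over monotone
#' grid-to-grid warping paths (dynamic programming with a configurable
#' slope window), i.e. the warp that carries curve 2 onto curve 1.  The
#' attained value is the elastic y-distance between the two curves.
#'
#' @param q1,q2 `srsf_curve` objects on a common unit grid (see
#'   [srsf_transform()]).
#' @param max_step slope window of the warping path: steps advance up to
#'   `max_step` grid points on either axis (coprime pairs), so representable
#'   local slopes range over \{a/b : 1 <= a, b <= max_step\}.
#' @return list with `warp` (a [warp_fun()]), and `distance` (D_y, the
#'   attained L2 value, >= 0).
#' @export
align_pair <- function(q1, q2, max_step = 6L) {
  stopifnot(inherits(q1, "srsf_curve"), inherits(q2, "srsf_curve"))
  if (!isTRUE(all.equal(q1$times, q2$times)))
    stop("the two curves must share a grid")
  res <- .dp_align_cpp(q1$times, q1$q, q2$q, as.integer(max_step))
  list(warp = warp_fun(res$gamma, q1$times),
       distance = sqrt(max(0, res$cost)))
}

#' Elastically align a set of curves to a common template
#'
#' Iterative template procedure: the template starts as the cross-sectional
#' mean SRSF; every curve is aligned to it with [align_pair()]; the template
#' is replaced by the mean of the aligned SRSFs; repeat until the template
#' moves less than `tol` in L2 or `max_iter` is reached.
#'
#' @param curves a [curve_set()].
#' @param tol template convergence tolerance (L2 norm of the update).
#' @param max_iter iteration cap; non-convergence returns the best iterate
#'   with `converged = FALSE`.
#' @param max_step passed to [align_pair()].
#' @return list of class `alignment` with `template` (mean function values on
#'   the unit grid), `template_q`, `unit_times`, `grid_map` (from
#'   [normalize_grid()]), `warps` (list of `warp_fun`, one per curve:
#'   curve a composed with its warp matches the template), `aligned_values`,
#'   `aligned_q`, `distances` (D_y per curve), `converged`, `iterations`.
#' @export
align_set <- function(curves, tol = 1e-4, max_iter = 20L, max_step = 6L) {
  stopifnot(inherits(curves, "curve_set"))
  n <- n_curves(curves)
  if (n < 2L) stop("need at least 2 curves to align")
  gm <- normalize_grid(curves$times)
  u <- gm$unit_times
  vals <- curves$values
  qs <- lapply(seq_len(n), function(a) srsf_transform(vals[a, ], u))
  qmat <- t(vapply(qs, function(x) x$q, numeric(length(u))))

  template_q <- colMeans(qmat)
  warps <- vector("list", n)
  aligned_values <- vals
  aligned_q <- qmat
  distances <- numeric(n)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    tq <- structure(list(times = u, q = template_q, f0 = 0),
                    class = "srsf_curve")
    for (a in seq_len(n)) {
      pa <- align_pair(tq, qs[[a]], max_step = max_step)
      warps[[a]] <- pa$warp
      distances[a] <- pa$distance
      aligned_values[a, ] <- apply_warp(vals[a, ], pa$warp)
      aligned_q[a, ] <- srsf_transform(aligned_values[a, ], u)$q
    }
    new_template <- colMeans(aligned_q)
    delta <- grid_norm(u, new_template - template_q)
    template_q <- new_template
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("template did not converge in ", max_iter,
            " iterations; returning the last iterate")
  tq <- structure(list(times = u, q = template_q,
                       f0 = mean(vals[, 1L])), class = "srsf_curve")
  structure(
    list(template = srsf_inverse(tq), template_q = template_q,
         unit_times = u, grid_map = gm, warps = warps,
         aligned_values = aligned_values, aligned_q = aligned_q,
         distances = distances, converged = converged, iterations = it),
    class = "alignment"
  )
}

#' @export
print.alignment <- function(x, ...) {
  cat("Elastic alignment of", length(x$warps), "curves on",
      length(x$unit_times), "grid points\n")
  cat("  converged:", x$converged, "after", x$iterations, "iteration(s)\n")
  cat("  y-distances: ", paste(format(x$distances, digits = 3),
                               collapse = ", "), "\n")
  invisible(x)
}
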