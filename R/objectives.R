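# Reconstruction from a subset of time points and the three selection
# criteria.
#
# All three criteria are expected squared L2 reconstruction errors over the
# full time range, estimated by Monte Carlo over J curves drawn from the
# fitted density:
#   f1 - error of the curve itself,
#   f2 - error of the difference to a control condition,
#   f3 - error of the difference normalised by its pointwise standard
#        deviation (the inverse coefficient of variation), which down-weights
#        noisy stretches of the time course.
# Interpolation from a subset (linear or B-spline of degree R) is a linear
# operator in the subset values, so it is represented as a reconstruction
# matrix and applied to whole sample matrices at once.

#' Specification of a selection objective
#'
#' @param criterion `"f1"` (curve shape), `"f2"` (difference to control) or
#'   `"f3"` (variance-normalised difference).
#' @param control required for f2/f3: either a numeric control curve on the
#'   full grid (a single, unreplicated control) or a [fit_curve_density()]
#'   object from replicated controls (a control drawn per sample).
#' @param J Monte-Carlo sample count (default 1000).
#' @param seed integer seed.
#' @param interpolation `"linear"` or `"spline"`.
#' @param spline_degree spline degree R >= 1 (only used for
#'   `interpolation = "spline"`).
#' @param variance_floor f3 only: the pointwise variance is floored at
#'   `variance_floor * max(variance)` to avoid division blow-ups where the
#'   reconstruction is exact (default 1e-6).
#' @param cv_target f3 only: if TRUE, normalise the full-resolution
#'   difference by its pointwise standard deviation first and then apply the
#'   f2 machinery (fit the inverse coefficient of variation itself), instead
#'   of normalising the subset-dependent reconstruction error.  Default
#'   FALSE.
#' @return an object of class `objective_spec`.
#' @export
objective_spec <- function(criterion = c("f1", "f2", "f3"), control = NULL,
                           J = 1000L, seed = 1L,
                           interpolation = c("linear", "spline"),
                           spline_degree = 3L, variance_floor = 1e-6,
                           cv_target = FALSE) {
  criterion <- match.arg(criterion)
  interpolation <- match.arg(interpolation)
  if (criterion %in% c("f2", "f3") && is.null(control))
    stop("criterion ", criterion, " requires a control curve or density")
  if (J < 1L) stop("J must be >= 1")
  if (spline_degree < 1L) stop("spline_degree must be >= 1")
  structure(
    list(criterion = criterion, control = control, J = as.integer(J),
         seed = as.integer(seed), interpolation = interpolation,
         spline_degree = as.integer(spline_degree),
         variance_floor = variance_floor, cv_target = isTRUE(cv_target)),
    class = "objective_spec"
  )
}

#' Linear reconstruction operator from a subset of grid points
#'
#' Returns the N x M matrix R such that `R %*% values_at_subset` is the
#' reconstruction of a curve on the full grid from its values at the subset,
#' by linear interpolation or a degree-R interpolating B-spline.  Outside
#' the subset range the reconstruction is constant from the nearest
#' selected point.
#'
#' @param times full grid.
#' @param indices subset (strictly increasing 1-based indices).
#' @param method `"linear"` or `"spline"`.
#' @param degree spline degree; silently capped at `length(indices) - 1`
#'   (with a warning) when too few points are selected.
#' @return N x M reconstruction matrix.
#' @export
interp_operator <- function(times, indices, method = c("linear", "spline"),
                            degree = 3L) {
  method <- match.arg(method)
  indices <- as.integer(indices)
  if (length(indices) == 0L) stop("subset must be non-empty")
  if (any(diff(indices) <= 0)) stop("subset indices must be strictly increasing")
  if (indices[1L] < 1L || indices[length(indices)] > length(times))
    stop("subset indices out of range")
  x <- times[indices]
  M <- length(indices)
  N <- length(times)
  if (M == 1L) return(matrix(1, N, 1L))
  # clamp evaluation points: constant extrapolation outside [x_1, x_M]
  xe <- pmin(pmax(times, x[1L]), x[M])
  if (method == "linear" || degree == 1L || M == 2L) {
    op <- matrix(0, N, M)
    seg <- findInterval(xe, x, rightmost.closed = TRUE)
    seg <- pmin(pmax(seg, 1L), M - 1L)
    wts <- (xe - x[seg]) / (x[seg + 1L] - x[seg])
    for (i in seq_len(N)) {
      op[i, seg[i]] <- 1 - wts[i]
      op[i, seg[i] + 1L] <- op[i, seg[i] + 1L] + wts[i]
    }
    return(op)
  }
  deg <- as.integer(degree)
  if (deg >= M) {
    warning("spline degree ", deg, " needs more than ", M,
            " points; using degree ", M - 1L)
    deg <- M - 1L
  }
  ord <- deg + 1L
  # clamped knot vector with interior knots by the averaging rule, which
  # guarantees the interpolation problem is well posed (Schoenberg-Whitney)
  interior <- if (M > ord)
    vapply(seq_len(M - ord), function(j) mean(x[(j + 1L):(j + ord - 1L)]),
           numeric(1L))
  else numeric(0)
  knots <- c(rep(x[1L], ord), interior, rep(x[M], ord))
  B <- splines::splineDesign(knots, x, ord = ord, outer.ok = FALSE)
  E <- splines::splineDesign(knots, xe, ord = ord, outer.ok = FALSE)
  E %*% solve(B)
}

#' Reconstruct curves on the full grid from a subset of time points
#'
#' @param values a curve (vector) or matrix of curves (rows) on the full
#'   grid.
#' @param times full grid.
#' @param indices selected time-point indices.
#' @param method,degree see [interp_operator()].
#' @return reconstruction with the same shape as `values`.
#' @export
interpolate_subset <- function(values, times, indices,
                               method = c("linear", "spline"), degree = 3L) {
  op <- interp_operator(times, indices, method, degree)
  if (is.matrix(values)) {
    values[, indices, drop = FALSE] %*% t(op)
  } else {
    drop(op %*% values[indices])
  }
}

#' Squared L2 distance between two sampled curves
#'
#' Trapezoidal approximation of the integral of (a - b)^2 over the grid
#' (optionally restricted to an index interval), in original time units.
#'
#' @param a,b curve values on `times`.
#' @param times common grid.
#' @param interval optional integer range `c(i, k)` restricting the
#'   integral to `[times[i], times[k]]`.
#' @return non-negative scalar.
#' @export
l2_error_sq <- function(a, b, times, interval = NULL) {
  if (length(a) != length(b) || length(a) != length(times))
    stop("curves and grid must have equal length")
  if (!is.null(interval)) {
    idx <- interval[1L]:interval[2L]
    a <- a[idx]; b <- b[idx]; times <- times[idx]
  }
  if (length(times) < 2L) return(0)
  sum(trapz_weights(times) * (a - b)^2)
}

#' Difference curves between control and sampled experiment curves
#'
#' For each sample j returns d_j = g_j - w_j on the full grid.  With a
#' single control curve g is fixed; with a control density a control curve
#' is drawn independently per sample (the product measure over the two
#' conditions).
#'
#' @param samples a `sampled_curves` object (or plain matrix of curves).
#' @param control numeric control curve on the same grid, or a
#'   `curve_density` for replicated controls.
#' @param seed seed used to draw controls when `control` is a density;
#'   defaults to the samples' seed + 1.
#' @return matrix of difference curves, same shape as the samples.
#' @export
difference_curves <- function(samples, control, seed = NULL) {
  vals <- if (inherits(samples, "sampled_curves")) samples$values
          else as.matrix(samples)
  J <- nrow(vals)
  if (inherits(control, "curve_density")) {
    if (is.null(seed))
      seed <- (if (inherits(samples, "sampled_curves")) samples$seed else 0L) + 1L
    g <- sample_curves(control, J = J, seed = seed)$values
    if (!isTRUE(all.equal(length(control$times), ncol(vals))))
      stop("control grid does not match the sample grid")
    g - vals
  } else {
    control <- as.numeric(control)
    if (length(control) != ncol(vals))
      stop("control grid does not match the sample grid")
    sweep(-vals, 2L, control, `+`)
  }
}

# Criterion-specific base matrix: the curves whose reconstruction error the
# objective integrates.  f1 uses the samples themselves (f1 is exactly f2
# with g = 0); f2/f3 use the control-experiment difference.
objective_base <- function(samples, spec) {
  vals <- if (inherits(samples, "sampled_curves")) samples$values
          else if (inherits(samples, "curve_set")) samples$values
          else as.matrix(samples)
  if (spec$criterion == "f1") -vals
  else difference_curves(samples, spec$control)
}

#' Monte-Carlo estimate of a selection objective
#'
#' Computes f1, f2 or f3 for a given subset of time points: the mean over
#' samples of the squared L2 distance between each (difference) curve and
#' its reconstruction from the subset, over the full time range.  For f3
#' the reconstruction error is divided pointwise by its sample variance
#' across the Monte-Carlo draws (floored at
#' `variance_floor * max(variance)`).  The 1/J factor is kept so estimates
#' are comparable across J; it does not change the minimiser.
#'
#' @param sel a `timepoint_selection` or a vector of selected indices.
#' @param samples a `sampled_curves` from [sample_curves()], or a
#'   [curve_set()] (whose per-curve weights are honoured for f1).
#' @param spec an [objective_spec()].
#' @param weights optional per-curve weights (f1 only); defaults to the
#'   curve-set weights when `samples` is a `curve_set`.
#' @return non-negative scalar.
#' @export
estimate_objective <- function(sel, samples, spec, weights = NULL) {
  indices <- if (inherits(sel, "timepoint_selection")) sel$indices else
    as.integer(sel)
  times <- if (inherits(samples, "sampled_curves")) samples$times
           else if (inherits(samples, "curve_set")) samples$times
           else stop("samples must be sampled_curves or a curve_set")
  if (is.null(weights) && inherits(samples, "curve_set"))
    weights <- samples$weights
  if (!is.null(weights) && !all(weights == weights[1L]) &&
      spec$criterion != "f1")
    stop("per-curve weights are defined for f1 only")
  D <- objective_base(samples, spec)
  J <- nrow(D)
  if (spec$criterion == "f3" && J < 3L)
    stop("f3 needs at least 3 samples to estimate the pointwise variance")
  if (spec$criterion == "f3" && spec$cv_target) {
    v <- apply(D, 2L, stats::var)
    v <- pmax(v, spec$variance_floor * max(v))
    D <- sweep(D, 2L, sqrt(v), `/`)
  }
  Z <- interpolate_subset(D, times, indices,
                          method = spec$interpolation,
                          degree = spec$spline_degree) - D
  if (spec$criterion == "f3" && !spec$cv_target) {
    v <- apply(Z, 2L, stats::var)
    if (max(v) == 0) return(0)  # exact reconstruction everywhere
    v <- pmax(v, spec$variance_floor * max(v))
    Z <- sweep(Z, 2L, sqrt(v), `/`)
  }
  w <- trapz_weights(times)
  per_curve <- as.numeric(Z^2 %*% w)
  if (is.null(weights)) mean(per_curve)
  else sum(weights * per_curve) / J
}
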