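# The non-parametric probability density over curves.
#
# Pipeline: elastically align the curves, take the Karcher mean of the
# phase deformations, log-map each deformation into the tangent space at
# that mean, and fit independent fPCA models to (i) the tangent vectors
# (phase / x-deformation model) and (ii) the aligned curves (amplitude /
# y-deformation model).  Scores on each retained axis are modelled as
# independent zero-mean Gaussians with variance equal to the eigenvalue, so
# the measure over curves is a diagonal multivariate normal in fPCA
# coordinates.  Sampling draws scores, exponentiates the phase tangent back
# to a warp, reconstructs an amplitude curve, and composes the two.

#' Fit a probability density over curves
#'
#' @param curves a [curve_set()] with at least 2 (ideally >= 3) curves.
#' @param variance_threshold fraction of variance each fPCA model must
#'   retain (default 0.95), applied independently to the phase and
#'   amplitude models.
#' @param tol,max_iter,max_step alignment controls, see [align_set()].
#' @return object of class `curve_density` with elements `alignment`,
#'   `karcher_warp` (Karcher mean of the phase deformations),
#'   `warp_model` (fPCA of warp tangent vectors), `amplitude_model`
#'   (fPCA of aligned curves), `times` (original grid), `unit_times`,
#'   `grid_map`, `mean_curve` (the zero-variance sample, original grid),
#'   and `call`.
#' @seealso [sample_curves()], [simulate.curve_density()],
#'   [pick_timepoints()]
#' @export
#' @examples
#' cs <- skew_gaussian_curves(n_curves = 3, n_times = 25, seed = 1)
#' fit <- fit_curve_density(cs)
#' fit
fit_curve_density <- function(curves, variance_threshold = 0.95,
                              tol = 1e-4, max_iter = 20L, max_step = 6L) {
  stopifnot(inherits(curves, "curve_set"))
  al <- align_set(curves, tol = tol, max_iter = max_iter,
                  max_step = max_step)
  u <- al$unit_times
  # phase deformations: the warp mapping the template onto each curve
  deformations <- lapply(al$warps, invert_warp)
  kmean <- karcher_mean_warps(deformations)
  tangents <- t(vapply(deformations, function(w) log_map(kmean, w)$v,
                       numeric(length(u))))
  warp_model <- fit_fpca(tangents, u, variance_threshold = variance_threshold,
                         center = FALSE)
  amplitude_model <- fit_fpca(al$aligned_values, u,
                              variance_threshold = variance_threshold)
  obj <- structure(
    list(alignment = al, karcher_warp = kmean, warp_model = warp_model,
         amplitude_model = amplitude_model, times = curves$times,
         unit_times = u, grid_map = al$grid_map,
         n_curves = n_curves(curves), call = match.call()),
    class = "curve_density"
  )
  obj$mean_curve <- drop(sample_curves(obj, J = 1L, seed = 1L,
                                       zero_variance = TRUE)$values)
  obj
}

#' Alias following the naming of the underlying procedure
#' @inheritParams fit_curve_density
#' @param ... passed to [fit_curve_density()]
#' @return a `curve_density`
#' @export
fit_distribution <- function(curves, variance_threshold = 0.95, ...) {
  fit_curve_density(curves, variance_threshold = variance_threshold, ...)
}

#' @export
print.curve_density <- function(x, ...) {
  cat("Probability density over curves fitted to", x$n_curves, "curves on",
      length(x$times), "time points\n")
  cat("  phase model:     ")
  print(x$warp_model)
  cat("  amplitude model: ")
  print(x$amplitude_model)
  invisible(x)
}

#' @export
summary.curve_density <- function(object, ...) {
  out <- list(
    n_curves = object$n_curves,
    n_times = length(object$times),
    converged = object$alignment$converged,
    distances = object$alignment$distances,
    phase_variances = object$warp_model$eigenvalues,
    phase_retained = object$warp_model$n_components,
    amplitude_variances = object$amplitude_model$eigenvalues,
    amplitude_retained = object$amplitude_model$n_components
  )
  class(out) <- "summary.curve_density"
  out
}

#' @export
print.summary.curve_density <- function(x, ...) {
  cat("Curve density fitted to", x$n_curves, "curves on", x$n_times,
      "time points (alignment converged:", x$converged, ")\n")
  cat("Phase (x-deformation) variances: ",
      paste(format(x$phase_variances, digits = 3), collapse = ", "),
      " [", x$phase_retained, " retained]\n", sep = "")
  cat("Amplitude (y-deformation) variances: ",
      paste(format(x$amplitude_variances, digits = 3), collapse = ", "),
      " [", x$amplitude_retained, " retained]\n", sep = "")
  invisible(x)
}

#' @export
coef.curve_density <- function(object, ...) {
  list(phase_eigenvalues = object$warp_model$eigenvalues,
       phase_scores = object$warp_model$scores,
       amplitude_eigenvalues = object$amplitude_model$eigenvalues,
       amplitude_scores = object$amplitude_model$scores)
}

#' @export
residuals.curve_density <- function(object, ...) {
  # residual amplitude variation not captured by the retained components
  am <- object$amplitude_model
  if (am$degenerate) return(object$alignment$aligned_values * 0)
  recon <- fpca_reconstruct(am, n_components = am$n_components)
  object$alignment$aligned_values - recon
}

#' @export
plot.curve_density <- function(x, J = 50L, seed = 1L, ...) {
  sc <- sample_curves(x, J = J, seed = seed)
  graphics::matplot(x$times, t(sc$values), type = "l", lty = 1,
                    col = grDevices::grey(0.7), xlab = "time",
                    ylab = "value", ...)
  graphics::lines(x$times, x$mean_curve, col = "black", lwd = 2)
  invisible(x)
}

#' Assemble a curve density from explicitly specified components
#'
#' Builds a `curve_density` directly from a mean amplitude curve, optional
#' phase and amplitude eigenfunctions (unit norm under the trapezoidal grid
#' inner product) and their score variances, without fitting.  Useful for
#' simulation studies with a known ground-truth model and as an extension
#' point for densities specified by the analyst.
#'
#' @param times sampling grid (treated as the unit grid if it already spans
#'   [0, 1]; otherwise normalised internally).
#' @param amplitude_mean mean amplitude curve on `times`.
#' @param warp_eigenfunctions matrix (components x N) of tangent-space
#'   eigenfunctions at the Karcher warp; may be NULL for no phase
#'   variation.  Each must be orthogonal to the Karcher warp's psi.
#' @param warp_variances score variances for the phase components.
#' @param amplitude_eigenfunctions matrix (components x N); NULL for no
#'   amplitude variation.
#' @param amplitude_variances score variances for the amplitude components.
#' @param karcher_warp central warp (default identity).
#' @return a `curve_density` usable with [sample_curves()] and
#'   [pick_timepoints()].
#' @export
curve_density_model <- function(times, amplitude_mean,
                                warp_eigenfunctions = NULL,
                                warp_variances = NULL,
                                amplitude_eigenfunctions = NULL,
                                amplitude_variances = NULL,
                                karcher_warp = NULL) {
  check_grid(times)
  gm <- normalize_grid(times)
  u <- gm$unit_times
  N <- length(u)
  if (is.null(karcher_warp)) karcher_warp <- identity_warp(u)
  as_model <- function(eigenfun, vars, mean_function) {
    if (is.null(eigenfun) || length(vars) == 0L) {
      structure(list(times = u, mean_function = mean_function,
                     eigenfunctions = matrix(0, 0L, N),
                     eigenvalues = numeric(0), scores = matrix(0, 1L, 0L),
                     n_components = 0L, total_variance = 0,
                     degenerate = TRUE), class = "fpca_model")
    } else {
      eigenfun <- matrix(eigenfun, ncol = N)
      ord <- order(vars, decreasing = TRUE)
      structure(list(times = u, mean_function = mean_function,
                     eigenfunctions = eigenfun[ord, , drop = FALSE],
                     eigenvalues = as.numeric(vars[ord]),
                     scores = matrix(0, 1L, length(vars)),
                     n_components = length(vars),
                     total_variance = sum(vars), degenerate = FALSE),
                class = "fpca_model")
    }
  }
  obj <- structure(
    list(alignment = NULL,
         karcher_warp = karcher_warp,
         warp_model = as_model(warp_eigenfunctions, warp_variances,
                               numeric(N)),
         amplitude_model = as_model(amplitude_eigenfunctions,
                                    amplitude_variances,
                                    as.numeric(amplitude_mean)),
         times = as.numeric(times), unit_times = u, grid_map = gm,
         n_curves = 0L, call = match.call()),
    class = "curve_density")
  obj$mean_curve <- drop(sample_curves(obj, J = 1L, seed = 1L,
                                       zero_variance = TRUE)$values)
  obj
}

#' Draw perturbation curves from a fitted curve density
#'
#' For each sample: draw independent normal scores on every retained axis of
#' the phase and amplitude models, exponentiate the phase tangent vector to
#' a warp at the Karcher mean, reconstruct the amplitude curve, and return
#' the amplitude evaluated at the warp (on the original grid).  Visualising
#' these samples against the training curves is the recommended sanity
#' check of the fitted density.
#'
#' @param dist a `curve_density`.
#' @param J number of samples (default 1000).
#' @param seed integer seed; identical `(dist, J, seed)` give identical
#'   output.
#' @param zero_variance draw all scores as 0 (returns the mean curve).
#' @return object of class `sampled_curves`: `times`, `values` (J x N),
#'   `seed`, `phase_scores`, `amplitude_scores`, `n_repaired` (samples whose
#'   warp needed monotonicity repair).
#' @export
sample_curves <- function(dist, J = 1000L, seed = 1L, zero_variance = FALSE) {
  stopifnot(inherits(dist, "curve_density"), J >= 1L)
  u <- dist$unit_times
  N <- length(u)
  wm <- dist$warp_model
  am <- dist$amplitude_model
  kx <- if (wm$degenerate) 0L else wm$n_components
  ky <- if (am$degenerate) 0L else am$n_components
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  draw <- function(k, lam) {
    if (k == 0L || zero_variance) return(matrix(0, J, max(k, 0L)))
    matrix(rnorm(J * k, sd = rep(sqrt(lam[seq_len(k)]), each = J)), J, k)
  }
  sx <- draw(kx, wm$eigenvalues)
  sy <- draw(ky, am$eigenvalues)
  amp <- fpca_reconstruct(am, scores = sy, n_components = ky)
  if (nrow(amp) == 1L && J > 1L)
    amp <- matrix(amp, J, N, byrow = TRUE)
  values <- matrix(0, J, N)
  n_repaired <- 0L
  for (j in seq_len(J)) {
    v <- if (kx > 0L)
      drop(sx[j, , drop = FALSE] %*%
             wm$eigenfunctions[seq_len(kx), , drop = FALSE])
    else numeric(N)
    gam <- withCallingHandlers(
      exp_map(dist$karcher_warp, v),
      warning = function(w) {
        if (grepl("monotonicity", conditionMessage(w))) {
          n_repaired <<- n_repaired + 1L
          invokeRestart("muffleWarning")
        }
      })
    values[j, ] <- stats::approx(u, amp[j, ], xout = gam$gamma, rule = 2)$y
  }
  structure(
    list(times = dist$times, values = values, seed = as.integer(seed),
         phase_scores = sx, amplitude_scores = sy, n_repaired = n_repaired),
    class = "sampled_curves"
  )
}

#' @export
print.sampled_curves <- function(x, ...) {
  cat("Sampled curves:", nrow(x$values), "draws on", length(x$times),
      "time points (seed", x$seed, ")\n")
  if (x$n_repaired > 0L)
    cat("  monotonicity repair triggered for", x$n_repaired, "warp(s)\n")
  invisible(x)
}

#' @export
#' @importFrom stats simulate
simulate.curve_density <- function(object, nsim = 1L, seed = 1L, ...) {
  sample_curves(object, J = nsim, seed = seed)
}
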