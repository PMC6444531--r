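# Functional principal component analysis on a grid.
#
# Discretised fPCA with trapezoidal quadrature weights W: the eigenproblem
# of the weighted covariance W^{1/2} C W^{1/2} gives eigenfunctions that are
# orthonormal under the grid inner product <f, g> = sum(W f g), and
# eigenvalues equal to the variance of the scores along each axis.

#' Fit a functional PCA model
#'
#' @param functions matrix, one row per function, sampled on `times`.
#' @param times common grid.
#' @param variance_threshold retain the smallest number of components whose
#'   cumulative eigenvalue fraction reaches this value (default 0.95).
#' @param center subtract the cross-sectional mean first (default TRUE).
#' @return object of class `fpca_model`: `times`, `mean_function`,
#'   `eigenfunctions` (rows, orthonormal under the grid inner product),
#'   `eigenvalues` (non-increasing), `scores` (inputs x components, all
#'   components), `n_components` (retained count), `total_variance`,
#'   `degenerate` (TRUE when the inputs carry no variance).
#' @export
fit_fpca <- function(functions, times, variance_threshold = 0.95,
                     center = TRUE) {
  functions <- as.matrix(functions)
  check_grid(times)
  if (ncol(functions) != length(times)) stop("functions/grid mismatch")
  if (nrow(functions) < 2L) stop("need at least 2 functions")
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("variance_threshold must be in (0, 1]")
  n <- nrow(functions)
  N <- length(times)
  mean_function <- if (center) colMeans(functions) else numeric(N)
  X <- sweep(functions, 2L, mean_function)
  w <- trapz_weights(times)
  sw <- sqrt(w)
  # weighted covariance, divisor n - 1
  Y <- sweep(X, 2L, sw, `*`)
  C <- crossprod(Y) / (n - 1L)
  eg <- eigen(C, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  total <- sum(lam)
  if (total < 1e-14) {
    # no variability at all: an all-zero model
    return(structure(
      list(times = as.numeric(times), mean_function = mean_function,
           eigenfunctions = matrix(0, 0L, N), eigenvalues = numeric(0),
           scores = matrix(0, n, 0L), n_components = 0L,
           total_variance = 0, degenerate = TRUE),
      class = "fpca_model"))
  }
  # keep the numerically meaningful part of the spectrum
  keep_all <- lam > total * 1e-12
  lam <- lam[keep_all]
  phi <- sweep(eg$vectors[, keep_all, drop = FALSE], 1L, sw, `/`)
  # scores under the grid inner product
  scores <- X %*% (phi * w)
  cum <- cumsum(lam) / total
  ncomp <- which(cum >= variance_threshold - 1e-12)[1L]
  structure(
    list(times = as.numeric(times), mean_function = mean_function,
         eigenfunctions = t(phi), eigenvalues = lam, scores = scores,
         n_components = as.integer(ncomp), total_variance = total,
         degenerate = FALSE),
    class = "fpca_model"
  )
}

#' @export
print.fpca_model <- function(x, ...) {
  if (x$degenerate) {
    cat("fPCA model: degenerate (no variance)\n")
  } else {
    frac <- cumsum(x$eigenvalues) / x$total_variance
    cat("fPCA model:", length(x$eigenvalues), "components,",
        x$n_components, "retained (",
        round(100 * frac[x$n_components], 1), "% of variance)\n")
  }
  invisible(x)
}

#' Reconstruct functions from an fPCA model
#'
#' @param model an `fpca_model`.
#' @param scores score matrix (rows = functions); defaults to the fitted
#'   scores.
#' @param n_components how many leading components to use; defaults to all
#'   columns of `scores`.
#' @return matrix of reconstructed functions (mean + score-weighted
#'   eigenfunctions).
#' @export
fpca_reconstruct <- function(model, scores = model$scores,
                             n_components = ncol(scores)) {
  scores <- as.matrix(scores)
  if (model$degenerate || n_components == 0L) {
    return(matrix(model$mean_function, nrow = max(1L, nrow(scores)),
                  ncol = length(model$times), byrow = TRUE))
  }
  k <- min(n_components, nrow(model$eigenfunctions), ncol(scores))
  sweep(scores[, seq_len(k), drop = FALSE] %*%
          model$eigenfunctions[seq_len(k), , drop = FALSE],
        2L, model$mean_function, `+`)
}
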