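# Synthetic curve populations with known structure.
#
# Three families: skew-Gaussian triplets (small-n realism check for the
# density), warped copies of a fixed template (phase-recovery ground
# truth), and a "noisy early window, informative late window" scenario
# (control vs experiment with localised noise, exercising f3).  All
# generators are pure functions of their arguments and seed, and leave the
# caller's RNG state untouched.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Random skew-Gaussian curves
#'
#' Each curve is f(t) = A * 2 * phi((t - m)/s) * Phi(alpha (t - m)/s), the
#' skew-normal density shape, with location m, scale s, skew alpha and
#' amplitude A drawn uniformly from the given ranges.
#'
#' @param n_curves number of curves (3 is a valid minimal input for
#'   [fit_curve_density()]).
#' @param n_times grid size (ignored when `times` is given).
#' @param times sampling grid; default a uniform unit grid.
#' @param m_range,s_range,alpha_range,amp_range parameter ranges.
#' @param seed integer seed.
#' @return a [curve_set()]; the drawn parameters are attached as attribute
#'   `parameters` (a data frame with columns m, s, alpha, A).
#' @export
skew_gaussian_curves <- function(n_curves = 3L, n_times = 24L,
                                 times = seq(0, 1, length.out = n_times),
                                 m_range = c(0.3, 0.7),
                                 s_range = c(0.05, 0.2),
                                 alpha_range = c(-5, 5),
                                 amp_range = c(0.5, 1.5), seed = 1L) {
  if (s_range[1L] <= 0) stop("scale range must be positive")
  pars <- with_seed(seed, data.frame(
    m = runif(n_curves, m_range[1L], m_range[2L]),
    s = runif(n_curves, s_range[1L], s_range[2L]),
    alpha = runif(n_curves, alpha_range[1L], alpha_range[2L]),
    A = runif(n_curves, amp_range[1L], amp_range[2L])
  ))
  vals <- t(vapply(seq_len(n_curves), function(i) {
    z <- (times - pars$m[i]) / pars$s[i]
    pars$A[i] * 2 * dnorm(z) * pnorm(pars$alpha[i] * z)
  }, numeric(length(times))))
  out <- curve_set(vals, times,
                   labels = sprintf("curve%02d", seq_len(n_curves)))
  attr(out, "parameters") <- pars
  attr(out, "seed") <- as.integer(seed)
  out
}

# exponential-family warp on [0,1]: (e^{a t} - 1)/(e^a - 1); identity at a=0
exp_warp_values <- function(times, a) {
  if (abs(a) < 1e-8) return(times)
  (exp(a * times) - 1) / (exp(a) - 1)
}

#' Warped copies of a fixed template
#'
#' A Gaussian-bump template composed with random monotone warps
#' gamma_a(t) = (e^{a t} - 1)/(e^a - 1), a ~ U(-strength, strength).  The
#' drawn warp parameters are centred (sum of a = 0) so the population's
#' mean phase deformation is close to the identity, which makes the
#' individual warps identifiable from the data alone.
#'
#' @param n_curves number of curves.
#' @param n_times grid size.
#' @param strength warp strength (0 gives identical curves and identity
#'   warps).
#' @param template function of t on [0, 1]; default a Gaussian bump centred
#'   at 0.5.
#' @param seed integer seed.
#' @return list with `curves` (a [curve_set()] on the unit grid),
#'   `true_warps` (list of [warp_fun()]), `a` (drawn warp parameters).
#' @export
warped_template_curves <- function(n_curves = 9L, n_times = 50L,
                                   strength = 1,
                                   template = function(t)
                                     exp(-(t - 0.5)^2 / (2 * 0.12^2)),
                                   seed = 1L) {
  if (strength < 0) stop("strength must be >= 0")
  times <- seq(0, 1, length.out = n_times)
  a <- with_seed(seed, runif(n_curves, -strength, strength))
  a <- a - mean(a)
  warps <- lapply(a, function(ai) warp_fun(exp_warp_values(times, ai), times))
  vals <- t(vapply(warps, function(w) template(w$gamma),
                   numeric(n_times)))
  list(curves = curve_set(vals, times), true_warps = warps, a = a)
}

#' Control/experiment scenario with a noisy and an informative window
#'
#' The control is a smooth baseline bump.  Experimental curves add (i) a
#' systematic smooth offset inside the informative window and (ii)
#' high-variance smooth random bumps inside the noisy window.  The two
#' windows must not overlap.  The f3 criterion should steer selections away
#' from the noisy window, unlike f1.
#'
#' @param n_curves number of experimental curves.
#' @param n_times grid size.
#' @param noisy_window,informative_window `c(lo, hi)` on [0, 1].
#' @param offset systematic effect size in the informative window.
#' @param noise_sd standard deviation of the random bump amplitudes in the
#'   noisy window.
#' @param n_noise_basis number of random bumps spread over the noisy
#'   window.
#' @param seed integer seed.
#' @return list with `curves` (experimental [curve_set()]), `control`
#'   (numeric curve), `noisy_window`, `informative_window`.
#' @export
noisy_window_curves <- function(n_curves = 12L, n_times = 24L,
                                noisy_window = c(0, 0.35),
                                informative_window = c(0.55, 0.9),
                                offset = 1, noise_sd = 0.8,
                                n_noise_basis = 3L, seed = 1L) {
  if (noisy_window[2L] > informative_window[1L] &&
      noisy_window[1L] < informative_window[2L])
    stop("noisy and informative windows must not overlap")
  times <- seq(0, 1, length.out = n_times)
  bump <- function(c0, s) exp(-(times - c0)^2 / (2 * s^2))
  control <- 1 + bump(0.5, 0.25)
  inf_c <- mean(informative_window)
  inf_s <- diff(informative_window) / 4
  systematic <- offset * bump(inf_c, inf_s)
  centers <- seq(noisy_window[1L] + 0.1 * diff(noisy_window),
                 noisy_window[2L] - 0.1 * diff(noisy_window),
                 length.out = n_noise_basis)
  nb <- vapply(centers, function(c0) bump(c0, diff(noisy_window) / 8),
               numeric(n_times))
  amps <- with_seed(seed, matrix(rnorm(n_curves * n_noise_basis,
                                       sd = noise_sd),
                                 n_curves, n_noise_basis))
  vals <- matrix(control + systematic, n_curves, n_times, byrow = TRUE) +
    amps %*% t(nb)
  list(curves = curve_set(vals, times), control = control,
       noisy_window = noisy_window, informative_window = informative_window)
}
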