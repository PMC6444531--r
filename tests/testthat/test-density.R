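test_that("identical curves give a point-mass density", {
  u <- unit_grid(30)
  common <- gauss_bump(u)
  cs <- curve_set(matrix(rep(common, 3), 3, byrow = TRUE), u)
  fit <- fit_curve_density(cs)
  sc <- sample_curves(fit, J = 20, seed = 5)
  for (j in 1:20) expect_equal(sc$values[j, ], common)
  # perfect reconstruction at full selection
  sp <- objective_spec("f1", J = 20)
  expect_equal(estimate_objective(seq_along(u), sc, sp), 0)
})

test_that("pure phase variation loads the warp model, not the amplitude", {
  u <- unit_grid(60)
  warps <- lapply(c(-0.9, 0, 0.9), function(a) exp_warp(u, a))
  vals <- t(vapply(warps, function(g) gauss_bump(g, 0.45, 0.13),
                   numeric(60)))
  fit <- suppressWarnings(fit_curve_density(curve_set(vals, u)))
  # amplitude variation is a small residue of imperfect registration
  expect_lt(fit$amplitude_model$total_variance,
            0.05 * stats::var(as.numeric(vals)) * 60)
  expect_gt(fit$warp_model$total_variance, 0)
  # the fitted phase deformations track the true warps (identifiable only
  # up to a common warp with three curves, hence the loose bound; the
  # tight recovery bound is tested on the warped-template generator)
  defs <- lapply(fit$alignment$warps, invert_warp)
  for (i in 1:3)
    expect_lt(max(abs(defs[[i]]$gamma - warps[[i]])), 0.1)
})

test_that("pure amplitude variation gives a rank-1 y-model and a flat x-model", {
  u <- unit_grid(50)
  m <- gauss_bump(u, 0.5, 0.2) + 1
  # vertical shifts: the SRSF is shift-invariant, so elastic alignment
  # leaves these curves alone and all variation is pure amplitude
  vals <- rbind(m - 0.3, m, m + 0.3)
  fit <- suppressWarnings(fit_curve_density(curve_set(vals, u)))
  expect_gt(fit$amplitude_model$eigenvalues[1] /
              fit$amplitude_model$total_variance, 0.98)
  # phase model close to degenerate
  if (!fit$warp_model$degenerate)
    expect_lt(fit$warp_model$total_variance,
              0.02 * fit$amplitude_model$total_variance)
})

test_that("sampling is deterministic in (distribution, J, seed)", {
  cs <- skew_gaussian_curves(4, 20, seed = 3)
  fit <- suppressWarnings(fit_curve_density(cs))
  a <- sample_curves(fit, J = 25, seed = 42)
  b <- sample_curves(fit, J = 25, seed = 42)
  expect_identical(a$values, b$values)
  c <- sample_curves(fit, J = 25, seed = 43)
  expect_false(identical(c$values, a$values))
  # simulate() is the same backend
  d <- simulate(fit, nsim = 25, seed = 42)
  expect_identical(d$values, a$values)
})

test_that("Monte-Carlo mean of a rank-1 amplitude model matches its mean curve", {
  u <- unit_grid(40)
  mean_amp <- gauss_bump(u, 0.5, 0.15) + 1
  phi <- sqrt(2) * sin(pi * u)
  dist <- curve_density_model(u, mean_amp,
                              amplitude_eigenfunctions = phi,
                              amplitude_variances = 0.2^2)
  sc <- sample_curves(dist, J = 1000, seed = 9)
  mu_hat <- colMeans(sc$values)
  se <- apply(sc$values, 2, stats::sd) / sqrt(1000)
  expect_true(all(abs(mu_hat - mean_amp) <= 3 * pmax(se, 1e-12)))
})

test_that("zero-variance sampling returns the mean curve", {
  cs <- skew_gaussian_curves(4, 20, seed = 6)
  fit <- suppressWarnings(fit_curve_density(cs))
  sc <- sample_curves(fit, J = 5, seed = 1, zero_variance = TRUE)
  for (j in 1:5) expect_equal(sc$values[j, ], fit$mean_curve)
})

test_that("model methods expose coefficients and residuals coherently", {
  cs <- skew_gaussian_curves(5, 24, seed = 2)
  fit <- suppressWarnings(fit_curve_density(cs))
  co <- coef(fit)
  expect_named(co, c("phase_eigenvalues", "phase_scores",
                     "amplitude_eigenvalues", "amplitude_scores"))
  expect_true(all(diff(co$amplitude_eigenvalues) <= 1e-12))
  r <- residuals(fit)
  expect_equal(dim(r), dim(cs$values))
  s <- summary(fit)
  expect_s3_class(s, "summary.curve_density")
  expect_output(print(s), "Amplitude")
})
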