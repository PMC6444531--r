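test_that("skew-Gaussian curves follow their parameterisation", {
  # collapse every range: alpha = 0 gives a symmetric Gaussian bump
  cs <- skew_gaussian_curves(2, 41, m_range = c(0.5, 0.5),
                             s_range = c(0.1, 0.1),
                             alpha_range = c(0, 0),
                             amp_range = c(1, 1), seed = 2)
  u <- cs$times
  expected <- 2 * dnorm((u - 0.5) / 0.1) * pnorm(0)
  expect_equal(cs$values[1, ], expected)
  expect_equal(cs$values[1, ], rev(cs$values[1, ]), tolerance = 1e-12)

  expect_identical(skew_gaussian_curves(5, 20, seed = 7)$values,
                   skew_gaussian_curves(5, 20, seed = 7)$values)
  expect_error(skew_gaussian_curves(3, 20, s_range = c(0, 0.1)),
               "positive")
})

test_that("three skew-Gaussian curves are a valid density input", {
  cs <- skew_gaussian_curves(3, 24, seed = 5)
  fit <- suppressWarnings(fit_curve_density(cs))
  expect_s3_class(fit, "curve_density")
  sc <- sample_curves(fit, J = 10, seed = 1)
  expect_equal(dim(sc$values), c(10L, 24L))
  expect_true(all(is.finite(sc$values)))
})

test_that("warped templates carry their ground truth", {
  w0 <- warped_template_curves(5, 40, strength = 0, seed = 3)
  for (i in 2:5) expect_equal(w0$curves$values[i, ], w0$curves$values[1, ])
  for (w in w0$true_warps) expect_equal(w$gamma, w0$curves$times)

  wt <- warped_template_curves(7, 50, strength = 1, seed = 4)
  al <- align_set(wt$curves)
  for (i in 1:7) {
    rec <- invert_warp(al$warps[[i]])
    expect_lt(max(abs(rec$gamma - wt$true_warps[[i]]$gamma)), 0.05)
  }
  expect_error(warped_template_curves(3, 30, strength = -1), ">= 0")
})

test_that("stronger warps increase the mean elastic distance to the raw mean", {
  # a single alignment pass against the cross-sectional mean template:
  # iterating to convergence would absorb the warps and flatten the trend
  dys <- vapply(c(0.2, 1, 2, 3), function(s) {
    w <- warped_template_curves(7, 50, strength = s, seed = 5)
    mean(suppressWarnings(align_set(w$curves, max_iter = 1L))$distances)
  }, numeric(1))
  expect_true(all(diff(dys) > 0))
})

test_that("noisy-window scenario validates its configuration", {
  expect_error(noisy_window_curves(5, 24, noisy_window = c(0, 0.6),
                                   informative_window = c(0.5, 0.9)),
               "overlap")
  sc <- noisy_window_curves(8, 24, seed = 2)
  expect_equal(n_curves(sc$curves), 8L)
  expect_equal(length(sc$control), 24L)
})

test_that("a null scenario (no offset, no noise) is perfectly sampled", {
  sc <- noisy_window_curves(6, 20, offset = 0, noise_sd = 0, seed = 3)
  # every experimental curve equals the control
  for (i in 1:6) expect_equal(sc$curves$values[i, ], sc$control)
  # any selection reconstructs the (zero) difference exactly
  s <- as_samples(sc$curves$values, sc$curves$times)
  sp <- objective_spec("f2", control = sc$control, J = 6)
  expect_equal(estimate_objective(c(1, 10, 20), s, sp), 0)
})

test_that("without noise the f2 and f3 selections coincide", {
  sc <- noisy_window_curves(8, 20, noise_sd = 0, offset = 1, seed = 4)
  # add a small constant vertical shift per curve so the pointwise
  # standard deviation of the difference is constant in t: then the
  # variance normalisation is a global rescaling and cannot move the optimum
  vals <- sc$curves$values + 0.1 * rep(c(-1, 1), length.out = 8)
  s <- as_samples(vals, sc$curves$times)
  sel2 <- dp_select(build_edge_matrix(
    s, objective_spec("f2", control = sc$control, J = 8)), 5)
  sel3 <- dp_select(build_edge_matrix(
    s, objective_spec("f3", control = sc$control, J = 8,
                      cv_target = TRUE)), 5)
  expect_identical(sel2$indices, sel3$indices)
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(skew_gaussian_curves(3, 20, seed = 1))
  invisible(warped_template_curves(3, 20, seed = 1))
  invisible(noisy_window_curves(3, 20, seed = 1))
  expect_identical(.Random.seed, before)
})
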