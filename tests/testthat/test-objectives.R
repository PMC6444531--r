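test_that("interpolation from the full grid is lossless", {
  u <- unit_grid(41)
  y <- gauss_bump(u) + 0.2 * sin(5 * u)
  expect_equal(interpolate_subset(y, u, seq_along(u), "linear"), y)
  expect_equal(interpolate_subset(y, u, seq_along(u), "spline", 3), y,
               tolerance = 1e-9)
})

test_that("linear curves are fixed points of linear interpolation", {
  u <- unit_grid(25)
  y <- 2 - 3 * u
  for (idx in list(c(1, 25), c(1, 7, 25), c(1, 3, 19, 25)))
    expect_equal(interpolate_subset(y, u, idx, "linear"), y,
                 tolerance = 1e-12)
})

test_that("cubic splines beat linear interpolation on smooth curves", {
  u <- unit_grid(101)
  y <- u^3
  idx <- c(1, 26, 51, 76, 101)
  interior <- 2:100
  e_sp <- max(abs(interpolate_subset(y, u, idx, "spline", 3) - y)[interior])
  e_li <- max(abs(interpolate_subset(y, u, idx, "linear") - y)[interior])
  expect_lt(e_sp, e_li)
  # a cubic is reconstructed exactly by a degree-3 spline
  expect_lt(e_sp, 1e-12)
})

test_that("infeasible spline degrees fall back with a warning", {
  u <- unit_grid(20)
  expect_warning(interpolate_subset(u^2, u, c(1, 10, 20), "spline", 5),
                 "degree 2")
})

test_that("extrapolation outside the selection is constant", {
  u <- unit_grid(21)
  y <- 1 + u
  rec <- interpolate_subset(y, u, c(6, 16), "linear")
  expect_equal(rec[1:6], rep(y[6], 6))
  expect_equal(rec[16:21], rep(y[16], 6))
})

test_that("squared L2 distance matches the closed form and converges", {
  u <- unit_grid(101)
  expect_equal(l2_error_sq(u, u, u), 0)
  err101 <- abs(l2_error_sq(u^2, u, u) - 1 / 30)
  expect_lt(err101, 1e-3)
  u2 <- unit_grid(201)
  err201 <- abs(l2_error_sq(u2^2, u2, u2) - 1 / 30)
  expect_gt(err101 / err201, 3.5) # at least second-order convergence
  # interval restriction
  expect_equal(l2_error_sq(u, rep(0, 101), u, interval = c(1, 1)), 0)
})

test_that("difference curves follow the control conventions", {
  u <- unit_grid(20)
  W <- rbind(sin(pi * u), cos(pi * u), u)
  s <- as_samples(W, u)
  expect_equal(difference_curves(s, rep(0, 20)), -W)
  # samples identical to the control difference out exactly
  sc <- as_samples(rbind(sin(pi * u), sin(pi * u)), u)
  expect_equal(difference_curves(sc, sin(pi * u)),
               matrix(0, 2, 20))
  # fixed control minus constant samples
  cc <- as_samples(rbind(rep(1, 20), rep(-2, 20)), u)
  d <- difference_curves(cc, u)
  expect_equal(d[1, ], u - 1)
  expect_equal(d[2, ], u + 2)
  expect_error(difference_curves(s, rep(0, 19)), "grid")
})

test_that("f1 is exactly f2 with a zero control", {
  set.seed(31)
  u <- unit_grid(24)
  for (r in 1:10) {
    W <- matrix(rnorm(8 * 24), 8, 24)
    s <- as_samples(W, u)
    idx <- sort(sample(2:23, 4))
    f1 <- estimate_objective(idx, s, objective_spec("f1", J = 8))
    f2 <- estimate_objective(idx, s,
                             objective_spec("f2", control = rep(0, 24), J = 8))
    expect_equal(f1, f2, tolerance = 1e-12)
  }
})

test_that("objective estimates behave like expected squared errors", {
  u <- unit_grid(30)
  set.seed(17)
  W <- t(replicate(6, gauss_bump(u, runif(1, 0.4, 0.6), 0.12)))
  s <- as_samples(W, u)
  sp <- objective_spec("f1", J = 6)
  # full selection is perfect, any estimate is non-negative
  expect_equal(estimate_objective(seq_along(u), s, sp), 0)
  for (r in 1:5) {
    idx <- sort(sample(30, 5))
    expect_gte(estimate_objective(idx, s, sp), 0)
  }
  # all-linear samples with endpoints selected reconstruct exactly
  lin <- as_samples(rbind(2 * u, 1 - u, 0.3 + 0.5 * u), u)
  expect_equal(estimate_objective(c(1, 14, 30), lin, sp), 0)
})

test_that("per-curve weights scale f1 linearly and are rejected elsewhere", {
  u <- unit_grid(25)
  set.seed(23)
  W <- matrix(rnorm(4 * 25), 4, 25)
  cs <- curve_set(W, u)
  sp <- objective_spec("f1", J = 4)
  idx <- c(1, 9, 25)
  base <- estimate_objective(idx, cs, sp)
  scaled <- estimate_objective(idx, cs, sp, weights = rep(3, 4))
  expect_equal(scaled, 3 * base, tolerance = 1e-12)
  expect_error(
    estimate_objective(idx, cs, objective_spec("f2", control = rep(0, 25)),
                       weights = c(1, 2, 1, 1)),
    "f1 only")
})

test_that("f3 is scale invariant and needs enough samples", {
  u <- unit_grid(22)
  set.seed(13)
  W <- matrix(rnorm(6 * 22), 6, 22)
  g <- sin(pi * u)
  idx <- c(1, 8, 15, 22)
  for (cv in c(FALSE, TRUE)) {
    sp <- objective_spec("f3", control = g, J = 6, cv_target = cv)
    v1 <- estimate_objective(idx, as_samples(W, u), sp)
    sp_scaled <- objective_spec("f3", control = 5 * g, J = 6, cv_target = cv)
    v2 <- estimate_objective(idx, as_samples(5 * W, u), sp_scaled)
    expect_equal(v1, v2, tolerance = 1e-9)
  }
  expect_error(
    estimate_objective(idx, as_samples(W[1:2, ], u),
                       objective_spec("f3", control = g, J = 2)),
    "at least 3")
})

test_that("refinement of a convex curve is exactly monotone", {
  # for a convex curve the chord lies above the curve and refinement moves
  # the interpolant pointwise toward it, so the L2 error cannot grow
  u <- unit_grid(21)
  s <- as_samples(matrix(exp(2 * u), 1), u)
  sp <- objective_spec("f1", J = 1)
  f0 <- estimate_objective(c(1, 11, 21), s, sp)
  for (extra in setdiff(2:20, 11)) {
    f1 <- estimate_objective(sort(c(1, 11, 21, extra)), s, sp)
    expect_lte(f1, f0 + 1e-15)
  }
})

test_that("refinement decreases f1 for the large majority of smooth cases", {
  cs <- skew_gaussian_curves(8, 24, seed = 19)
  fit <- suppressWarnings(fit_curve_density(cs))
  sp <- objective_spec("f1", J = 50)
  set.seed(91)
  checks <- 0L; decreases <- 0L
  for (r in 1:5) {
    s <- sample_curves(fit, J = 50, seed = 600 + r)
    idx <- sort(sample(24, 6))
    f0 <- estimate_objective(idx, s, sp)
    for (extra in setdiff(1:24, idx)) {
      f1 <- estimate_objective(sort(c(idx, extra)), s, sp)
      checks <- checks + 1L
      decreases <- decreases + (f1 <= f0 + 1e-12)
    }
  }
  expect_gt(decreases / checks, 0.9)
})
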