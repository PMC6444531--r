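test_that("edge matrix has the documented structure", {
  u <- unit_grid(9)
  set.seed(3)
  W <- t(replicate(4, gauss_bump(u, runif(1, 0.4, 0.6), 0.15)))
  e <- build_edge_matrix(as_samples(W, u), objective_spec("f1", J = 4))
  N <- 9L
  Ew <- e$weights
  expect_equal(dim(Ew), c(N + 2L, N + 2L))
  # backward and self edges are infinite
  for (i in 1:(N + 2L)) for (k in 1:i)
    expect_identical(Ew[i, k], Inf)
  # adjacent-node edges cost nothing at grid-level evaluation
  for (i in 1:(N - 1L)) expect_equal(Ew[i + 1L, i + 2L], 0)
  # all forward edges are non-negative
  expect_true(all(Ew[upper.tri(Ew)] >= 0 | !is.finite(Ew[upper.tri(Ew)])))
})

test_that("all-linear samples make every interior edge vanish", {
  u <- unit_grid(8)
  W <- rbind(2 * u + 1, -u, 0.5 * u + 3)
  e <- build_edge_matrix(as_samples(W, u), objective_spec("f1", J = 3))
  for (i in 1:7) for (k in (i + 1):8)
    expect_equal(e$weights[i + 1L, k + 1L], 0, tolerance = 1e-14)
  # full selection costs nothing
  expect_equal(dp_select(e, 8)$objective_estimate, 0)
})

test_that("a single quadratic sample reproduces the hand trapezoid", {
  tt <- c(0, 0.5, 1)
  s <- as_samples(matrix(tt^2, 1), tt)
  e <- build_edge_matrix(s, objective_spec("f1", J = 1))
  # chord of t^2 between 0 and 1 evaluated on the grid is (0, 0.5, 1);
  # z = (0, 0.25, 0); trapezoid with weights (0.25, 0.5, 0.25) -> 0.03125
  expect_equal(e$weights[2, 4], 0.03125)
})

test_that("dp_select equals exhaustive enumeration on random instances", {
  set.seed(7)
  for (r in 1:15) {
    e <- random_edge_matrix(12)
    for (M in c(2, 4, 6)) {
      a <- dp_select(e, M)
      b <- brute_force_select(e, M)
      expect_identical(a$indices, b$indices)
      expect_identical(a$objective_estimate, b$objective_estimate)
      # path cost re-read from the edge matrix matches the DP tables
      expect_equal(path_cost(e, a$indices), a$objective_estimate,
                   tolerance = 1e-12)
    }
  }
})

test_that("exact ties resolve to the lexicographically smallest sequence", {
  N <- 4L
  E <- matrix(Inf, N + 2L, N + 2L)
  E[upper.tri(E)] <- 1
  E[1L, N + 2L] <- Inf
  e <- structure(list(weights = E, times = 1:4, criterion = "f1"),
                 class = "edge_matrix")
  # every 2-point path costs exactly 3; the smallest sequence is (1, 2)
  a <- dp_select(e, 2)
  b <- brute_force_select(e, 2)
  expect_identical(a$indices, c(1L, 2L))
  expect_identical(b$indices, c(1L, 2L))
})

test_that("hand-set weights favouring {2, 4} are found via the start/end path", {
  N <- 4L
  E <- matrix(Inf, N + 2L, N + 2L)
  for (i in 1:(N + 1L)) for (k in (i + 1L):(N + 2L)) E[i, k] <- 10
  E[1L, 3L] <- 0.1 # edge(0, 2)
  E[3L, 5L] <- 0.2 # edge(2, 4)
  E[5L, 6L] <- 0.3 # edge(4, end)
  e <- structure(list(weights = E, times = 1:4, criterion = "f1"),
                 class = "edge_matrix")
  b <- brute_force_select(e, 2)
  expect_identical(b$indices, c(2L, 4L))
  expect_equal(b$objective_estimate, 0.1 + 0.2 + 0.3)
  expect_identical(dp_select(e, 2)$indices, c(2L, 4L))
})

test_that("M = N selects every point at zero incremental cost", {
  u <- unit_grid(6)
  W <- rbind(sin(pi * u), cos(pi * u))
  e <- build_edge_matrix(as_samples(W, u), objective_spec("f1", J = 2))
  a <- dp_select(e, 6)
  expect_identical(a$indices, 1:6)
  expect_equal(a$objective_estimate, 0)
  expect_identical(brute_force_select(e, 6)$indices, 1:6)
  expect_error(dp_select(e, 7), "between 1 and")
})

test_that("single-point selection matches an independent exhaustive oracle", {
  tt <- unit_grid(9)
  cur <- sin(pi * tt)^0.25
  s <- as_samples(matrix(cur, 1), tt)
  sp <- objective_spec("f1", J = 1)
  d <- dp_select(build_edge_matrix(s, sp), 1)
  f <- vapply(1:9, function(j) estimate_objective(j, s, sp), numeric(1))
  expect_identical(d$indices, which.min(f))
  expect_equal(d$objective_estimate, min(f), tolerance = 1e-12)
})

test_that("dp path cost equals the full objective for linear f1", {
  cs <- skew_gaussian_curves(6, 18, seed = 13)
  fit <- suppressWarnings(fit_curve_density(cs))
  s <- sample_curves(fit, J = 40, seed = 2)
  sp <- objective_spec("f1", J = 40)
  e <- build_edge_matrix(s, sp)
  for (M in c(3, 5, 8)) {
    d <- dp_select(e, M)
    expect_equal(estimate_objective(d$indices, s, sp),
                 d$objective_estimate, tolerance = 1e-10)
  }
})

test_that("dp cost is non-increasing in M and beats every baseline", {
  cs <- skew_gaussian_curves(8, 20, seed = 17)
  fit <- suppressWarnings(fit_curve_density(cs))
  s <- sample_curves(fit, J = 60, seed = 3)
  e <- build_edge_matrix(s, objective_spec("f1", J = 60))
  costs <- vapply(1:10, function(M) dp_select(e, M)$objective_estimate,
                  numeric(1))
  expect_true(all(diff(costs) <= 1e-12))
  for (M in c(3, 6)) {
    opt <- dp_select(e, M)$objective_estimate
    for (strat in c("even", "random")) {
      b <- baseline_select(20, M, strat, seed = 5)
      expect_lte(opt, path_cost(e, b$indices) + 1e-12)
    }
  }
})

test_that("baseline selectors cover the documented cases", {
  expect_identical(baseline_select(12, 12, "even")$indices, 1:12)
  expect_identical(baseline_select(5, 2, "even")$indices, c(1L, 5L))
  r1 <- baseline_select(30, 7, "random", seed = 9)
  r2 <- baseline_select(30, 7, "random", seed = 9)
  expect_identical(r1$indices, r2$indices)
  expect_true(all(diff(r1$indices) > 0))
})

test_that("the brute-force oracle refuses oversized problems", {
  e <- random_edge_matrix(40)
  expect_error(brute_force_select(e, 12), "bound exceeded")
})

test_that("spline mode: degree 1 reduces to the linear DP exactly", {
  cs <- skew_gaussian_curves(5, 15, seed = 8)
  fit <- suppressWarnings(fit_curve_density(cs))
  s <- sample_curves(fit, J = 40, seed = 2)
  lin <- dp_select(build_edge_matrix(s, objective_spec("f1", J = 40)), 6)
  sp1 <- spline_select(s, objective_spec("f1", J = 40,
                                         interpolation = "spline",
                                         spline_degree = 1), 6)
  expect_identical(sp1$indices, lin$indices)
})

test_that("spline mode beats the linear selection rescored with splines", {
  cs <- skew_gaussian_curves(5, 15, seed = 8)
  fit <- suppressWarnings(fit_curve_density(cs))
  s <- sample_curves(fit, J = 40, seed = 2)
  spec_sp <- objective_spec("f1", J = 40, interpolation = "spline",
                            spline_degree = 3)
  sel_sp <- spline_select(s, spec_sp, 6)
  lin <- dp_select(build_edge_matrix(s, objective_spec("f1", J = 40)), 6)
  expect_lte(sel_sp$objective_estimate,
             estimate_objective(lin, s, spec_sp) + 1e-12)
  expect_error(spline_select(s, spec_sp, 3), "M > spline degree")
})

test_that("cubic samples are reconstructed exactly by degree-3 selection", {
  u <- unit_grid(15)
  W <- rbind(u^3, 1 + u - 2 * u^3, 0.5 * u^2 + u^3)
  s <- as_samples(W, u)
  spec_sp <- objective_spec("f1", J = 3, interpolation = "spline",
                            spline_degree = 3)
  sel <- spline_select(s, spec_sp, 6)
  expect_lt(sel$objective_estimate, 1e-12)
})

test_that("forward and backward spline runs agree on symmetric samples", {
  u <- unit_grid(15)
  sym <- rbind(sin(pi * u), 0.5 * sin(pi * u) + 0.2, cos(2 * pi * u))
  s <- as_samples(sym, u)
  spec_sp <- objective_spec("f1", J = 3, interpolation = "spline",
                            spline_degree = 2)
  sel <- spline_select(s, spec_sp, 5)
  mirror <- sort(15L + 1L - sel$indices)
  f_sel <- estimate_objective(sel$indices, s, spec_sp)
  f_mir <- estimate_objective(mirror, s, spec_sp)
  expect_equal(f_sel, f_mir, tolerance = 1e-9)
})

test_that("pinning endpoints forces the first and last time points", {
  cs <- skew_gaussian_curves(5, 16, seed = 4)
  fit <- suppressWarnings(fit_curve_density(cs))
  sel <- pick_timepoints(fit, m = 4, J = 80, seed = 2,
                         pin_endpoints = TRUE)
  expect_identical(sel$indices[1], 1L)
  expect_identical(sel$indices[4], 16L)
})
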