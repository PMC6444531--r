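# Held-out evaluation of a selection: train/test splits, test-set L2
# error, and comparison of the optimal selector against even and random
# baselines, replicated over random splits.

#' Split a curve set into training and testing partitions
#'
#' @param curves a [curve_set()].
#' @param train_fraction fraction of curves in the training set (0 < f < 1).
#' @param seed integer seed.
#' @return list with `train`, `test` (both [curve_set()], weights and
#'   labels preserved) and `train_idx`.
#' @export
train_test_split <- function(curves, train_fraction = 0.5, seed = 1L) {
  stopifnot(inherits(curves, "curve_set"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be strictly between 0 and 1")
  n <- n_curves(curves)
  n_train <- round(train_fraction * n)
  if (n_train < 2L || n - n_train < 1L)
    stop("partition too small: ", n_train, " train / ", n - n_train,
         " test curves")
  idx <- with_seed(seed, sort(sample.int(n, n_train)))
  list(train = curves[idx], test = curves[-idx], train_idx = idx)
}

#' Test-set reconstruction errors of a selection
#'
#' For each held-out curve, the squared L2 distance between the full curve
#' (or its difference from a control) and its reconstruction from the
#' selected time points only.
#'
#' @param sel a `timepoint_selection` (or vector of indices).
#' @param test a [curve_set()] on the same grid.
#' @param method,degree interpolation used for the reconstruction; should
#'   match how the selection was made.
#' @param control optional control curve (full grid): errors are then
#'   computed on the difference g - curve, matching the f2 objective.
#' @return numeric vector of per-curve errors (>= 0).
#' @export
test_error <- function(sel, test, method = c("linear", "spline"),
                       degree = 3L, control = NULL) {
  method <- match.arg(method)
  indices <- if (inherits(sel, "timepoint_selection")) sel$indices else
    as.integer(sel)
  stopifnot(inherits(test, "curve_set"))
  if (inherits(sel, "timepoint_selection") &&
      !isTRUE(all.equal(sel$grid, test$times)))
    stop("selection and test set are on different grids")
  D <- if (is.null(control)) test$values else {
    if (length(control) != length(test$times))
      stop("control grid does not match the test grid")
    sweep(-test$values, 2L, as.numeric(control), `+`)
  }
  Z <- interpolate_subset(D, test$times, indices, method = method,
                          degree = degree) - D
  as.numeric(Z^2 %*% trapz_weights(test$times))
}

#' Compare the optimal selector with even and random baselines
#'
#' The evaluation design: per replicate, split the curves, fit the density
#' on the training partition, select M points with the dynamic programme,
#' draw even and random baseline selections, and score every strategy by
#' its mean reconstruction error on the held-out partition.
#'
#' @param curves a [curve_set()].
#' @param M points to select.
#' @param spec an [objective_spec()]; its J/seed/interpolation/criterion are
#'   used for the optimal selector.
#' @param replicates number of random splits (default 10).
#' @param seed master seed; replicate r uses seed + r for its split, its
#'   Monte-Carlo draw and its random baseline.
#' @param train_fraction passed to [train_test_split()].
#' @param variance_threshold passed to [fit_curve_density()].
#' @return object of class `evaluation_report`: `summary` (data frame with
#'   one row per replicate x strategy: replicate, strategy, mean_error,
#'   seed), `selections` (list of lists), `errors` (per-curve errors),
#'   `config`.
#' @export
compare_strategies <- function(curves, M, spec = objective_spec(),
                               replicates = 10L, seed = 1L,
                               train_fraction = 0.5,
                               variance_threshold = 0.95) {
  stopifnot(inherits(curves, "curve_set"), replicates >= 1L)
  N <- length(curves$times)
  interp <- spec$interpolation
  deg <- spec$spline_degree
  rows <- list()
  selections <- list()
  errors <- list()
  control_curve <- if (is.numeric(spec$control)) spec$control else NULL
  for (r in seq_len(replicates)) {
    rs <- seed + r
    sp <- train_test_split(curves, train_fraction, seed = rs)
    fit <- fit_curve_density(sp$train,
                             variance_threshold = variance_threshold)
    samples <- sample_curves(fit, J = spec$J, seed = rs)
    sel_dp <- if (interp == "spline" && deg > 1L) {
      spline_select(samples, spec, M)
    } else {
      dp_select(build_edge_matrix(samples, spec), M)
    }
    sel_even <- baseline_select(N, M, "even", times = curves$times)
    sel_rand <- baseline_select(N, M, "random", seed = rs,
                                times = curves$times)
    sels <- list(optimal = sel_dp, even = sel_even, random = sel_rand)
    errs <- lapply(sels, function(s)
      test_error(s, sp$test, method = interp, degree = deg,
                 control = control_curve))
    selections[[r]] <- sels
    errors[[r]] <- errs
    rows[[r]] <- data.frame(
      replicate = r,
      strategy = names(sels),
      mean_error = vapply(errs, mean, numeric(1L)),
      seed = rs, row.names = NULL)
  }
  structure(
    list(summary = do.call(rbind, rows), selections = selections,
         errors = errors,
         config = list(M = M, criterion = spec$criterion, J = spec$J,
                       replicates = replicates, seed = seed,
                       train_fraction = train_fraction,
                       interpolation = interp)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cfg <- x$config
  cat("Strategy comparison: M =", cfg$M, ", criterion", cfg$criterion,
      ",", cfg$replicates, "replicate(s)\n")
  agg <- stats::aggregate(mean_error ~ strategy, data = x$summary, FUN = mean)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-8s mean test error %.5g\n", agg$strategy[i],
                agg$mean_error[i]))
  wins <- with(x$summary, {
    m <- tapply(mean_error, list(replicate, strategy), identity)
    c(vs_random = mean(m[, "optimal"] <= m[, "random"]),
      vs_even = mean(m[, "optimal"] <= m[, "even"]))
  })
  cat(sprintf("  optimal beats random in %.0f%%, even in %.0f%% of replicates\n",
              100 * wins["vs_random"], 100 * wins["vs_even"]))
  invisible(x)
}
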