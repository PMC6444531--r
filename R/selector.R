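# Exact selection of M time points by a fixed-edge-count shortest path.
#
# Nodes 0 (start), 1..N (time points), N+1 (end).  The weight of edge
# (i, k) is the Monte-Carlo mean squared L2 reconstruction error over
# [tau_i, tau_k] when only tau_i and tau_k are sampled; start/end edges use
# constant extrapolation from their single real endpoint.  A path from
# start to end with exactly M+1 edges visits M time points, and under
# linear interpolation its length equals the full objective of that
# selection, so the M-point minimiser of the objective is the shortest
# such path.  The recursion is
#   theta_min(j, k) = min_{i < j} [ theta_min(i, k-1) + edge(i, j) ]
# with theta_min(start, 0) = 0, i.e. a modified Viterbi pass, plus a
# traceback.  Ties are broken toward the lexicographically smallest index
# sequence (identically in the DP and the brute-force oracle).

#' Build the edge-weight matrix for the selection graph
#'
#' @param samples a `sampled_curves` from [sample_curves()] (or a
#'   [curve_set()] to select against observed curves directly).
#' @param spec an [objective_spec()]; edges always use linear (chord)
#'   reconstruction between their two endpoints, which is exact for the
#'   linear-interpolation objective (spline-aware costs are handled by
#'   [spline_select()]).
#' @param weights optional per-curve weights (f1 only).
#' @return an `edge_matrix`: list with `weights` ((N+2) x (N+2), +Inf on
#'   backward/self edges; rows/cols 1..N+2 are nodes 0..N+1), `times`,
#'   `criterion`.
#' @export
build_edge_matrix <- function(samples, spec, weights = NULL) {
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
  N <- length(times)
  if (spec$criterion == "f3" && spec$cv_target) {
    v <- apply(D, 2L, stats::var)
    v <- pmax(v, spec$variance_floor * max(v))
    D <- sweep(D, 2L, sqrt(v), `/`)
  }
  f3_local <- spec$criterion == "f3" && !spec$cv_target

  # mean (weighted) squared L2 error of Z over the interval idx
  seg_score <- function(Z, idx) {
    w <- trapz_weights(times[idx])
    if (f3_local) {
      v <- apply(Z, 2L, stats::var)
      if (max(v) > 0) {
        v <- pmax(v, spec$variance_floor * max(v))
        Z <- sweep(Z, 2L, sqrt(v), `/`)
      }
    }
    per <- as.numeric(Z^2 %*% w)
    if (is.null(weights)) mean(per) else sum(weights * per) / J
  }

  E <- matrix(Inf, N + 2L, N + 2L)
  # interior edges: chord between tau_i and tau_k
  for (i in seq_len(N - 1L)) {
    for (k in (i + 1L):N) {
      idx <- i:k
      frac <- (times[idx] - times[i]) / (times[k] - times[i])
      chord <- outer(D[, i], 1 - frac) + outer(D[, k], frac)
      E[i + 1L, k + 1L] <- seg_score(chord - D[, idx, drop = FALSE], idx)
    }
  }
  # start edges: only tau_k sampled on [tau_1, tau_k]
  for (k in seq_len(N)) {
    idx <- 1L:k
    E[1L, k + 1L] <- if (k == 1L) 0 else
      seg_score(matrix(D[, k], J, k) - D[, idx, drop = FALSE], idx)
  }
  # end edges: only tau_i sampled on [tau_i, tau_N]
  for (i in seq_len(N)) {
    idx <- i:N
    E[i + 1L, N + 2L] <- if (i == N) 0 else
      seg_score(matrix(D[, i], J, N - i + 1L) - D[, idx, drop = FALSE], idx)
  }
  structure(list(weights = E, times = times, criterion = spec$criterion),
            class = "edge_matrix")
}

#' @export
print.edge_matrix <- function(x, ...) {
  cat("Edge matrix over", length(x$times), "time points (criterion",
      x$criterion, ")\n")
  invisible(x)
}

# forward table: theta[j, k] = min cost start -> node j with exactly k edges
dp_forward <- function(E) {
  n <- nrow(E) # N + 2 nodes
  K <- n - 1L
  theta <- matrix(Inf, n, K + 1L)
  trace <- matrix(NA_integer_, n, K + 1L)
  theta[1L, 1L] <- 0 # node 0, zero edges
  for (k in seq_len(K)) {
    for (j in 2L:n) {
      prev <- theta[1L:(j - 1L), k] + E[1L:(j - 1L), j]
      b <- which.min(prev) # which.min returns the first (smallest) index
      if (is.finite(prev[b])) {
        theta[j, k + 1L] <- prev[b]
        trace[j, k + 1L] <- b
      }
    }
  }
  list(theta_min = theta, theta_trace = trace)
}

# backward table: psi[j, k] = min cost node j -> end with exactly k edges
dp_backward <- function(E) {
  n <- nrow(E)
  K <- n - 1L
  psi <- matrix(Inf, n, K + 1L)
  psi[n, 1L] <- 0
  for (k in seq_len(K)) {
    for (j in (n - 1L):1L) {
      nxt <- E[j, (j + 1L):n] + psi[(j + 1L):n, k]
      b <- which.min(nxt)
      if (is.finite(nxt[b])) psi[j, k + 1L] <- nxt[b]
    }
  }
  psi
}

#' Optimal M-point selection by dynamic programming
#'
#' Globally minimal-cost path from the start node to the end node using
#' exactly M+1 edges; the intermediate nodes are the selected time points.
#'
#' @param edges an `edge_matrix` from [build_edge_matrix()].
#' @param M number of time points to select (1 <= M <= N).
#' @param criterion stored on the returned selection.
#' @return a [selection()] with `objective_estimate` set to the path cost;
#'   also carries the DP tables as attribute `dp_tables` (`theta_min`,
#'   `theta_trace`).
#' @export
dp_select <- function(edges, M, criterion = edges$criterion) {
  stopifnot(inherits(edges, "edge_matrix"))
  N <- length(edges$times)
  M <- as.integer(M)
  if (M < 1L || M > N) stop("M must be between 1 and ", N)
  E <- edges$weights
  K <- M + 1L # edges in the path
  fwd <- dp_forward(E)
  cost <- fwd$theta_min[N + 2L, K + 1L]
  if (!is.finite(cost)) stop("no feasible path (all relevant edges infinite)")
  # lexicographically smallest optimal sequence: walk from the front,
  # using the backward table to certify optimality of each extension
  psi <- dp_backward(E)
  path <- integer(0)
  cur <- 1L # start node
  for (k in K:1L) {
    cand <- (cur + 1L):(N + 2L)
    # k - 1 edges remain after stepping to the candidate
    tot <- E[cur, cand] + psi[cand, (k - 1L) + 1L]
    j <- cand[which(tot == psi[cur, k + 1L])[1L]]
    if (is.na(j)) j <- cand[which.min(tot)] # numerical guard
    path <- c(path, j)
    cur <- j
  }
  nodes <- path[-length(path)] # drop the end node
  sel <- selection(nodes - 1L, edges$times, criterion = criterion,
                   objective_estimate = cost, strategy = "dp")
  attr(sel, "dp_tables") <- fwd
  sel
}

#' Exhaustive-search oracle for the selection problem
#'
#' Enumerates all C(N, M) subsets and returns the minimum-cost path under
#' the same tie-break rule as [dp_select()] (lexicographically smallest
#' index sequence).  Only intended as a correctness oracle on small
#' instances.
#'
#' @inheritParams dp_select
#' @return a [selection()].
#' @export
brute_force_select <- function(edges, M, criterion = edges$criterion) {
  stopifnot(inherits(edges, "edge_matrix"))
  N <- length(edges$times)
  M <- as.integer(M)
  if (M < 1L || M > N) stop("M must be between 1 and ", N)
  if (choose(N, M) > 1e6) stop("combinatorial bound exceeded (C(N, M) > 1e6)")
  E <- edges$weights
  subsets <- utils::combn(N, M)
  best_cost <- Inf
  best <- NULL
  for (s in seq_len(ncol(subsets))) {
    nodes <- c(0L, subsets[, s], N + 1L) + 1L
    cost <- 0
    for (e in seq_len(length(nodes) - 1L)) {
      cost <- cost + E[nodes[e], nodes[e + 1L]]
      if (!is.finite(cost)) break
    }
    if (is.finite(cost) && cost < best_cost) { # strict: ties keep the
      best_cost <- cost                        # earlier (lex smaller) subset
      best <- subsets[, s]
    }
  }
  if (is.null(best)) stop("no feasible selection")
  selection(best, edges$times, criterion = criterion,
            objective_estimate = best_cost, strategy = "brute_force")
}

#' Baseline selections: evenly spaced or random
#'
#' @param N grid size.
#' @param M points to select.
#' @param strategy `"even"` (rounded linspace over 1..N, duplicates
#'   resolved by shifting right) or `"random"` (uniform without
#'   replacement).
#' @param seed seed for the random strategy.
#' @param times optional grid (defaults to 1..N) stored on the selection.
#' @return a [selection()].
#' @export
baseline_select <- function(N, M, strategy = c("even", "random"), seed = 1L,
                            times = seq_len(N)) {
  strategy <- match.arg(strategy)
  N <- as.integer(N); M <- as.integer(M)
  if (M < 1L || M > N) stop("M must be between 1 and ", N)
  idx <- if (strategy == "even") {
    ix <- as.integer(round(seq(1, N, length.out = M)))
    # deduplicate by shifting right
    for (i in seq_along(ix)[-1L])
      if (ix[i] <= ix[i - 1L]) ix[i] <- ix[i - 1L] + 1L
    if (ix[M] > N) stop("cannot place ", M, " distinct points on ", N)
    ix
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    sort(sample.int(N, M))
  }
  selection(idx, times, criterion = "f1", seed = seed, strategy = strategy)
}

#' Spline-aware selection (degree R > 1)
#'
#' With spline interpolation an edge cost depends on the R-1 previously
#' selected points, which breaks the exact edge decomposition.  Following
#' the standard approximation, the history of a node is recovered from the
#' running traceback while the DP fills in; the algorithm is run once on
#' the forward grid and once on the reversed grid (to soften the spline's
#' edge effects at the start of the sequence), and whichever selection has
#' the lower exact spline-interpolation objective is returned.
#'
#' @param samples a `sampled_curves` (or `curve_set`).
#' @param spec an [objective_spec()] with `interpolation = "spline"` and
#'   `spline_degree` R; R = 1 reduces exactly to [dp_select()] on the
#'   linear edge matrix.
#' @param M points to select; must exceed the spline degree.
#' @param weights optional per-curve weights (f1 only).
#' @return a [selection()] with `objective_estimate` re-evaluated exactly
#'   with full spline interpolation over the whole selection.
#' @export
spline_select <- function(samples, spec, M, weights = NULL) {
  R <- spec$spline_degree
  M <- as.integer(M)
  if (R == 1L) {
    edges <- build_edge_matrix(samples, spec, weights = weights)
    return(dp_select(edges, M))
  }
  if (M <= R) stop("spline mode needs M > spline degree (M = ", M,
                   ", R = ", R, ")")
  fwd <- spline_dp_once(samples, spec, M, weights)
  bwd <- spline_dp_once(reverse_samples(samples), spec, M, weights)
  times <- samples$times
  N <- length(times)
  idx_bwd <- sort(N + 1L - bwd)
  f_fwd <- estimate_objective(fwd, samples, spec, weights = weights)
  f_bwd <- estimate_objective(idx_bwd, samples, spec, weights = weights)
  idx <- if (f_bwd < f_fwd) idx_bwd else fwd
  selection(idx, times, criterion = spec$criterion,
            objective_estimate = min(f_fwd, f_bwd),
            n_samples = nrow(samples$values),
            seed = spec$seed, strategy = "dp_spline")
}

reverse_samples <- function(samples) {
  if (inherits(samples, "sampled_curves")) {
    out <- samples
    out$times <- rev(-samples$times) + 0 # reversed axis, increasing again
    out$values <- samples$values[, rev(seq_len(ncol(samples$values))),
                                 drop = FALSE]
    out
  } else {
    curve_set(samples$values[, rev(seq_along(samples$times)), drop = FALSE],
              rev(-samples$times), weights = samples$weights,
              labels = samples$labels)
  }
}

# one forward spline DP pass; returns selected indices (forward orientation)
spline_dp_once <- function(samples, spec, M, weights) {
  times <- samples$times
  N <- length(times)
  D <- objective_base(samples, spec)
  J <- nrow(D)
  if (spec$criterion == "f3" && spec$cv_target) {
    v <- apply(D, 2L, stats::var)
    v <- pmax(v, spec$variance_floor * max(v))
    D <- sweep(D, 2L, sqrt(v), `/`)
  }
  f3_local <- spec$criterion == "f3" && !spec$cv_target
  R <- spec$spline_degree

  seg_score <- function(Z, idx) {
    w <- trapz_weights(times[idx])
    if (f3_local) {
      v <- apply(Z, 2L, stats::var)
      if (max(v) > 0) {
        v <- pmax(v, spec$variance_floor * max(v))
        Z <- sweep(Z, 2L, sqrt(v), `/`)
      }
    }
    per <- as.numeric(Z^2 %*% w)
    if (is.null(weights)) mean(per) else sum(weights * per) / J
  }

  # edge cost over [tau_a, tau_b] reconstructing from the points `pts`
  hist_cost <- function(a, b, pts) {
    idx <- a:b
    if (length(pts) == 0L) return(Inf)
    # history shorter than the degree needs silently degrades the spline
    recon <- suppressWarnings(
      interpolate_subset(D, times, sort(unique(pts)),
                         method = "spline", degree = R))
    seg_score(recon[, idx, drop = FALSE] - D[, idx, drop = FALSE], idx)
  }

  K <- M + 1L
  nn <- N + 2L
  theta <- matrix(Inf, nn, K + 1L)
  trace <- matrix(NA_integer_, nn, K + 1L)
  theta[1L, 1L] <- 0
  history <- function(node, k) {
    # last up-to-R real nodes on the traced path ending at `node` with k edges
    h <- integer(0)
    cur <- node; kk <- k
    while (!is.na(cur) && cur > 1L && length(h) < R) {
      h <- c(cur - 1L, h)
      cur <- trace[cur, kk + 1L]
      kk <- kk - 1L
    }
    h
  }
  for (k in seq_len(K)) {
    for (j in 2L:nn) {
      best <- Inf; barg <- NA_integer_
      for (i in seq_len(j - 1L)) {
        if (!is.finite(theta[i, k])) next
        hist <- history(i, k - 1L)
        a <- if (i == 1L) 1L else i - 1L
        b <- if (j == nn) N else j - 1L
        if (a >= b && !(i == 1L && j == nn)) {
          c_edge <- 0
        } else if (i == 1L && j == nn) {
          next # start -> end directly never needed (M >= 1)
        } else {
          pts <- unique(c(hist, if (j < nn) j - 1L))
          c_edge <- if (length(pts) == 0L) Inf else {
            recon_pts <- pts[pts >= 1L & pts <= N]
            hist_cost(a, b, recon_pts)
          }
        }
        tot <- theta[i, k] + c_edge
        if (tot < best) { best <- tot; barg <- i }
      }
      theta[j, k + 1L] <- best
      trace[j, k + 1L] <- barg
    }
  }
  if (!is.finite(theta[nn, K + 1L])) stop("spline DP found no feasible path")
  # traceback
  nodes <- integer(0)
  cur <- nn; kk <- K
  while (cur > 1L) {
    prev <- trace[cur, kk + 1L]
    nodes <- c(prev, nodes)
    cur <- prev; kk <- kk - 1L
  }
  path <- c(nodes[-1L], nn) # drop start, add end
  sort(setdiff(c(nodes, path), c(1L, nn))) - 1L
}

#' Select time points from fitted curves
#'
#' The main user-facing selector: fits (or accepts) a curve density, draws
#' J Monte-Carlo perturbation curves, builds the edge matrix for the chosen
#' criterion, and solves the fixed-edge-count shortest path exactly.
#'
#' @param object a [fit_curve_density()] result, or a [curve_set()] (which
#'   is fitted first with default settings).
#' @param m number of time points to select.
#' @param criterion `"f1"`, `"f2"` or `"f3"`.
#' @param control control curve (full grid, original units) or control
#'   `curve_density`; required for f2/f3.
#' @param J Monte-Carlo sample count (default 1000).
#' @param seed integer seed for the sampling.
#' @param interpolation `"linear"` or `"spline"`.
#' @param spline_degree degree R for spline mode.
#' @param pin_endpoints force the first and last time points into every
#'   path (some designs always sample the ends); default FALSE.
#' @param variance_floor,cv_target f3 controls, see [objective_spec()].
#' @return a [selection()] (class `timepoint_selection`).
#' @export
#' @examples
#' cs <- skew_gaussian_curves(n_curves = 4, n_times = 20, seed = 2)
#' fit <- fit_curve_density(cs)
#' pick_timepoints(fit, m = 4, J = 100, seed = 1)
pick_timepoints <- function(object, m, criterion = c("f1", "f2", "f3"),
                            control = NULL, J = 1000L, seed = 1L,
                            interpolation = c("linear", "spline"),
                            spline_degree = 3L, pin_endpoints = FALSE,
                            variance_floor = 1e-6, cv_target = FALSE) {
  criterion <- match.arg(criterion)
  interpolation <- match.arg(interpolation)
  dist <- if (inherits(object, "curve_density")) object
          else fit_curve_density(object)
  samples <- sample_curves(dist, J = J, seed = seed)
  spec <- objective_spec(criterion = criterion, control = control, J = J,
                         seed = seed, interpolation = interpolation,
                         spline_degree = spline_degree,
                         variance_floor = variance_floor,
                         cv_target = cv_target)
  if (interpolation == "spline" && spline_degree > 1L) {
    sel <- spline_select(samples, spec, m)
  } else {
    edges <- build_edge_matrix(samples, spec)
    if (pin_endpoints) {
      N <- length(samples$times)
      edges$weights[1L, 2L + seq_len(N - 1L)] <- Inf # start only to node 1
      edges$weights[1L + seq_len(N - 1L), N + 2L] <- Inf # end only from N
    }
    sel <- dp_select(edges, m)
  }
  sel$n_samples <- as.integer(J)
  sel$seed <- as.integer(seed)
  sel
}
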