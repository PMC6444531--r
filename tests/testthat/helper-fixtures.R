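# Shared fixtures, all built in code at test time.

unit_grid <- function(n) seq(0, 1, length.out = n)

gauss_bump <- function(t, center = 0.5, width = 0.1)
  exp(-(t - center)^2 / (2 * width^2))

# exponential-family warp values on [0,1]; identity at a = 0
exp_warp <- function(t, a) if (abs(a) < 1e-8) t else
  (exp(a * t) - 1) / (exp(a) - 1)

# wrap a plain matrix of curves as a sampled_curves object
as_samples <- function(values, times, seed = 1L) {
  structure(list(times = as.numeric(times), values = as.matrix(values),
                 seed = as.integer(seed), n_repaired = 0L),
            class = "sampled_curves")
}

# random non-negative edge matrix over N time points (forward edges only)
random_edge_matrix <- function(N, scale = 1) {
  E <- matrix(Inf, N + 2L, N + 2L)
  for (i in 1:(N + 1L))
    for (k in (i + 1L):(N + 2L)) E[i, k] <- scale * runif(1)
  E[1L, N + 2L] <- Inf # start -> end direct is never part of an M >= 1 path
  structure(list(weights = E, times = seq_len(N), criterion = "f1"),
            class = "edge_matrix")
}

# path cost read directly off an edge matrix
path_cost <- function(edges, indices) {
  N <- length(edges$times)
  nodes <- c(0L, indices, N + 1L) + 1L
  sum(edges$weights[cbind(nodes[-length(nodes)], nodes[-1L])])
}

# trapezoidal L2 norm on a grid, written independently of the package
grid_norm_for_test <- function(times, f) {
  d <- diff(times)
  wts <- c(d[1] / 2, (d[-length(d)] + d[-1]) / 2, d[length(d)] / 2)
  sqrt(sum(wts * f^2))
}
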