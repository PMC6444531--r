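---
title: "Selecting time points for follow-up experiments: model and methods"
author: "curvepick"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting time points for follow-up experiments: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvepick)
```

## The design question

Given a small number of high-resolution time courses sampled at times
$\tau_1 < \dots < \tau_N$, which $M$ of those times should a follow-up
experiment keep? curvepick answers this by treating the observed curves
as draws from an unknown distribution over functions, and choosing the
subset $\mathbf{t} \subset \tau$ that minimises the *expected* squared
$L^2$ error of reconstructing a curve from its values at $\mathbf{t}$
alone. Three criteria are supported:

* **f1** — reconstruct the curve itself. Use this when the follow-up
  simply repeats the pilot at lower resolution.
* **f2** — reconstruct the difference $g - w$ between a control curve $g$
  and the experimental curves $w$. Use this when the question is how a
  perturbation changes the curve. f1 is exactly f2 with $g \equiv 0$,
  and the implementation computes it through the same code path.
* **f3** — reconstruct the difference normalised by its pointwise
  standard deviation across the population (the inverse coefficient of
  variation). Use this when parts of the time course are known to be
  noisy and accuracy there is worth sacrificing.

The expectation is estimated by Monte Carlo: `J` curves are drawn from a
fitted density over curves (J = 1000 by default; halving or doubling J
moves the selection little because only the *ranking* of subsets
matters). All integrals use the trapezoid rule on the observed grid; the
grid need not be uniform, and the `1/J` factor is kept so that objective
values are comparable across runs.

## The density over curves

Curves vary in two qualitatively different ways: *when* things happen
(phase, x-deformation) and *how much* happens (amplitude,
y-deformation). A PCA of the raw values confounds the two — a small
timing shift of a sharp burst looks like a large amplitude change — so
the two are separated first:

1. **Elastic registration.** Each curve is mapped to its square-root
   slope function $q = \mathrm{sign}(\dot f)\sqrt{|\dot f|}$, under which
   the distance
   $D_y(h_1, h_2) = \inf_\gamma \| q_1 - (q_2 \circ \gamma)\sqrt{\dot\gamma} \|_{L^2}$
   is invariant to simultaneous warping and can be minimised exactly over
   discrete warping paths by dynamic programming. Curves are aligned to
   an iteratively refined template: start from the cross-sectional mean
   SRSF, align every curve, replace the template with the mean of the
   aligned SRSFs, and repeat (tolerance $10^{-4}$, at most 20 passes;
   non-convergence is flagged and the last iterate used). The template
   procedure is a replaceable strategy, not a modelling commitment.
2. **Phase model.** Warping functions are monotone maps of $[0,1]$ with
   fixed endpoints; their SRSFs $\psi = \sqrt{\dot\gamma}$ have unit
   $L^2$ norm, so warps live on the unit sphere in $L^2$. The sphere is
   linearised at the Karcher mean of the *inverse* alignment warps — the
   deformations that carry the template onto each curve — using the log
   map, and a functional PCA is fitted to the tangent vectors. Fitting
   the inverses keeps the generative convention simple: a sampled curve
   is the amplitude curve evaluated at a sampled warp.
3. **Amplitude model.** The aligned curves already live in a linear
   space, so a functional PCA is fitted to them directly.
4. **Scores.** Independent zero-mean Gaussians with variance equal to
   each eigenvalue, i.e. a diagonal multivariate normal in the joint
   fPCA coordinates.

Sampling reverses the construction: draw scores, reconstruct a tangent
vector and exponentiate it to a warp, reconstruct an amplitude curve,
and compose the two. Discarding trailing fPCA components smooths the
sampled curves, which is intended — it is what makes the density robust
to noise in individual pilot curves. Each model retains the smallest
number of components explaining `variance_threshold` (default 0.95) of
its variance; the threshold applies independently to the phase and
amplitude models.

Two caveats are inherent to the construction. The linearisation step is
accurate for moderate deformations but exaggerates distances between
outlying pairs of warps; no correction is applied. And with very few
curves (the method runs from three upwards) the density is a smoothed
interpolation of the examples — **always plot sampled curves against the
training data** (`plot(fit)`) before trusting a selection.

## Exact selection

For an interval $[\tau_i, \tau_k]$ sampled only at its endpoints, define
$\mathrm{edge}(i,k)$ as the Monte-Carlo mean squared $L^2$ error of the
(criterion-specific) reconstruction over that interval. Adding a virtual
start and end node, the objective of any $M$-point subset is the length
of the path start $\to t_1 \to \dots \to t_M \to$ end, so the optimal
subset is the shortest path with exactly $M+1$ edges:
$\Theta_{\min}(j,k) = \min_{i<j}\left[\Theta_{\min}(i,k-1) + \mathrm{edge}(i,j)\right]$,
computed in $O(N^2 M)$ with a traceback. This is globally optimal — a
greedy search can stall in local optima — and `brute_force_select()`
provides an exhaustive oracle against which the programme is tested
exactly, including a shared lexicographic tie-break.

Design choices worth knowing:

* **Boundary handling.** Outside $[t_1, t_M]$ the reconstruction is
  constant from the nearest selected point. The virtual start/end edges
  use the same convention, so the first and last grid points are *not*
  forced into the selection; `pin_endpoints = TRUE` restores the
  always-sample-the-ends behaviour some designs require.
* **Edge costs store the mean over the J samples**, a monotone transform
  of the sum that leaves the argmin unchanged.
* **Spline mode.** With degree-$R$ interpolation an edge cost depends on
  the $R-1$ previously selected points, which breaks the exact
  decomposition. The implementation follows the standard approximation —
  the history is read off the running traceback — and runs the programme
  forward and backward (splines have edge effects at the start of a
  sequence), returning whichever selection scores better when re-scored
  exactly with full spline interpolation. Degree 1 reduces exactly to
  the linear programme. B-spline interpolation uses clamped knots with
  the averaging rule, so the interpolation problem is always well posed;
  a degree too high for the number of points falls back with a warning.

## The f3 normalisation, precisely

The variance in f3 can be read two ways: the variance of the
subset-dependent reconstruction error $z$, or the variance of the
underlying difference $d = g - w$. Both are implemented.

* The default (`cv_target = FALSE`) normalises $z$ by its pointwise
  Monte-Carlo variance, floored at `variance_floor` (default $10^{-6}$)
  times the maximum variance to avoid division blow-ups where the
  reconstruction is exact. Edge costs floor within their own interval so
  that a path cost is exactly the sum of its edges.
* `cv_target = TRUE` divides the full-resolution difference by its
  pointwise standard deviation *first* and then applies the f2
  machinery — i.e. it fits the inverse coefficient of variation itself.

The distinction matters. Under the default reading, the variance of $z$
over an unsampled stretch inherits the sampling noise of its endpoint
values, so in a scenario with a noisy early window the normalisation
largely cancels and the selection is *not* steered away from the noise.
Fitting the inverse CV (`cv_target = TRUE`) is the reading that
implements "sample less where the population is noisy", and it is the
configuration the package's noise-avoidance tests exercise: in the
bundled noisy-window scenario the f3 selection places fewer points in
the high-variance window than f1 in every replicate.

## Numerical conventions

* Derivatives: central differences in the interior, one-sided at the
  boundaries. The SRSF round trip is second-order accurate in the grid
  spacing.
* The $\psi$ (sphere) representation is primary for warp geometry: the
  log/exp maps are exact on $\psi$, while warp values are recovered by
  integrating $\psi^2$ and renormalising, accurate to quadrature error.
* Monotonicity repair: a sampled warp whose $\psi$ dips below zero is
  clipped and renormalised; occurrences are counted on the returned
  object (`n_repaired`). Frequent repairs mean the phase variance is too
  large for the linearisation — inspect the density.
* Warping paths in `align_pair()` move between grid nodes with coprime
  steps up to `max_step` (default 6) on either axis, so representable
  local slopes span $[1/6, 6]$; linear interpolation is used between
  nodes. The attained cost is returned as $D_y$, so $D_y$ never exceeds
  the unwarped distance.
* Ties in the selection programme break toward the lexicographically
  smallest index sequence, identically in the DP and the oracle.
* Missing values are rejected, not imputed; ragged per-curve grids are
  out of scope. All user-facing indices are 1-based.

## What the synthetic generators emulate

* `skew_gaussian_curves()` — expression-burst-like curves
  $A\,2\varphi((t-m)/s)\,\Phi(\alpha(t-m)/s)$ with location, scale, skew
  and amplitude drawn uniformly from configurable ranges (defaults
  $m \in [0.3, 0.7]$, $s \in [0.05, 0.2]$, $\alpha \in [-5, 5]$,
  $A \in [0.5, 1.5]$ on the unit grid). A triplet of such curves is the
  minimal realistic input for the density.
* `warped_template_curves()` — a fixed bump composed with random
  exponential-family warps, returning the ground-truth warps. The drawn
  warp parameters are centred so the population mean deformation is
  close to the identity; individual warps are otherwise identifiable
  only up to a common warp.
* `noisy_window_curves()` — a smooth control, a systematic offset in an
  informative window, and high-variance smooth bumps in a disjoint noisy
  window: the scenario in which f3 and f1 should disagree.

All generators are pure functions of their configuration and seed. What
they do *not* emulate: measurement noise at single time points (curves
are smooth by construction), count-data heteroscedasticity, missing
samples, or replicate structure — passing tests on these populations
shows the machinery is correct, not that any particular biological
dataset satisfies the model.

The evaluation harness (`compare_strategies()`) mirrors the standard
held-out design: split the curves, fit the density and select on the
training half, and score all strategies by reconstruction error on the
unseen half. The bundled studies use 40 curves on a 24-point grid,
$M = 8$, $J = 1000$ and 10 replicate splits for the selection-quality
comparison, and 20 replicates of the 12-curve noisy-window scenario —
sizes at which the comparisons are stable from run to run.

## Known limitations

* The programme returns a single optimal subset with no confidence
  measure on the selection.
* Piecewise-linear reconstruction error is *not* universally monotone
  under refinement: adding a time point outside the selected range
  changes the extrapolation, and even an interior point can raise the
  error when a curve has a feature narrower than the local spacing. In
  practice refinements of an optimal selection improve the objective in
  the large majority of cases, and the package asserts the exact
  monotone property only where it is a theorem (convex curves; the
  optimal cost as a function of $M$).
* Spline-mode selection is approximate (traceback history); the final
  selection is always re-scored exactly.
* Per-curve importance weights apply to f1 only, where they rescale each
  curve's contribution; extending them to f2/f3 would mix two different
  expectations and is rejected with a message.
* Sobolev-norm objectives (matching derivatives as well as values) are a
  natural extension and are not implemented.
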