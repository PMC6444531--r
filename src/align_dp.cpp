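#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Dynamic programme for pairwise elastic alignment in SRSF space.
//
// Finds the monotone grid-to-grid warping path gamma minimising
//   || q1(t) - q2(gamma(t)) sqrt(gamma'(t)) ||_{L2}
// over paths from (1,1) to (n,n) whose steps come from a fixed set of
// coprime slope pairs (a, b): a grid points forward on the q1 axis, b on
// the q2 axis.  gamma is linear within a step; q2 is linearly interpolated
// between grid points; the integral is the trapezoid rule on the q1 grid
// restricted to the step.  The identity path is always admissible, so the
// attained cost never exceeds the plain (trapezoidal) L2 distance.

static double seg_cost(const NumericVector& t, const NumericVector& q1,
                       const NumericVector& q2, int i0, int j0, int i1,
                       int j1) {
  // segment from node (i0, j0) to (i1, j1), 0-based grid indices
  double ti0 = t[i0], ti1 = t[i1];
  double tj0 = t[j0], tj1 = t[j1];
  double slope = (tj1 - tj0) / (ti1 - ti0);
  double sq = std::sqrt(slope);
  int m = i1 - i0; // number of sub-intervals on the q1 axis
  double cost = 0.0;
  double prev_val = 0.0;
  for (int k = 0; k <= m; ++k) {
    double tk = t[i0 + k];
    double g = tj0 + slope * (tk - ti0);
    // linear interpolation of q2 at g within [tj0, tj1]
    double q2g;
    if (g <= t[0]) {
      q2g = q2[0];
    } else if (g >= t[t.size() - 1]) {
      q2g = q2[t.size() - 1];
    } else {
      // locate within [j0, j1] (g is monotone in k)
      int lo = j0;
      int hi = j1;
      while (hi - lo > 1) {
        int mid = (lo + hi) / 2;
        if (t[mid] <= g) lo = mid; else hi = mid;
      }
      double w = (g - t[lo]) / (t[lo + 1] - t[lo]);
      q2g = (1.0 - w) * q2[lo] + w * q2[lo + 1];
    }
    double diff = q1[i0 + k] - q2g * sq;
    double val = diff * diff;
    if (k > 0) cost += 0.5 * (t[i0 + k] - t[i0 + k - 1]) * (val + prev_val);
    prev_val = val;
  }
  return cost;
}

// [[Rcpp::export(name = ".dp_align_cpp")]]
List dp_align_cpp(NumericVector t, NumericVector q1, NumericVector q2,
                  int max_step = 6) {
  int n = t.size();
  if (q1.size() != n || q2.size() != n)
    stop("q1, q2 and t must have equal length");

  // coprime step pairs up to max_step on each axis
  std::vector<int> sa, sb;
  for (int a = 1; a <= max_step; ++a)
    for (int b = 1; b <= max_step; ++b) {
      int x = a, y = b;
      while (y) { int r = x % y; x = y; y = r; }
      if (x == 1) { sa.push_back(a); sb.push_back(b); }
    }
  int ns = sa.size();

  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix D(n, n);
  IntegerMatrix Pi(n, n), Pj(n, n);
  std::fill(D.begin(), D.end(), INF);
  std::fill(Pi.begin(), Pi.end(), -1);
  std::fill(Pj.begin(), Pj.end(), -1);
  D(0, 0) = 0.0;

  for (int i = 1; i < n; ++i) {
    for (int j = 1; j < n; ++j) {
      double best = INF;
      int bi = -1, bj = -1;
      for (int s = 0; s < ns; ++s) {
        int pi = i - sa[s];
        int pj = j - sb[s];
        if (pi < 0 || pj < 0) continue;
        if (D(pi, pj) == INF) continue;
        double c = D(pi, pj) + seg_cost(t, q1, q2, pi, pj, i, j);
        if (c < best) { best = c; bi = pi; bj = pj; }
      }
      D(i, j) = best;
      Pi(i, j) = bi;
      Pj(i, j) = bj;
    }
  }

  if (D(n - 1, n - 1) == INF)
    stop("no admissible warping path; increase max_step");

  // traceback: nodes of the optimal path
  std::vector<int> pi_nodes, pj_nodes;
  int ci = n - 1, cj = n - 1;
  while (ci >= 0 && cj >= 0) {
    pi_nodes.push_back(ci);
    pj_nodes.push_back(cj);
    if (ci == 0 && cj == 0) break;
    int ni = Pi(ci, cj), nj = Pj(ci, cj);
    ci = ni; cj = nj;
  }
  std::reverse(pi_nodes.begin(), pi_nodes.end());
  std::reverse(pj_nodes.begin(), pj_nodes.end());

  // piecewise-linear gamma evaluated on the full grid
  NumericVector gamma(n);
  size_t seg = 0;
  for (int k = 0; k < n; ++k) {
    double tk = t[k];
    while (seg + 1 < pi_nodes.size() - 1 && t[pi_nodes[seg + 1]] <= tk) ++seg;
    double x0 = t[pi_nodes[seg]], x1 = t[pi_nodes[seg + 1]];
    double y0 = t[pj_nodes[seg]], y1 = t[pj_nodes[seg + 1]];
    double w = (tk - x0) / (x1 - x0);
    if (w < 0) w = 0;
    if (w > 1) w = 1;
    gamma[k] = y0 + w * (y1 - y0);
  }
  gamma[0] = t[0];
  gamma[n - 1] = t[n - 1];

  return List::create(_["gamma"] = gamma,
                      _["cost"] = D(n - 1, n - 1));
}
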