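#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pairwise ML distances on a precomputed log-likelihood grid.
//
// codes:  S x n integer matrix, residue codes 0..19, negative = missing.
// w:      length-S column weights (bootstrap multiplicities; may be 0).
// Lgrid:  G x 400 matrix, Lgrid(g, 20*a + b) = log(pi_a * m_ab(t_g)) where
//         m(t) is the rate-mixture transition matrix at branch length t_g.
// logt:   log of the G grid branch lengths, uniformly spaced.
// max_distance: value reported (with a saturation flag) when the optimum
//         sits at the upper end of the grid.
//
// Per pair: accumulate the weighted 20x20 joint count table over shared
// ungapped sites, evaluate the log-likelihood at every grid point, take the
// argmax and refine by quadratic interpolation in log branch length.
// [[Rcpp::export]]
List pairwise_grid_distances(IntegerMatrix codes, NumericVector w,
                             NumericMatrix Lgrid, NumericVector logt,
                             double max_distance) {
  const int S = codes.nrow(), n = codes.ncol(), G = Lgrid.nrow();
  if (w.size() != S) stop("weights length must equal number of columns");
  if (Lgrid.ncol() != 400) stop("Lgrid must have 400 columns");
  NumericMatrix D(n, n);
  LogicalMatrix sat(n, n);
  std::vector<double> cnt(400, 0.0);
  std::vector<int> used;
  used.reserve(400);
  std::vector<double> ll(G);
  const double dlog = (G > 1) ? (logt[G - 1] - logt[0]) / (G - 1) : 0.0;
  const double* L = Lgrid.begin();  // column-major: L[g + G*cell]

  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      used.clear();
      double tot = 0.0, diff = 0.0;
      for (int s = 0; s < S; ++s) {
        const double ws = w[s];
        if (ws == 0.0) continue;
        const int a = codes(s, i), b = codes(s, j);
        if (a < 0 || b < 0) continue;
        const int cell = 20 * a + b;
        if (cnt[cell] == 0.0) used.push_back(cell);
        cnt[cell] += ws;
        tot += ws;
        if (a != b) diff += ws;
      }
      double d;
      bool fl = false;
      if (tot == 0.0) {
        d = NA_REAL;
        fl = true;
      } else if (diff == 0.0) {
        d = 0.0;
      } else {
        // two-stage search: coarse scan with stride 4, then the full
        // resolution within +/- one coarse step of the coarse optimum
        // (the mixture log-likelihood is smooth and unimodal in t).
        std::fill(ll.begin(), ll.end(), 0.0);
        const int stride = 4;
        for (size_t u = 0; u < used.size(); ++u) {
          const double c = cnt[used[u]];
          const double* col = L + (size_t)G * used[u];
          for (int g = 0; g < G; g += stride) ll[g] += c * col[g];
        }
        int gc = 0;
        for (int g = stride; g < G; g += stride)
          if (ll[g] > ll[gc]) gc = g;
        int lo = gc - stride > 0 ? gc - stride : 0;
        int hi = gc + stride < G - 1 ? gc + stride : G - 1;
        for (size_t u = 0; u < used.size(); ++u) {
          const double c = cnt[used[u]];
          const double* col = L + (size_t)G * used[u];
          for (int g = lo; g <= hi; ++g)
            if (g % stride != 0) ll[g] += c * col[g];
        }
        int gm = lo;
        for (int g = lo + 1; g <= hi; ++g) if (ll[g] > ll[gm]) gm = g;
        // a coarse grid point outside the window could still win
        for (int g = 0; g < G; g += stride) if (ll[g] > ll[gm]) gm = g;
        // exact evaluation at a grid point (neighbours of gm may lie
        // outside the refined window)
        auto eval = [&](int g) -> double {
          double v = 0.0;
          for (size_t u = 0; u < used.size(); ++u)
            v += cnt[used[u]] * L[g + (size_t)G * used[u]];
          return v;
        };
        if (gm == G - 1) {
          d = max_distance;
          fl = true;
        } else if (gm == 0) {
          d = std::exp(logt[0]);
        } else {
          const double y0 = eval(gm - 1), y1 = ll[gm], y2 = eval(gm + 1);
          const double denom = y0 - 2.0 * y1 + y2;
          double delta = (denom < 0.0) ? 0.5 * (y0 - y2) / denom : 0.0;
          if (delta > 0.5) delta = 0.5;
          if (delta < -0.5) delta = -0.5;
          d = std::exp(logt[gm] + delta * dlog);
        }
      }
      for (size_t u = 0; u < used.size(); ++u) cnt[used[u]] = 0.0;
      D(i, j) = D(j, i) = d;
      sat(i, j) = sat(j, i) = fl;
    }
  }
  return List::create(_["distance"] = D, _["saturated"] = sat);
}
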