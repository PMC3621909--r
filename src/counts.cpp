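#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Nearest-neighbour distance for every point. With periodic = true the
// minimum-image torus metric on the W x H rectangle is used (equivalent to
// searching the 3x3 tiling); otherwise the plain Euclidean metric.
// O(n^2) symmetric sweep; distances kept squared until the final sqrt.
// [[Rcpp::export]]
NumericVector cpp_nnd(NumericVector x, NumericVector y,
                      double W, double H, bool periodic) {
  const int n = x.size();
  NumericVector out(n, R_PosInf);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    double best = out[i];
    for (int j = i + 1; j < n; ++j) {
      double dx = xi - x[j], dy = yi - y[j];
      if (periodic) {
        dx -= W * std::round(dx / W);
        dy -= H * std::round(dy / H);
      }
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
      if (d2 < out[j]) out[j] = d2;
    }
    out[i] = best;
  }
  return sqrt(out);
}

// Cumulative neighbour counts at each radius edge, summed over all
// reference points. When periodic, targets are counted across the 3x3
// tiling (offsets -W,0,W by -H,0,H), so an image of a point can be
// counted in addition to the point itself at large r, exactly as when
// a field is surrounded by 8 identical copies. same_set skips the
// reference itself in the untranslated tile. Counting is inclusive:
// a pair at distance exactly equal to an edge lands in that bin.
// [[Rcpp::export]]
NumericVector cpp_cum_counts(NumericVector xr, NumericVector yr,
                             NumericVector xt, NumericVector yt,
                             NumericVector edges, double W, double H,
                             bool periodic, bool same_set) {
  const int nr = xr.size(), nt = xt.size(), nb = edges.size();
  std::vector<double> e2(nb);
  for (int b = 0; b < nb; ++b) e2[b] = edges[b] * edges[b];
  const double rmax2 = e2[nb - 1];
  std::vector<double> counts(nb, 0.0);
  const int o0 = periodic ? -1 : 0, o1 = periodic ? 1 : 0;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nt; ++j) {
      for (int ox = o0; ox <= o1; ++ox) {
        for (int oy = o0; oy <= o1; ++oy) {
          if (same_set && i == j && ox == 0 && oy == 0) continue;
          const double dx = (xr[i] - xt[j]) - ox * W;
          const double dy = (yr[i] - yt[j]) - oy * H;
          const double d2 = dx * dx + dy * dy;
          if (d2 > rmax2) continue;
          const int b = std::lower_bound(e2.begin(), e2.end(), d2) - e2.begin();
          counts[b] += 1.0;
        }
      }
    }
  }
  NumericVector out(nb);
  double acc = 0.0;
  for (int b = 0; b < nb; ++b) { acc += counts[b]; out[b] = acc; }
  return out;
}

// Per-reference counts of targets lying within distance r (inclusive),
// with the same periodic-tiling and self-exclusion conventions as
// cpp_cum_counts.
// [[Rcpp::export]]
IntegerVector cpp_counts_within(NumericVector xr, NumericVector yr,
                                NumericVector xt, NumericVector yt,
                                double r, double W, double H,
                                bool periodic, bool same_set) {
  const int nr = xr.size(), nt = xt.size();
  const double r2 = r * r;
  IntegerVector out(nr);
  const int o0 = periodic ? -1 : 0, o1 = periodic ? 1 : 0;
  for (int i = 0; i < nr; ++i) {
    int cnt = 0;
    for (int j = 0; j < nt; ++j) {
      for (int ox = o0; ox <= o1; ++ox) {
        for (int oy = o0; oy <= o1; ++oy) {
          if (same_set && i == j && ox == 0 && oy == 0) continue;
          const double dx = (xr[i] - xt[j]) - ox * W;
          const double dy = (yr[i] - yt[j]) - oy * H;
          if (dx * dx + dy * dy <= r2) ++cnt;
        }
      }
    }
    out[i] = cnt;
  }
  return out;
}

// Resolve hard-core overlaps by symmetric pairwise relaxation on the torus:
// every pair closer than s is pushed apart along its separation axis by
// half the overlap (plus 5% to speed convergence), with minimum-image
// wrapping. Convergence is declared when no pair remains below
// s * (1 - tol); near the jamming density the last fraction of a percent
// of overlap shrinks geometrically and would otherwise never terminate.
// Deterministic for a given input configuration.
// [[Rcpp::export]]
List cpp_relax_packing(NumericVector x0, NumericVector y0,
                       double W, double H, double s, int max_iter,
                       double tol) {
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  const int n = x.size();
  const double s2 = s * s;
  const double s2_ok = s * (1.0 - tol) * s * (1.0 - tol);
  int it = 0;
  bool converged = false;
  for (it = 0; it < max_iter; ++it) {
    bool moved = false;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = x[j] - x[i], dy = y[j] - y[i];
        dx -= W * std::round(dx / W);
        dy -= H * std::round(dy / H);
        double d2 = dx * dx + dy * dy;
        if (d2 >= s2) continue;
        double d = std::sqrt(d2);
        if (d < 1e-9) { dx = 1.0; dy = 0.0; d = 1.0; }  // coincident seeds
        const double push = 0.5 * (s - d) * 1.05 / d;
        x[i] -= dx * push; y[i] -= dy * push;
        x[j] += dx * push; y[j] += dy * push;
        x[i] -= W * std::floor(x[i] / W); y[i] -= H * std::floor(y[i] / H);
        x[j] -= W * std::floor(x[j] / W); y[j] -= H * std::floor(y[j] / H);
        if (d2 < s2_ok) moved = true;
      }
    }
    if (!moved) { converged = true; break; }
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["y"] = NumericVector(y.begin(), y.end()),
                      _["iterations"] = it,
                      _["converged"] = converged);
}
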