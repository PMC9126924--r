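#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Simplex-projection cross mapping over a batch of library draws.
//
// dist:  full pairwise distance matrix between delay vectors (n x n)
// y:     target values aligned with delay-vector indices (NA = unusable)
// libs:  one library draw per row, 1-based delay-vector indices
// n_neighbors: neighbors requested (E + 1); fewer are used when the
//              usable candidate set is smaller
// excl:  Theiler exclusion radius in time steps (0 = exclude target only)
// times: time index of each delay vector (for the Theiler window)
//
// Weights follow the simplex convention w_i = exp(-d_i / d_min); when the
// nearest neighbor lies at distance zero, the zero-distance neighbors get
// uniform weight and the rest none. Equidistant neighbors are ordered by
// time index so results are deterministic. Skill is the Pearson correlation
// between estimates and observed targets; a constant estimate or constant
// truth yields skill 0 (degeneracy convention).
// [[Rcpp::export]]
List simplex_xmap_cpp(NumericMatrix dist, NumericVector y, IntegerMatrix libs,
                      int n_neighbors, int excl, IntegerVector times) {
  const int n = dist.nrow();
  const int n_sub = libs.nrow();
  const int L = libs.ncol();
  NumericVector rhos(n_sub);
  IntegerVector npreds(n_sub);
  LogicalVector degenerate(n_sub);
  std::vector<int> cand;
  cand.reserve(L);

  for (int s = 0; s < n_sub; ++s) {
    int np = 0;
    double sxy = 0, sx = 0, sy = 0, sxx = 0, syy = 0;
    for (int i = 0; i < n; ++i) {
      if (ISNAN(y[i])) continue;
      cand.clear();
      for (int j = 0; j < L; ++j) {
        const int lj = libs(s, j) - 1;
        if (lj == i) continue;
        if (ISNAN(y[lj])) continue;
        if (excl > 0 && std::abs(times[lj] - times[i]) <= excl) continue;
        cand.push_back(lj);
      }
      if (cand.empty()) continue;
      const int k = std::min<int>(n_neighbors, (int)cand.size());
      std::partial_sort(cand.begin(), cand.begin() + k, cand.end(),
                        [&](int a, int b) {
                          const double da = dist(i, a), db = dist(i, b);
                          if (da != db) return da < db;
                          return a < b;
                        });
      const double dmin = dist(i, cand[0]);
      double wsum = 0, est = 0;
      for (int m = 0; m < k; ++m) {
        const double d = dist(i, cand[m]);
        const double w = (dmin > 0) ? std::exp(-d / dmin)
                                    : (d == 0 ? 1.0 : 0.0);
        wsum += w;
        est += w * y[cand[m]];
      }
      if (wsum <= 0) continue;
      est /= wsum;
      ++np;
      const double t = y[i];
      sxy += est * t; sx += est; sy += t; sxx += est * est; syy += t * t;
    }
    npreds[s] = np;
    if (np >= 2) {
      const double vx = sxx - sx * sx / np;
      const double vy = syy - sy * sy / np;
      if (vx > 1e-300 && vy > 1e-300) {
        rhos[s] = (sxy - sx * sy / np) / std::sqrt(vx * vy);
      } else {
        rhos[s] = 0.0;
        degenerate[s] = true;
      }
    } else {
      rhos[s] = 0.0;
      degenerate[s] = true;
    }
  }
  return List::create(_["rho"] = rhos, _["n_pred"] = npreds,
                      _["degenerate"] = degenerate);
}
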