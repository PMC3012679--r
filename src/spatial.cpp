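#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Inverse-distance-weighted refinement of a coarse lat/lon grid.
//
// Coarse grid: n_lat x n_lon matrix, rows = latitude ascending, NA = land.
// Fine grid: `factor` x finer in both directions. A fine cell inherits NA if
// its containing coarse cell is NA (the land mask is kept at coarse
// resolution); otherwise it is the d^-power weighted mean of the `nnb`
// nearest coarse ocean cell centers (planar degrees, longitude wrapped).
// An exact hit (d ~ 0) returns that cell's value.
//
// [[Rcpp::export]]
NumericMatrix idw_refine_cpp(NumericMatrix z, NumericVector lat, NumericVector lon,
                             int factor, double power, int nnb, int max_radius,
                             bool mask_land) {
  int nr = z.nrow(), nc = z.ncol();
  int fr = nr * factor, fc = nc * factor;
  double lat0 = lat[0] - 0.5 * (lat[1] - lat[0]);
  double dlat = (lat[1] - lat[0]);
  double lon0 = lon[0] - 0.5 * (lon[1] - lon[0]);
  double dlon = (lon[1] - lon[0]);
  double span = dlon * nc;  // 360 for a global grid
  NumericMatrix out(fr, fc);
  std::vector<std::pair<double, double> > nbr;  // (dist2, value)
  for (int fi = 0; fi < fr; ++fi) {
    double flat = lat0 + dlat * (fi + 0.5) / factor;
    int ci0 = fi / factor;
    for (int fj = 0; fj < fc; ++fj) {
      int cj0 = fj / factor;
      if (mask_land && NumericMatrix::is_na(z(ci0, cj0))) { out(fi, fj) = NA_REAL; continue; }
      double flon = lon0 + dlon * (fj + 0.5) / factor;
      nbr.clear();
      bool exact = false;
      double exact_val = 0.0;
      for (int r = 0; r <= max_radius; ++r) {
        // once nnb found, stop when the ring cannot beat the current worst
        if ((int) nbr.size() >= nnb) {
          std::sort(nbr.begin(), nbr.end());
          nbr.resize(nnb);
          double worst = std::sqrt(nbr.back().first);
          if ((r - 1) * std::min(std::fabs(dlat), std::fabs(dlon)) > worst) break;
        }
        // scan ring at Chebyshev radius r around (ci0, cj0)
        for (int di = -r; di <= r; ++di) {
          int ci = ci0 + di;
          if (ci < 0 || ci >= nr) continue;
          double clat = lat[ci];
          int jlo = -r, jhi = r;
          for (int dj = jlo; dj <= jhi; ++dj) {
            if (std::abs(di) != r && std::abs(dj) != r) continue;  // ring only
            int cj = ((cj0 + dj) % nc + nc) % nc;  // wrap longitude
            double v = z(ci, cj);
            if (NumericMatrix::is_na(v)) continue;
            double dla = clat - flat;
            double dlo = std::fabs(lon[cj] - flon);
            if (dlo > span / 2.0) dlo = span - dlo;
            double d2 = dla * dla + dlo * dlo;
            if (d2 < 1e-18) { exact = true; exact_val = v; break; }
            nbr.push_back(std::make_pair(d2, v));
          }
          if (exact) break;
        }
        if (exact) break;
      }
      if (exact) { out(fi, fj) = exact_val; continue; }
      if (nbr.empty()) { out(fi, fj) = NA_REAL; continue; }
      std::sort(nbr.begin(), nbr.end());
      if ((int) nbr.size() > nnb) nbr.resize(nnb);
      double wsum = 0.0, vsum = 0.0;
      for (size_t k = 0; k < nbr.size(); ++k) {
        double w = std::pow(std::sqrt(nbr[k].first), -power);
        wsum += w;
        vsum += w * nbr[k].second;
      }
      out(fi, fj) = vsum / wsum;
    }
  }
  return out;
}

// Fisher-Jenks optimal 1-D classification by dynamic programming.
// x must be sorted ascending. Returns 1-based index of the last element of
// each of the k classes. Minimizes total within-class sum of squared
// deviations; O(k n^2).
// [[Rcpp::export]]
IntegerVector jenks_dp_cpp(NumericVector x, int k) {
  int n = x.size();
  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    cs2[i + 1] = cs2[i] + x[i] * x[i];
  }
  // ssd of x[i..j] inclusive, 0-based
  #define SSD(i, j) (cs2[(j) + 1] - cs2[(i)] - \
      (cs[(j) + 1] - cs[(i)]) * (cs[(j) + 1] - cs[(i)]) / ((j) - (i) + 1))
  std::vector<std::vector<double> > D(k, std::vector<double>(n, 0.0));
  std::vector<std::vector<int> > B(k, std::vector<int>(n, 0));
  for (int j = 0; j < n; ++j) D[0][j] = SSD(0, j);
  for (int m = 1; m < k; ++m) {
    for (int j = m; j < n; ++j) {
      double best = R_PosInf;
      int arg = m;
      for (int i = m; i <= j; ++i) {
        double v = D[m - 1][i - 1] + SSD(i, j);
        if (v < best - 1e-12) { best = v; arg = i; }
      }
      D[m][j] = best;
      B[m][j] = arg;
    }
  }
  #undef SSD
  IntegerVector ends(k);
  int j = n - 1;
  for (int m = k - 1; m >= 0; --m) {
    ends[m] = j + 1;            // 1-based last index of class m
    if (m > 0) j = B[m][j] - 1;
  }
  return ends;
}
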