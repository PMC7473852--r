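#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact Euclidean feature transform on a cell grid (Felzenszwalb &
// Huttenlocher two-pass lower-envelope algorithm, with the nearest site
// index propagated alongside the distance).  For every cell, returns the
// 1-based column-major linear index of the nearest TRUE cell in `sites`,
// or NA if the grid holds no site.  Distances are centre-to-centre in cell
// units; callers scale by the cell size.
// [[Rcpp::export]]
IntegerMatrix ft_nearest_cpp(LogicalMatrix sites) {
  const int nr = sites.nrow(), nc = sites.ncol();
  const double INF = 1e18;
  IntegerMatrix src1(nr, nc);   // nearest site row within own column
  NumericMatrix d1(nr, nc);     // vertical distance to it (cells)
  for (int j = 0; j < nc; ++j) {
    int last = -1;
    for (int i = 0; i < nr; ++i) {
      if (sites(i, j)) last = i;
      if (last >= 0) { d1(i, j) = i - last; src1(i, j) = last; }
      else           { d1(i, j) = INF;      src1(i, j) = -1;   }
    }
    last = -1;
    for (int i = nr - 1; i >= 0; --i) {
      if (sites(i, j)) last = i;
      if (last >= 0 && last - i < d1(i, j)) { d1(i, j) = last - i; src1(i, j) = last; }
    }
  }
  IntegerMatrix out(nr, nc);
  std::vector<int> v(nc);
  std::vector<double> z(nc + 1), f(nc);
  std::vector<int> cols; cols.reserve(nc);
  for (int i = 0; i < nr; ++i) {
    cols.clear();
    for (int j = 0; j < nc; ++j) {
      double d = d1(i, j);
      f[j] = (d >= INF) ? INF : d * d;
      if (f[j] < INF) cols.push_back(j);
    }
    if (cols.empty()) {
      for (int j = 0; j < nc; ++j) out(i, j) = NA_INTEGER;
      continue;
    }
    int k = 0;
    v[0] = cols[0]; z[0] = -INF; z[1] = INF;
    for (size_t t = 1; t < cols.size(); ++t) {
      int q = cols[t];
      double s = 0.0;
      while (true) {
        int p = v[k];
        s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) / (2.0 * (q - p));
        if (s <= z[k]) { --k; } else break;
      }
      ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
    }
    int kk = 0;
    for (int j = 0; j < nc; ++j) {
      while (z[kk + 1] < j) ++kk;
      int p = v[kk];
      out(i, j) = src1(i, p) + p * nr + 1;
    }
  }
  return out;
}

// Connected-component labelling of a logical mask (iterative flood fill).
// Labels are 1..n in scan order, 0 for background.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, bool diagonal) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  const int di8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dj8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int nn = diagonal ? 8 : 4;
  int cur = 0;
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0)) continue;
      ++cur;
      lab(i0, j0) = cur;
      stack.push_back(i0 + j0 * nr);
      while (!stack.empty()) {
        int id = stack.back(); stack.pop_back();
        int i = id % nr, j = id / nr;
        for (int t = 0; t < nn; ++t) {
          int ii = i + di8[t], jj = j + dj8[t];
          if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
          if (mask(ii, jj) && !lab(ii, jj)) {
            lab(ii, jj) = cur;
            stack.push_back(ii + jj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Count exposed cell edges per labelled region (boundary edges against a
// different label, background, or the grid border).  Used for raster
// perimeters: perimeter_km = edges * cellsize.
// [[Rcpp::export]]
NumericVector boundary_edges_cpp(IntegerMatrix lab, int nlab) {
  const int nr = lab.nrow(), nc = lab.ncol();
  NumericVector out(nlab);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l <= 0 || l > nlab) continue;
      if (i == 0      || lab(i - 1, j) != l) out[l - 1] += 1;
      if (i == nr - 1 || lab(i + 1, j) != l) out[l - 1] += 1;
      if (j == 0      || lab(i, j - 1) != l) out[l - 1] += 1;
      if (j == nc - 1 || lab(i, j + 1) != l) out[l - 1] += 1;
    }
  }
  return out;
}
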