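#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher,
// Theory of Computing 2012) with nearest-site tracking.
//
// mask: logical matrix, TRUE = feature (contour) pixel.
// Returns dist (Euclidean, double) plus the row/col (1-based) of one nearest
// feature pixel for every pixel.
//
// Pass 1 scans each column for the nearest feature row (1-D transform along
// rows); pass 2 computes the lower envelope of parabolas along each row.
// [[Rcpp::export(name = ".edt_cpp")]]
List edt_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  const double INF = std::numeric_limits<double>::infinity();

  // nearest feature row per (row, col) within the same column
  NumericMatrix d1(H, W);       // vertical distance
  IntegerMatrix nrow1(H, W);    // row index (0-based) of that feature, -1 if none
  for (int x = 0; x < W; ++x) {
    int last = -1;
    for (int y = 0; y < H; ++y) {
      if (mask(y, x)) last = y;
      nrow1(y, x) = last;
      d1(y, x) = (last < 0) ? INF : (double)(y - last);
    }
    last = -1;
    for (int y = H - 1; y >= 0; --y) {
      if (mask(y, x)) last = y;
      if (last >= 0) {
        double d = (double)(last - y);
        if (d < d1(y, x)) { d1(y, x) = d; nrow1(y, x) = last; }
      }
    }
  }

  NumericMatrix dist(H, W);
  IntegerMatrix nr(H, W), nc(H, W);
  std::vector<int> v(W);          // parabola sites (column indices)
  std::vector<double> z(W + 1);   // envelope breakpoints

  for (int y = 0; y < H; ++y) {
    // f(x) = d1(y,x)^2 ; skip columns with no feature at all
    int k = 0;
    bool any = false;
    for (int x = 0; x < W; ++x) if (nrow1(y, x) >= 0) { any = true; break; }
    if (!any) {
      for (int x = 0; x < W; ++x) { dist(y, x) = R_PosInf; nr(y, x) = NA_INTEGER; nc(y, x) = NA_INTEGER; }
      continue;
    }
    k = -1;
    for (int x = 0; x < W; ++x) {
      double fx = d1(y, x);
      if (!R_FINITE(fx)) continue;
      fx *= fx;
      if (k < 0) { k = 0; v[0] = x; z[0] = -INF; z[1] = INF; continue; }
      double s;
      while (true) {
        int q = v[k];
        double fq = d1(y, q) * d1(y, q);
        s = ((fx + (double)x * x) - (fq + (double)q * q)) / (2.0 * (x - q));
        if (s <= z[k]) { --k; if (k < 0) break; } else break;
      }
      ++k;
      v[k] = x; z[k] = (k == 0) ? -INF : s; z[k + 1] = INF;
    }
    int j = 0;
    for (int x = 0; x < W; ++x) {
      while (z[j + 1] < (double)x) ++j;
      int q = v[j];
      double dy = d1(y, q), dx = (double)(x - q);
      dist(y, x) = std::sqrt(dx * dx + dy * dy);
      nr(y, x) = nrow1(y, q) + 1;  // 1-based for R
      nc(y, x) = q + 1;
    }
  }
  return List::create(_["dist"] = dist, _["nearest_row"] = nr, _["nearest_col"] = nc);
}
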