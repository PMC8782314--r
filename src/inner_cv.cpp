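#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Shared helpers for the nested-CV decoding hot loop. Data are passed as
// flat row-major buffers (rows = patterns) to avoid R-level subsetting in
// the inner loops.

namespace {

struct Mat {
  std::vector<double> v; int n, d;
  Mat(int n_, int d_) : v((size_t)n_ * d_), n(n_), d(d_) {}
  double *row(int i) { return v.data() + (size_t)i * d; }
  const double *row(int i) const { return v.data() + (size_t)i * d; }
};

void dcd_train_flat(const Mat &X, const std::vector<double> &y, double C,
                    int max_pass, double tol, std::vector<double> &w) {
  const int n = X.n, d = X.d;
  std::vector<double> alpha(n, 0.0), Q(n);
  w.assign(d + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    const double *xi = X.row(i);
    double q = 1.0;
    for (int j = 0; j < d; ++j) q += xi[j] * xi[j];
    Q[i] = q;
  }
  for (int pass = 0; pass < max_pass; ++pass) {
    double max_delta = 0.0;
    for (int i = 0; i < n; ++i) {
      const double *xi = X.row(i);
      double wx = w[d];
      for (int j = 0; j < d; ++j) wx += w[j] * xi[j];
      double G = y[i] * wx - 1.0;
      double a_old = alpha[i];
      double a_new = std::min(std::max(a_old - G / Q[i], 0.0), C);
      double delta = a_new - a_old;
      if (delta != 0.0) {
        alpha[i] = a_new;
        double dyi = delta * y[i];
        for (int j = 0; j < d; ++j) w[j] += dyi * xi[j];
        w[d] += dyi;
      }
      max_delta = std::max(max_delta, std::fabs(delta));
    }
    if (max_delta < tol) break;
  }
}

// one-vs-one prediction; ytr in 1..K
void ovo_predict_flat(const Mat &Xtr, const std::vector<int> &ytr,
                      const Mat &Xte, double C, int max_pass, double tol,
                      std::vector<int> &pred) {
  int K = 0;
  for (int v : ytr) K = std::max(K, v);
  std::vector<int> votes((size_t)Xte.n * K, 0);
  std::vector<double> w;
  for (int a = 1; a < K; ++a) {
    for (int b = a + 1; b <= K; ++b) {
      std::vector<int> idx;
      for (int i = 0; i < Xtr.n; ++i)
        if (ytr[i] == a || ytr[i] == b) idx.push_back(i);
      if (idx.empty()) continue;
      Mat Xs((int)idx.size(), Xtr.d);
      std::vector<double> ys(idx.size());
      for (size_t r = 0; r < idx.size(); ++r) {
        std::copy(Xtr.row(idx[r]), Xtr.row(idx[r]) + Xtr.d, Xs.row((int)r));
        ys[r] = (ytr[idx[r]] == a) ? 1.0 : -1.0;
      }
      dcd_train_flat(Xs, ys, C, max_pass, tol, w);
      for (int t = 0; t < Xte.n; ++t) {
        const double *xt = Xte.row(t);
        double s = w[Xtr.d];
        for (int j = 0; j < Xtr.d; ++j) s += w[j] * xt[j];
        votes[(size_t)t * K + (s >= 0 ? a - 1 : b - 1)] += 1;
      }
    }
  }
  pred.assign(Xte.n, 1);
  for (int t = 0; t < Xte.n; ++t) {
    int best = 0;
    for (int k = 1; k < K; ++k)
      if (votes[(size_t)t * K + k] > votes[(size_t)t * K + best]) best = k;
    pred[t] = best + 1;
  }
}

// one-way ANOVA F per column over rows `rows` of X (patterns x voxels,
// column-major as passed from R)
void anova_f_rows(const NumericMatrix &X, const std::vector<int> &rows,
                  const IntegerVector &y, int K, std::vector<double> &F) {
  const int V = X.ncol();
  const int n = (int)rows.size();
  F.assign(V, 0.0);
  std::vector<int> cnt(K, 0);
  for (int i : rows) cnt[y[i] - 1] += 1;
  std::vector<double> gsum(K);
  for (int v = 0; v < V; ++v) {
    std::fill(gsum.begin(), gsum.end(), 0.0);
    double tot = 0.0, ss = 0.0;
    for (int i : rows) {
      double x = X(i, v);
      gsum[y[i] - 1] += x; tot += x; ss += x * x;
    }
    double gm = tot / n, ssb = 0.0;
    for (int k = 0; k < K; ++k)
      if (cnt[k] > 0) {
        double m = gsum[k] / cnt[k];
        ssb += cnt[k] * (m - gm) * (m - gm);
      }
    double sst = ss - n * gm * gm;
    double ssw = sst - ssb;
    F[v] = (ssb / (K - 1)) / (ssw / (n - K));
  }
}

}  // namespace

// Inner leave-one-run-out accuracy for every candidate voxel count.
// X: patterns x voxels, y: 1..K labels, runs: run id per pattern,
// n_keep: voxel counts to evaluate. Returns hits per candidate and the
// total number of inner test patterns.
// [[Rcpp::export(name = ".inner_cv_cpp")]]
List inner_cv_cpp(NumericMatrix X, IntegerVector y, IntegerVector runs,
                  IntegerVector n_keep, double C, int max_pass, double tol) {
  const int n = X.nrow();
  int K = 0;
  for (int i = 0; i < n; ++i) K = std::max(K, y[i]);
  std::vector<int> ur;
  for (int i = 0; i < n; ++i)
    if (std::find(ur.begin(), ur.end(), runs[i]) == ur.end())
      ur.push_back(runs[i]);
  NumericVector hits(n_keep.size());
  int total = 0;
  std::vector<double> F;
  for (int r : ur) {
    std::vector<int> tr, te;
    for (int i = 0; i < n; ++i) (runs[i] == r ? te : tr).push_back(i);
    anova_f_rows(X, tr, y, K, F);
    std::vector<int> ord(F.size());
    for (size_t j = 0; j < ord.size(); ++j) ord[j] = (int)j;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return F[a] > F[b]; });
    total += (int)te.size();
    std::vector<int> ytr_v(tr.size()), pred;
    for (size_t i = 0; i < tr.size(); ++i) ytr_v[i] = y[tr[i]];
    for (int gi = 0; gi < n_keep.size(); ++gi) {
      int k = n_keep[gi];
      Mat Xtr((int)tr.size(), k), Xte((int)te.size(), k);
      for (size_t i = 0; i < tr.size(); ++i)
        for (int j = 0; j < k; ++j) Xtr.row((int)i)[j] = X(tr[i], ord[j]);
      for (size_t i = 0; i < te.size(); ++i)
        for (int j = 0; j < k; ++j) Xte.row((int)i)[j] = X(te[i], ord[j]);
      ovo_predict_flat(Xtr, ytr_v, Xte, C, max_pass, tol, pred);
      for (size_t i = 0; i < te.size(); ++i)
        if (pred[i] == y[te[i]]) hits[gi] += 1;
    }
  }
  return List::create(_["hits"] = hits, _["total"] = total);
}
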