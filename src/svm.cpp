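#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// L2-regularized L1-loss linear SVM, solved in the dual by coordinate
// descent (Hsieh et al., ICML 2008). Deterministic cyclic coordinate order
// so results are reproducible without an RNG. A constant feature (value 1)
// is appended internally to provide a bias term.
static void dcd_train(const NumericMatrix &X, const std::vector<double> &y,
                      double C, int max_pass, double tol,
                      std::vector<double> &w) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> alpha(n, 0.0), Q(n);
  w.assign(d + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    double q = 1.0;  // bias feature
    for (int j = 0; j < d; ++j) q += X(i, j) * X(i, j);
    Q[i] = q;
  }
  for (int pass = 0; pass < max_pass; ++pass) {
    double max_delta = 0.0;
    for (int i = 0; i < n; ++i) {
      double wx = w[d];
      for (int j = 0; j < d; ++j) wx += w[j] * X(i, j);
      double G = y[i] * wx - 1.0;
      double a_old = alpha[i];
      double a_new = a_old - G / Q[i];
      if (a_new < 0.0) a_new = 0.0;
      if (a_new > C) a_new = C;
      double delta = a_new - a_old;
      if (delta != 0.0) {
        alpha[i] = a_new;
        double dyi = delta * y[i];
        for (int j = 0; j < d; ++j) w[j] += dyi * X(i, j);
        w[d] += dyi;
      }
      if (std::fabs(delta) > max_delta) max_delta = std::fabs(delta);
    }
    if (max_delta < tol) break;
  }
}

// One-vs-one multiclass linear SVM: train on (Xtrain, ytrain in 1..K),
// predict labels for Xtest by majority vote over all K(K-1)/2 binary
// machines; ties go to the smallest class label.
// [[Rcpp::export(name = ".ovo_svm_cpp")]]
IntegerVector ovo_svm_cpp(NumericMatrix Xtrain, IntegerVector ytrain,
                          NumericMatrix Xtest, double C,
                          int max_pass, double tol) {
  const int n = Xtrain.nrow(), d = Xtrain.ncol(), m = Xtest.nrow();
  int K = 0;
  for (int i = 0; i < n; ++i) if (ytrain[i] > K) K = ytrain[i];
  IntegerMatrix votes(m, K);
  std::vector<double> w;
  for (int a = 1; a < K; ++a) {
    for (int b = a + 1; b <= K; ++b) {
      std::vector<int> idx;
      for (int i = 0; i < n; ++i)
        if (ytrain[i] == a || ytrain[i] == b) idx.push_back(i);
      if (idx.empty()) continue;
      NumericMatrix Xs((int)idx.size(), d);
      std::vector<double> ys(idx.size());
      for (size_t r = 0; r < idx.size(); ++r) {
        for (int j = 0; j < d; ++j) Xs(r, j) = Xtrain(idx[r], j);
        ys[r] = (ytrain[idx[r]] == a) ? 1.0 : -1.0;
      }
      dcd_train(Xs, ys, C, max_pass, tol, w);
      for (int t = 0; t < m; ++t) {
        double s = w[d];
        for (int j = 0; j < d; ++j) s += w[j] * Xtest(t, j);
        if (s >= 0) votes(t, a - 1) += 1; else votes(t, b - 1) += 1;
      }
    }
  }
  IntegerVector pred(m);
  for (int t = 0; t < m; ++t) {
    int best = 0;
    for (int k = 1; k < K; ++k) if (votes(t, k) > votes(t, best)) best = k;
    pred[t] = best + 1;
  }
  return pred;
}
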