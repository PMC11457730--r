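#include <Rcpp.h>
using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger estimator, algorithm 1, max-norm metric.
// For each point i: eps_i = max-norm distance in the joint (x, y) space to
// its k-th nearest neighbour; n_x(i), n_y(i) = number of other points whose
// marginal distance is strictly less than eps_i. Exact O(n^2) scans with the
// marginal distances computed once per reference point.
// Returns digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1)).
// [[Rcpp::export(name = ".ksg_mi_cpp")]]
double ksg_mi_cpp(NumericMatrix x, NumericMatrix y, int k) {
  const int n = x.nrow();
  if (y.nrow() != n) stop("x and y must have the same number of rows");
  if (k < 1 || n <= k + 1) stop("need n > k + 1");
  const int dx = x.ncol(), dy = y.ncol();
  const double* xp = REAL(x);
  const double* yp = REAL(y);

  std::vector<double> mdx(n), mdy(n), dj(n), tmp(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dxx = 0.0;
      for (int c = 0; c < dx; ++c) {
        double v = std::fabs(xp[i + (size_t) c * n] - xp[j + (size_t) c * n]);
        if (v > dxx) dxx = v;
      }
      double dyy = 0.0;
      for (int c = 0; c < dy; ++c) {
        double v = std::fabs(yp[i + (size_t) c * n] - yp[j + (size_t) c * n]);
        if (v > dyy) dyy = v;
      }
      mdx[j] = dxx;
      mdy[j] = dyy;
      dj[j] = dxx > dyy ? dxx : dyy;
    }
    dj[i] = R_PosInf;
    tmp = dj;
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    const double eps = tmp[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (mdx[j] < eps) ++nx;
      if (mdy[j] < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  return R::digamma((double) k) + R::digamma((double) n) - acc / n;
}
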