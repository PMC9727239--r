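#include <Rcpp.h>
using namespace Rcpp;

// Asymmetric least squares baseline (Whittaker smoother with asymmetric
// weights). The normal-equation matrix diag(w) + lambda * D'D, with D the
// second-difference operator, is pentadiagonal SPD; it is factorized as a
// banded LDL' in O(m) per iteration.
//
// Returns the fitted baseline with attribute "converged" (weights fixed
// point reached within n_iter).
// [[Rcpp::export]]
NumericVector asls_baseline_cpp(NumericVector y, double lambda, double p,
                                int n_iter) {
  const int m = y.size();
  if (m < 5) stop("AsLS needs at least 5 points");

  // bands of D'D for the second-difference penalty
  std::vector<double> dd(m, 6.0), od1(m - 1, -4.0), od2(m - 2, 1.0);
  dd[0] = dd[m - 1] = 1.0;
  dd[1] = dd[m - 2] = 5.0;
  od1[0] = od1[m - 2] = -2.0;

  std::vector<double> w(m, 1.0), wn(m), d(m), e1(m - 1), e2(m - 2),
      x(m), z(m);
  bool converged = false;

  for (int iter = 0; iter < n_iter; ++iter) {
    // factorize A = diag(w) + lambda * D'D as L D L'
    for (int i = 0; i < m; ++i) {
      double di = w[i] + lambda * dd[i];
      if (i >= 1) di -= e1[i - 1] * e1[i - 1] * d[i - 1];
      if (i >= 2) di -= e2[i - 2] * e2[i - 2] * d[i - 2];
      d[i] = di;
      if (i + 1 < m) {
        double a1 = lambda * od1[i];
        if (i >= 1) a1 -= e2[i - 1] * e1[i - 1] * d[i - 1];
        e1[i] = a1 / di;
      }
      if (i + 2 < m) e2[i] = lambda * od2[i] / di;
    }
    // solve L D L' z = w * y
    for (int i = 0; i < m; ++i) {
      double xi = w[i] * y[i];
      if (i >= 1) xi -= e1[i - 1] * x[i - 1];
      if (i >= 2) xi -= e2[i - 2] * x[i - 2];
      x[i] = xi;
    }
    for (int i = 0; i < m; ++i) x[i] /= d[i];
    for (int i = m - 1; i >= 0; --i) {
      double zi = x[i];
      if (i + 1 < m) zi -= e1[i] * z[i + 1];
      if (i + 2 < m) zi -= e2[i] * z[i + 2];
      z[i] = zi;
    }
    // asymmetric reweighting
    bool same = true;
    for (int i = 0; i < m; ++i) {
      wn[i] = (y[i] > z[i]) ? p : 1.0 - p;
      if (wn[i] != w[i]) same = false;
    }
    if (same && iter > 0) { converged = true; break; }
    w = wn;
  }

  NumericVector out(z.begin(), z.end());
  out.attr("converged") = converged;
  return out;
}
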