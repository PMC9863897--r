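#include <Rcpp.h>
using namespace Rcpp;

// Epsilon-insensitive support vector regression, dual coordinate descent.
//
// The bias term is absorbed into the kernel (K + 1), i.e. a regularized
// intercept, which removes the equality constraint from the dual and makes
// single-coordinate updates exact:
//   maximize  -1/2 b' K b - eps * sum|b_i| + y' b,   -C <= b_i <= C
// Each coordinate has the closed-form soft-threshold/clip solution.

// [[Rcpp::export]]
NumericVector svr_dual_cd(NumericMatrix K, NumericVector y, double C,
                          double eps, double tol = 1e-5,
                          int max_sweeps = 1000,
                          Nullable<NumericVector> warm = R_NilValue) {
  int n = y.size();
  NumericVector beta(n);
  NumericVector f(n);  // f = K beta
  if (warm.isNotNull()) {
    NumericVector w(warm);
    for (int i = 0; i < n; ++i) {
      double bi = w[i];
      if (bi > C) bi = C; else if (bi < -C) bi = -C;
      beta[i] = bi;
    }
    for (int j = 0; j < n; ++j) {
      double fj = 0.0;
      for (int i = 0; i < n; ++i) fj += K(j, i) * beta[i];
      f[j] = fj;
    }
  }
  double obj_prev = 0.0;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double max_delta = 0.0;
    for (int i = 0; i < n; ++i) {
      double kii = K(i, i);
      if (kii <= 0.0) continue;
      double g = y[i] - (f[i] - kii * beta[i]);
      double b_new;
      if (g > eps) b_new = (g - eps) / kii;
      else if (g < -eps) b_new = (g + eps) / kii;
      else b_new = 0.0;
      if (b_new > C) b_new = C;
      else if (b_new < -C) b_new = -C;
      double d = b_new - beta[i];
      if (d != 0.0) {
        NumericMatrix::Column kcol = K(_, i);
        for (int j = 0; j < n; ++j) f[j] += kcol[j] * d;
        beta[i] = b_new;
        double ad = d < 0 ? -d : d;
        if (ad > max_delta) max_delta = ad;
      }
    }
    if (max_delta < tol * (C > 1.0 ? C : 1.0)) break;
    // dual objective: -1/2 b'Kb - eps*sum|b| + y'b ; stop on stagnation
    double quad = 0.0, lin = 0.0;
    for (int i = 0; i < n; ++i) {
      quad += beta[i] * f[i];
      lin += y[i] * beta[i] - eps * (beta[i] < 0 ? -beta[i] : beta[i]);
    }
    double obj = -0.5 * quad + lin;
    if (sweep > 0 && obj - obj_prev < 1e-8 * (1.0 + (obj < 0 ? -obj : obj)))
      break;
    obj_prev = obj;
  }
  return beta;
}

// direct-form II transposed IIR filter with explicit initial state
// (a[0] assumed 1 after normalization in R)
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int n = x.size();
  int nf = std::max(b.size(), a.size());
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0), z(nf - 1, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  for (int i = 0; i < zi.size() && i < nf - 1; ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int k = 0; k < nf - 2; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}
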