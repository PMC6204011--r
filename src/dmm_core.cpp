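#include <Rcpp.h>
using namespace Rcpp;

// Log Dirichlet-multinomial likelihood of every sample under every component.
// X: n x S count matrix, alpha: S x K matrix of positive Dirichlet parameters.
// Returns n x K matrix of log f(x_i | alpha_k).
// [[Rcpp::export]]
NumericMatrix dm_logliks_cpp(const IntegerMatrix& X, const NumericMatrix& alpha) {
  const int n = X.nrow(), S = X.ncol(), K = alpha.ncol();
  std::vector<double> A(K), lgA(K);
  std::vector< std::vector<double> > lga(K, std::vector<double>(S));
  for (int k = 0; k < K; ++k) {
    double a = 0.0;
    for (int j = 0; j < S; ++j) {
      a += alpha(j, k);
      lga[k][j] = R::lgammafn(alpha(j, k));
    }
    A[k] = a;
    lgA[k] = R::lgammafn(a);
  }
  NumericMatrix out(n, K);
  for (int i = 0; i < n; ++i) {
    double ni = 0.0;
    for (int j = 0; j < S; ++j) ni += X(i, j);
    for (int k = 0; k < K; ++k) {
      double ll = lgA[k] - R::lgammafn(A[k] + ni);
      for (int j = 0; j < S; ++j) {
        const int x = X(i, j);
        if (x > 0) ll += R::lgammafn(alpha(j, k) + x) - lga[k][j];
      }
      out(i, k) = ll;
    }
  }
  return out;
}

// Responsibility-weighted fixed-point update of one component's alpha
// (Minka's iteration for the Dirichlet-multinomial, weights w_i >= 0).
// Each pass multiplies alpha_j by
//   sum_i w_i [psi(alpha_j + x_ij) - psi(alpha_j)] /
//   sum_i w_i [psi(A + n_i) - psi(A)],
// which cannot decrease the weighted likelihood.
// [[Rcpp::export]]
NumericVector dm_alpha_update_cpp(const IntegerMatrix& X, const NumericVector& w,
                                  const NumericVector& alpha, int inner, double floor_) {
  const int n = X.nrow(), S = X.ncol();
  std::vector<double> rowtot(n);
  for (int i = 0; i < n; ++i) {
    double t = 0.0;
    for (int j = 0; j < S; ++j) t += X(i, j);
    rowtot[i] = t;
  }
  NumericVector a = clone(alpha);
  for (int it = 0; it < inner; ++it) {
    double A = 0.0;
    for (int j = 0; j < S; ++j) A += a[j];
    double den = 0.0;
    for (int i = 0; i < n; ++i)
      if (w[i] > 0) den += w[i] * (R::digamma(rowtot[i] + A) - R::digamma(A));
    if (den <= 0.0) break;
    std::vector<double> num(S, 0.0);
    for (int i = 0; i < n; ++i) {
      const double wi = w[i];
      if (wi <= 0.0) continue;
      for (int j = 0; j < S; ++j) {
        const int x = X(i, j);
        if (x > 0) num[j] += wi * (R::digamma(a[j] + x) - R::digamma(a[j]));
      }
    }
    for (int j = 0; j < S; ++j) {
      double v = a[j] * num[j] / den;
      a[j] = (v > floor_) ? v : floor_;
    }
  }
  return a;
}

// Weighted gradient and curvature sums used by the Laplace evidence.
// Returns, for one component with weights w:
//   g[j] = sum_i w_i [psi(A) - psi(A + n_i) + psi(alpha_j + x_ij) - psi(alpha_j)]
//   d[j] = sum_i w_i [psi'(alpha_j + x_ij) - psi'(alpha_j)]
//   c    = sum_i w_i [psi'(A) - psi'(A + n_i)]
// [[Rcpp::export]]
List dm_laplace_terms_cpp(const IntegerMatrix& X, const NumericVector& w,
                          const NumericVector& alpha) {
  const int n = X.nrow(), S = X.ncol();
  double A = 0.0;
  for (int j = 0; j < S; ++j) A += alpha[j];
  double common = 0.0, c = 0.0;
  for (int i = 0; i < n; ++i) {
    if (w[i] <= 0.0) continue;
    double ni = 0.0;
    for (int j = 0; j < S; ++j) ni += X(i, j);
    common += w[i] * (R::digamma(A) - R::digamma(A + ni));
    c += w[i] * (R::trigamma(A) - R::trigamma(A + ni));
  }
  NumericVector g(S), d(S);
  for (int i = 0; i < n; ++i) {
    const double wi = w[i];
    if (wi <= 0.0) continue;
    for (int j = 0; j < S; ++j) {
      const int x = X(i, j);
      if (x > 0) {
        g[j] += wi * (R::digamma(alpha[j] + x) - R::digamma(alpha[j]));
        d[j] += wi * (R::trigamma(alpha[j] + x) - R::trigamma(alpha[j]));
      }
    }
  }
  for (int j = 0; j < S; ++j) g[j] += common;
  return List::create(_["g"] = g, _["d"] = d, _["c"] = c);
}
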