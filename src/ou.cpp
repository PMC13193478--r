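// Map-conditional Gaussian likelihood of a multi-regime BM/OU model.
//
// Means and variances are propagated segment-wise down the painted tree;
// the covariance of two tips is the variance at their MRCA attenuated by
// exp(-integral of alpha) along both descending paths.  The dense
// log-density uses an in-place Cholesky factorization.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <R_ext/Lapack.h>
#include <cmath>
#include <vector>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// [[Rcpp::export]]
double ou_map_loglik_cpp(IntegerMatrix pre_edge, IntegerVector seg_count,
                         IntegerVector seg_regime, NumericVector seg_dur,
                         IntegerMatrix mrca, int n_tip, int n_node,
                         int root_regime, NumericVector sigma2,
                         NumericVector alpha, NumericVector theta,
                         double root_mean, bool is_ou, bool stationary,
                         NumericVector x, double ridge) {
  std::vector<double> m(n_node), v(n_node), la(n_node);
  const int root = n_tip; // 0-based ape root index (n_tip + 1 in R)
  if (is_ou) {
    m[root] = theta[root_regime];
    v[root] = stationary
      ? sigma2[root_regime] / (2.0 * alpha[root_regime]) : 0.0;
  } else {
    m[root] = root_mean;
    v[root] = 0.0;
  }
  la[root] = 0.0;
  int sp = 0;
  for (int e = 0; e < pre_edge.nrow(); ++e) {
    const int par = pre_edge(e, 0) - 1, ch = pre_edge(e, 1) - 1;
    double mm = m[par], vv = v[par], ll = la[par];
    for (int s = 0; s < seg_count[e]; ++s, ++sp) {
      const int r = seg_regime[sp];
      const double t = seg_dur[sp], a = alpha[r], s2 = sigma2[r];
      if (a > 1e-12) {
        const double e1 = std::exp(-a * t);
        mm = theta[r] + (mm - theta[r]) * e1;
        vv = vv * e1 * e1 + s2 * (-std::expm1(-2.0 * a * t)) / (2.0 * a);
        ll -= a * t;
      } else {
        vv += s2 * t;
      }
    }
    m[ch] = mm; v[ch] = vv; la[ch] = ll;
  }
  // tip covariance: v[anc] * A_i * A_j / A_anc^2 with A = exp(la)
  std::vector<double> A(n_node), w(n_node);
  for (int k = 0; k < n_node; ++k) {
    A[k] = std::exp(la[k]);
    w[k] = v[k] / (A[k] * A[k]);
  }
  std::vector<double> S((size_t)n_tip * n_tip);
  for (int i = 0; i < n_tip; ++i) {
    for (int j = 0; j < i; ++j) {
      const int anc = mrca(i, j) - 1;
      const double val = w[anc] * A[i] * A[j];
      S[(size_t)i * n_tip + j] = S[(size_t)j * n_tip + i] = val;
    }
    S[(size_t)i * n_tip + i] = v[i];
  }
  std::vector<double> z(n_tip);
  for (int i = 0; i < n_tip; ++i) z[i] = x[i] - m[i];
  // LAPACK Cholesky with one ridge retry
  for (int attempt = 0; attempt < 2; ++attempt) {
    std::vector<double> L(S);
    if (attempt == 1)
      for (int i = 0; i < n_tip; ++i) L[(size_t)i * n_tip + i] += ridge;
    int info = 0;
    F77_CALL(dpotrf)("L", &n_tip, L.data(), &n_tip, &info FCONE);
    if (info != 0) continue;
    double logdet = 0.0;
    for (int i = 0; i < n_tip; ++i)
      logdet += std::log(L[(size_t)i * n_tip + i]);
    std::vector<double> u(z);
    int one = 1;
    F77_CALL(dtrtrs)("L", "N", "N", &n_tip, &one, L.data(), &n_tip,
                     u.data(), &n_tip, &info FCONE FCONE FCONE);
    if (info != 0) continue;
    double q = 0.0;
    for (int i = 0; i < n_tip; ++i) q += u[i] * u[i];
    return -0.5 * (n_tip * std::log(2.0 * M_PI) + q) - logdet;
  }
  return R_NegInf;
}
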