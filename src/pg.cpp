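// Polya-Gamma PG(1, z) sampler (Devroye's alternating-series method, as used
// for exact Gibbs sampling of Bayesian logistic models).  Uses R's RNG so
// draws are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const double TRUNC = 0.64;

// piece-wise series coefficients a_n(x) of the Jacobi theta-type density
inline double a_coef(int n, double x) {
  const double np = n + 0.5;
  if (x > TRUNC)
    return M_PI * np * std::exp(-np * np * M_PI * M_PI * x / 2.0);
  return M_PI * np * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * np * np / x);
}

// CDF of inverse-Gaussian(mu, lambda = 1) at t (mu may be +Inf when z = 0)
inline double pigauss(double t, double z) {
  // parameterized by z = 1/mu; lambda = 1
  const double rt = std::sqrt(t);
  const double a = 1.0 / rt;
  double cdf = R::pnorm(a * (t * z - 1.0), 0.0, 1.0, 1, 0);
  if (z > 0.0)
    cdf += std::exp(2.0 * z) * R::pnorm(-a * (t * z + 1.0), 0.0, 1.0, 1, 0);
  else
    cdf += R::pnorm(-a, 0.0, 1.0, 1, 0);
  return cdf;
}

// inverse-Gaussian(1/z, 1) truncated to (0, TRUNC)
double rtigauss(double z) {
  const double t = TRUNC;
  double x = t + 1.0;
  if (1.0 / z > t || z <= 0.0) { // small tilt: sample 1/chi^2-style then tilt
    while (true) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      const double alpha = std::exp(-0.5 * z * z * x);
      if (unif_rand() <= alpha) break;
    }
  } else {
    const double mu = 1.0 / z;
    while (x > t) {
      double y = norm_rand();
      y = y * y;
      const double muy = mu * y;
      x = mu + 0.5 * mu * muy -
          0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

// one PG(1, z) draw
double pg1_draw(double z) {
  z = std::fabs(z) * 0.5;
  const double t = TRUNC;
  const double K = M_PI * M_PI / 8.0 + z * z / 2.0;
  const double p = (M_PI / (2.0 * K)) * std::exp(-K * t);
  const double q = 2.0 * std::exp(-z) * pigauss(t, z);
  while (true) {
    double x;
    if (unif_rand() < p / (p + q)) {
      x = t + exp_rand() / K; // exponential right tail
    } else {
      x = rtigauss(z); // truncated inverse-Gaussian left part
    }
    double s = a_coef(0, x);
    const double y = unif_rand() * s;
    int n = 0;
    bool accept = false, done = false;
    while (!done) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) { accept = true; done = true; }
      } else {
        s += a_coef(n, x);
        if (y > s) done = true;
      }
      if (n > 1000) { accept = true; done = true; } // numerically converged
    }
    if (accept) return x / 4.0;
  }
}

} // namespace

// [[Rcpp::export]]
NumericVector rpg1_cpp(NumericVector z) {
  const int n = z.size();
  NumericVector out(n);
  GetRNGstate();
  for (int i = 0; i < n; ++i) out[i] = pg1_draw(z[i]);
  PutRNGstate();
  return out;
}
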