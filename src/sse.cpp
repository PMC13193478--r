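// Time-stratified state-dependent speciation-extinction (SSE) likelihood with
// 4 composite states (2 observed x 2 hidden) and a single epoch boundary.
//
// Time runs backward: t = age before present, tips at 0, root at tree height.
// "early" epoch = ages > slice_age, "late" = ages <= slice_age.
//
// Along each branch the standard D/E equations are integrated with an
// embedded Cash-Karp Runge-Kutta 4(5) pair; the epoch boundary is always an
// integration breakpoint. D vectors are rescaled at every node to avoid
// underflow; accumulated log factors are added back at the root.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Rates {
  double lam[4];
  double mu[4];
  double q[4][4];   // off-diagonal instantaneous rates, q[i][j]: i -> j
  double qrow[4];   // row sums of off-diagonal entries
};

inline void deriv(const Rates &r, const double *y, double *dy) {
  const double *E = y;
  const double *D = y + 4;
  for (int i = 0; i < 4; ++i) {
    const double s = r.lam[i] + r.mu[i] + r.qrow[i];
    double qe = 0.0, qd = 0.0;
    for (int j = 0; j < 4; ++j) {
      if (j == i) continue;
      qe += r.q[i][j] * E[j];
      qd += r.q[i][j] * D[j];
    }
    dy[i] = r.mu[i] - s * E[i] + r.lam[i] * E[i] * E[i] + qe;
    dy[4 + i] = -s * D[i] + 2.0 * r.lam[i] * E[i] * D[i] + qd;
  }
}

// Cash-Karp tableau
const double b21 = 1.0 / 5.0;
const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0, b53 = -70.0 / 27.0,
             b54 = 35.0 / 27.0;
const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
             b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
             b65 = 253.0 / 4096.0;
const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
             c6 = 512.0 / 1771.0;
const double dc1 = c1 - 2825.0 / 27648.0, dc3 = c3 - 18575.0 / 48384.0,
             dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0,
             dc6 = c6 - 1.0 / 4.0;

// integrate y over [t0, t1] (t1 > t0) with constant rates; adaptive steps
int integrate_const(const Rates &r, double *y, double t0, double t1,
                    double rtol, double atol, int *clip_count) {
  const int n = 8;
  double t = t0;
  double h = (t1 - t0);
  double k1[8], k2[8], k3[8], k4[8], k5[8], k6[8], ytmp[8], yerr[8], ynew[8];
  int steps = 0;
  const int max_steps = 2000000;
  while (t < t1) {
    if (t + h > t1) h = t1 - t;
    deriv(r, y, k1);
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * b21 * k1[i];
    deriv(r, ytmp, k2);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
    deriv(r, ytmp, k3);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
    deriv(r, ytmp, k4);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] +
                            b54 * k4[i]);
    deriv(r, ytmp, k5);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                            b64 * k4[i] + b65 * k5[i]);
    deriv(r, ytmp, k6);
    double errmax = 0.0;
    for (int i = 0; i < n; ++i) {
      ynew[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
      yerr[i] = h * (dc1 * k1[i] + dc3 * k3[i] + dc4 * k4[i] + dc5 * k5[i] +
                     dc6 * k6[i]);
      const double sk = atol + rtol * std::max(std::fabs(y[i]),
                                               std::fabs(ynew[i]));
      const double e = std::fabs(yerr[i]) / sk;
      if (e > errmax) errmax = e;
    }
    if (errmax <= 1.0) {
      t += h;
      for (int i = 0; i < n; ++i) y[i] = ynew[i];
      // keep solutions in their admissible ranges
      for (int i = 0; i < 4; ++i) {
        if (y[i] < 0.0) y[i] = 0.0;
        if (y[i] > 1.0) y[i] = 1.0;
        if (y[4 + i] < 0.0) { y[4 + i] = 0.0; (*clip_count)++; }
      }
      double fac = 0.9 * std::pow(std::max(errmax, 1e-16), -0.2);
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(errmax, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
    }
    if (h < 1e-14 * std::max(1.0, t1)) return 1;   // step underflow
    if (++steps > max_steps) return 2;             // too many steps
  }
  return 0;
}

Rates make_rates(const NumericMatrix &lambda, const NumericMatrix &mu,
                 const NumericVector &qflat, int epoch) {
  Rates r;
  for (int i = 0; i < 4; ++i) {
    r.lam[i] = lambda(epoch, i);
    r.mu[i] = mu(epoch, i);
    r.qrow[i] = 0.0;
    for (int j = 0; j < 4; ++j) {
      r.q[i][j] = qflat[epoch * 16 + i * 4 + j];
      if (j != i) r.qrow[i] += r.q[i][j];
    }
  }
  return r;
}

} // namespace

// [[Rcpp::export]]
List sse_loglik_cpp(IntegerMatrix edge, int n_tip, NumericVector node_age,
                    IntegerVector tip_state, NumericMatrix lambda,
                    NumericMatrix mu, NumericVector qflat, double slice_age,
                    NumericVector rho, int root_weighting, bool condition_surv,
                    double rtol, double atol) {
  const int n_node = node_age.size();
  const int n_edge = edge.nrow();
  // children lists (1-based node ids in `edge`)
  std::vector<std::vector<int> > kids(n_node);
  std::vector<bool> is_child(n_node, false);
  for (int e = 0; e < n_edge; ++e) {
    kids[edge(e, 0) - 1].push_back(edge(e, 1) - 1);
    is_child[edge(e, 1) - 1] = true;
  }
  int root = -1;
  for (int v = 0; v < n_node; ++v)
    if (!is_child[v] && !kids[v].empty()) { root = v; break; }
  if (root < 0) stop("could not locate root node");

  // explicit postorder over internal nodes
  std::vector<int> order;
  order.reserve(n_node);
  std::vector<int> stack;
  stack.push_back(root);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    for (size_t k = 0; k < kids[v].size(); ++k) stack.push_back(kids[v][k]);
  }
  std::reverse(order.begin(), order.end());

  const Rates early = make_rates(lambda, mu, qflat, 0);
  const Rates late = make_rates(lambda, mu, qflat, 1);

  std::vector<std::array<double, 8> > Y(n_node);
  // tip initial conditions
  for (int i = 0; i < n_tip; ++i) {
    for (int s = 0; s < 4; ++s) {
      const int obs = s & 1;
      Y[i][s] = 1.0 - rho[obs];
      Y[i][4 + s] = (obs == tip_state[i]) ? rho[obs] : 0.0;
    }
  }

  double logscale = 0.0;
  int clip_count = 0;

  for (size_t oi = 0; oi < order.size(); ++oi) {
    const int v = order[oi];
    if (kids[v].empty()) continue;   // tip
    const double t_up = node_age[v];
    double Dacc[4] = {1.0, 1.0, 1.0, 1.0};
    double Eacc[4] = {0.0, 0.0, 0.0, 0.0};
    const int k = (int)kids[v].size();
    for (int ci = 0; ci < k; ++ci) {
      const int c = kids[v][ci];
      double y[8];
      for (int i = 0; i < 8; ++i) y[i] = Y[c][i];
      const double t_lo = node_age[c];
      int code = 0;
      if (t_up > t_lo) {
        if (t_lo < slice_age && t_up > slice_age) {
          code = integrate_const(late, y, t_lo, slice_age, rtol, atol,
                                 &clip_count);
          if (code == 0)
            code = integrate_const(early, y, slice_age, t_up, rtol, atol,
                                   &clip_count);
        } else if (t_up <= slice_age) {
          code = integrate_const(late, y, t_lo, t_up, rtol, atol, &clip_count);
        } else {
          code = integrate_const(early, y, t_lo, t_up, rtol, atol,
                                 &clip_count);
        }
      }
      if (code != 0)
        stop("ODE integration failed on branch above node %d (code %d)",
             c + 1, code);
      for (int s = 0; s < 4; ++s) {
        Dacc[s] *= y[4 + s];
        Eacc[s] += y[s];
      }
    }
    const Rates &rn = (t_up > slice_age) ? early : late;
    double sum = 0.0;
    for (int s = 0; s < 4; ++s) {
      double lpow = 1.0;
      for (int j = 0; j < k - 1; ++j) lpow *= rn.lam[s];
      Y[v][4 + s] = Dacc[s] * lpow;
      Y[v][s] = Eacc[s] / k;
      sum += Y[v][4 + s];
    }
    if (!(sum > 0.0) || !std::isfinite(sum))
      return List::create(_["loglik"] = R_NegInf,
                          _["clip_count"] = clip_count);
    for (int s = 0; s < 4; ++s) Y[v][4 + s] /= sum;
    logscale += std::log(sum);
  }

  // root treatment
  const double t_root = node_age[root];
  const Rates &rr = (t_root > slice_age) ? early : late;
  double w[4];
  double dsum = 0.0;
  for (int s = 0; s < 4; ++s) dsum += Y[root][4 + s];
  for (int s = 0; s < 4; ++s)
    w[s] = (root_weighting == 0) ? 0.25 : Y[root][4 + s] / dsum;
  double lik = 0.0;
  for (int s = 0; s < 4; ++s) {
    double d = Y[root][4 + s];
    if (condition_surv) {
      const double surv = rr.lam[s] * (1.0 - Y[root][s]) * (1.0 - Y[root][s]);
      d = (surv > 0.0) ? d / surv : 0.0;
    }
    lik += w[s] * d;
  }
  double loglik = (lik > 0.0) ? std::log(lik) + logscale : R_NegInf;
  return List::create(_["loglik"] = loglik, _["clip_count"] = clip_count);
}
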