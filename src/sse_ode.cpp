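#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State-dependent speciation-extinction ODE right-hand side for k states.
// y = [E_0..E_{k-1}, D_0..D_{k-1}], time measured from the branch's
// rootward... (tipward end toward the root; the system is autonomous).
//
//   E_i' = mu_i - (lambda_i + mu_i + s_i) E_i + lambda_i E_i^2 + sum_j q_ij E_j
//   D_i' = -(lambda_i + mu_i + s_i) D_i + 2 lambda_i E_i D_i + sum_j q_ij D_j
//
// with s_i = sum_{j != i} q_ij (off-diagonal row sum of Q).
static void sse_deriv(int k, const double *y, double *dy,
                      const double *lambda, const double *mu,
                      const double *Q /* k x k, column-major */) {
  for (int i = 0; i < k; ++i) {
    double s = 0.0, qe = 0.0, qd = 0.0;
    for (int j = 0; j < k; ++j) {
      if (j == i) continue;
      double qij = Q[i + j * k];
      s += qij;
      qe += qij * y[j];
      qd += qij * y[k + j];
    }
    double tot = lambda[i] + mu[i] + s;
    double Ei = y[i], Di = y[k + i];
    dy[i]     = mu[i] - tot * Ei + lambda[i] * Ei * Ei + qe;
    dy[k + i] = -tot * Di + 2.0 * lambda[i] * Ei * Di + qd;
  }
}

// Cash-Karp embedded Runge-Kutta 4(5) step
static void rkck_step(int n, const double *y, const double *dydx, double h,
                      double *yout, double *yerr,
                      const double *lambda, const double *mu, const double *Q,
                      int k, std::vector<double> &work) {
  static const double b21 = 0.2,
    b31 = 3.0 / 40.0, b32 = 9.0 / 40.0,
    b41 = 0.3, b42 = -0.9, b43 = 1.2,
    b51 = -11.0 / 54.0, b52 = 2.5, b53 = -70.0 / 27.0, b54 = 35.0 / 27.0,
    b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0, b63 = 575.0 / 13824.0,
    b64 = 44275.0 / 110592.0, b65 = 253.0 / 4096.0,
    c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
    c6 = 512.0 / 1771.0,
    dc1 = c1 - 2825.0 / 27648.0, dc3 = c3 - 18575.0 / 48384.0,
    dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0,
    dc6 = c6 - 0.25;
  work.resize(6 * n);
  double *ak2 = &work[0], *ak3 = &work[n], *ak4 = &work[2 * n],
         *ak5 = &work[3 * n], *ak6 = &work[4 * n], *ytmp = &work[5 * n];

  for (int i = 0; i < n; ++i) ytmp[i] = y[i] + b21 * h * dydx[i];
  sse_deriv(k, ytmp, ak2, lambda, mu, Q);
  for (int i = 0; i < n; ++i)
    ytmp[i] = y[i] + h * (b31 * dydx[i] + b32 * ak2[i]);
  sse_deriv(k, ytmp, ak3, lambda, mu, Q);
  for (int i = 0; i < n; ++i)
    ytmp[i] = y[i] + h * (b41 * dydx[i] + b42 * ak2[i] + b43 * ak3[i]);
  sse_deriv(k, ytmp, ak4, lambda, mu, Q);
  for (int i = 0; i < n; ++i)
    ytmp[i] = y[i] + h * (b51 * dydx[i] + b52 * ak2[i] + b53 * ak3[i] +
                          b54 * ak4[i]);
  sse_deriv(k, ytmp, ak5, lambda, mu, Q);
  for (int i = 0; i < n; ++i)
    ytmp[i] = y[i] + h * (b61 * dydx[i] + b62 * ak2[i] + b63 * ak3[i] +
                          b64 * ak4[i] + b65 * ak5[i]);
  sse_deriv(k, ytmp, ak6, lambda, mu, Q);
  for (int i = 0; i < n; ++i) {
    yout[i] = y[i] + h * (c1 * dydx[i] + c3 * ak3[i] + c4 * ak4[i] +
                          c6 * ak6[i]);
    yerr[i] = h * (dc1 * dydx[i] + dc3 * ak3[i] + dc4 * ak4[i] +
                   dc5 * ak5[i] + dc6 * ak6[i]);
  }
}

//' Integrate the SSE extinction/data ODE system along one branch
//'
//' Adaptive Cash-Karp Runge-Kutta integration of the k-state
//' speciation-extinction system from time 0 (tipward end) to time t.
//'
//' @param y0 Numeric vector of length 2k: extinction probabilities E then
//'   data partial likelihoods D at the tipward end.
//' @param t Branch length (My).
//' @param lambda,mu Speciation/extinction rates per state.
//' @param Q k x k transition-rate matrix (off-diagonal rates; the diagonal
//'   is ignored).
//' @param rtol,atol Relative/absolute local error tolerances.
//' @return Numeric vector of length 2k at the rootward end.
//' @keywords internal
// [[Rcpp::export]]
NumericVector sse_branch_cpp(NumericVector y0, double t,
                             NumericVector lambda, NumericVector mu,
                             NumericMatrix Q,
                             double rtol = 1e-8, double atol = 1e-10) {
  const int k = lambda.size();
  const int n = 2 * k;
  if (y0.size() != n || mu.size() != k || Q.nrow() != k || Q.ncol() != k)
    stop("sse_branch_cpp: dimension mismatch");
  if (t < 0) stop("sse_branch_cpp: negative branch length");
  std::vector<double> y(y0.begin(), y0.end());
  if (t == 0.0) return y0;

  std::vector<double> dydx(n), yerr(n), ytmp(n), work;
  const double *lam = lambda.begin(), *muv = mu.begin(), *q = Q.begin();

  double x = 0.0;
  double h = t / 10.0;
  const double hmin = t * 1e-14;
  const int max_steps = 100000;
  int steps = 0;

  while (x < t) {
    if (++steps > max_steps)
      stop("sse_branch_cpp: step limit exceeded (stiff branch?)");
    if (x + h > t) h = t - x;
    sse_deriv(k, y.data(), dydx.data(), lam, muv, q);
    for (;;) {
      rkck_step(n, y.data(), dydx.data(), h, ytmp.data(), yerr.data(),
                lam, muv, q, k, work);
      double errmax = 0.0;
      for (int i = 0; i < n; ++i) {
        double sc = atol + rtol * std::max(std::fabs(y[i]),
                                           std::fabs(ytmp[i]));
        double e = std::fabs(yerr[i]) / sc;
        if (e > errmax) errmax = e;
      }
      if (!std::isfinite(errmax))
        stop("sse_branch_cpp: non-finite solution during integration");
      if (errmax <= 1.0) {
        x += h;
        y.assign(ytmp.begin(), ytmp.end());
        double grow = 0.9 * std::pow(std::max(errmax, 1e-10), -0.2);
        h *= std::min(grow, 5.0);
        break;
      }
      h *= std::max(0.9 * std::pow(errmax, -0.25), 0.1);
      if (h < hmin)
        stop("sse_branch_cpp: step size underflow");
    }
  }
  // guard: E must stay within [0,1] up to tolerance
  for (int i = 0; i < k; ++i) {
    if (y[i] < -1e-6 || y[i] > 1.0 + 1e-6)
      stop("sse_branch_cpp: extinction probability left [0,1]");
    if (y[i] < 0.0) y[i] = 0.0;
    if (y[i] > 1.0) y[i] = 1.0;
  }
  return NumericVector(y.begin(), y.end());
}

// Integrate a single branch in place (same stepper as sse_branch_cpp,
// operating on a raw buffer).
static void integrate_branch(double *y, int k, double t,
                             const double *lam, const double *muv,
                             const double *q, double rtol, double atol,
                             std::vector<double> &work6) {
  const int n = 2 * k;
  if (t == 0.0) return;
  std::vector<double> dydx(n), yerr(n), ytmp(n);
  double x = 0.0, h = t / 10.0;
  const double hmin = t * 1e-14;
  int steps = 0;
  while (x < t) {
    if (++steps > 100000)
      stop("SSE integration: step limit exceeded");
    if (x + h > t) h = t - x;
    sse_deriv(k, y, dydx.data(), lam, muv, q);
    for (;;) {
      rkck_step(n, y, dydx.data(), h, ytmp.data(), yerr.data(),
                lam, muv, q, k, work6);
      double errmax = 0.0;
      for (int i = 0; i < n; ++i) {
        double sc = atol + rtol * std::max(std::fabs(y[i]),
                                           std::fabs(ytmp[i]));
        double e = std::fabs(yerr[i]) / sc;
        if (e > errmax) errmax = e;
      }
      if (!std::isfinite(errmax))
        stop("SSE integration: non-finite solution");
      if (errmax <= 1.0) {
        x += h;
        std::copy(ytmp.begin(), ytmp.end(), y);
        h *= std::min(0.9 * std::pow(std::max(errmax, 1e-10), -0.2), 5.0);
        break;
      }
      h *= std::max(0.9 * std::pow(errmax, -0.25), 0.1);
      if (h < hmin) stop("SSE integration: step size underflow");
    }
  }
  for (int i = 0; i < k; ++i) {
    if (y[i] < -1e-6 || y[i] > 1.0 + 1e-6)
      stop("SSE integration: extinction probability left [0,1]");
    y[i] = std::min(std::max(y[i], 0.0), 1.0);
  }
}

//' Full postorder SSE pruning pass
//'
//' Integrates every branch tipward-to-rootward in postorder, combining
//' daughter D vectors at nodes (sequential pairwise, times lambda) with
//' per-node log rescaling of D.
//'
//' @param edge 2-column edge matrix (parent, child; 1-based as in ape).
//' @param edge_length Branch lengths, per edge row.
//' @param postorder Edge row indices (1-based) in postorder.
//' @param tipD k x ntip matrix of tip D initial values.
//' @param lambda,mu,Q Model rates.
//' @param ntip Number of tips.
//' @param rtol,atol ODE tolerances.
//' @return List: root D vector (rescaled), root E vector, log compensation.
//' @keywords internal
// [[Rcpp::export]]
List sse_prune_cpp(IntegerMatrix edge, NumericVector edge_length,
                   IntegerVector postorder, NumericMatrix tipD,
                   NumericVector lambda, NumericVector mu, NumericMatrix Q,
                   int ntip, double rtol = 1e-8, double atol = 1e-10) {
  const int k = lambda.size();
  const int nedge = edge.nrow();
  const int nnode_total = ntip + nedge; // >= tips + internals; safe bound
  const double *lam = lambda.begin(), *muv = mu.begin(), *q = Q.begin();

  // per-node current (E, D) and per-child rootward values
  std::vector<double> E(nnode_total * k, 0.0), D(nnode_total * k, 0.0);
  std::vector<double> upE(nnode_total * k, 0.0), upD(nnode_total * k, 0.0);
  std::vector<int> n_done(nnode_total, 0);
  std::vector<char> combined(nnode_total, 0);
  for (int i = 0; i < ntip; ++i)
    for (int s = 0; s < k; ++s) D[i * k + s] = tipD(s, i);

  // children-combination bookkeeping: count children per parent
  std::vector<int> nchild(nnode_total, 0);
  for (int e = 0; e < nedge; ++e) nchild[edge(e, 0) - 1] += 1;

  double logcomp = 0.0;
  std::vector<double> work6, y(2 * k);

  for (int idx = 0; idx < nedge; ++idx) {
    int e = postorder[idx] - 1;
    int parent = edge(e, 0) - 1, child = edge(e, 1) - 1;
    if (child >= ntip && !combined[child])
      stop("sse_prune_cpp: postorder does not visit children first");
    for (int s = 0; s < k; ++s) {
      y[s] = E[child * k + s];
      y[k + s] = D[child * k + s];
    }
    integrate_branch(y.data(), k, edge_length[e], lam, muv, q,
                     rtol, atol, work6);
    for (int s = 0; s < k; ++s) {
      upE[child * k + s] = y[s];
      upD[child * k + s] = y[k + s];
    }
    // fold this child into the parent's accumulating D
    if (n_done[parent] == 0) {
      for (int s = 0; s < k; ++s) {
        D[parent * k + s] = upD[child * k + s];
        E[parent * k + s] = upE[child * k + s];
      }
    } else {
      for (int s = 0; s < k; ++s)
        D[parent * k + s] *= upD[child * k + s] * lam[s];
    }
    n_done[parent] += 1;
    if (n_done[parent] == nchild[parent]) {
      double ssum = 0.0;
      for (int s = 0; s < k; ++s) ssum += D[parent * k + s];
      if (!std::isfinite(ssum) || ssum <= 0.0)
        stop("sse_prune_cpp: partial likelihood underflow");
      for (int s = 0; s < k; ++s) D[parent * k + s] /= ssum;
      logcomp += std::log(ssum);
      combined[parent] = 1;
    }
  }
  int root = ntip; // ape convention: root node index = ntip + 1 (1-based)
  NumericVector Droot(k), Eroot(k);
  for (int s = 0; s < k; ++s) {
    Droot[s] = D[root * k + s];
    Eroot[s] = E[root * k + s];
  }
  return List::create(_["D"] = Droot, _["E"] = Eroot,
                      _["logcomp"] = logcomp);
}
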