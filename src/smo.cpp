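#include <Rcpp.h>
using namespace Rcpp;

// Two-variable SMO for the binary C-SVC dual on a precomputed linear Gram
// matrix. Problem sizes here are tiny (tens of super-trials), so a maximal
// violating pair working-set strategy converges in a few hundred cheap
// iterations; the feature dimension never enters the solver.
//
// maximize  sum(alpha) - 0.5 * sum_ij alpha_i alpha_j y_i y_j K_ij
// s.t.      0 <= alpha_i <= C,  sum_i alpha_i y_i = 0
//
// Returns alpha and the bias rho (decision: f(x) = sum alpha_i y_i K(x_i,x) - rho),
// matching the libsvm sign convention for y in {+1, -1}.
// [[Rcpp::export(name = ".smo_svc")]]
List smo_svc(NumericMatrix K, NumericVector y, double C,
             double tol = 1e-3, int max_iter = 10000) {
  int n = K.nrow();
  std::vector<double> alpha(n, 0.0);
  // gradient of the dual objective wrt alpha: G_i = y_i * f_int(x_i) - 1
  std::vector<double> G(n, -1.0);

  for (int iter = 0; iter < max_iter; ++iter) {
    // select maximal violating pair (i, j) as in libsvm (working set selection 1)
    int i = -1, j = -1;
    double Gmax = -R_PosInf, Gmin = R_PosInf;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (lo && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < tol) break;

    // joint 2-variable update with box clipping, as in the reference SMO
    double ai = alpha[i], aj = alpha[j];
    // curvature along the feasible direction is the same in both branches:
    // |x_i - x_j|^2 in kernel space
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = 1e-12;
    if (y[i] != y[j]) {
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > 0) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; } }
      else          { if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; } }
    } else {
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; } }
      else         { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; } }
      if (sum > C) { if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; } }
      else         { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; } }
    }

    double ddi = alpha[i] - ai, ddj = alpha[j] - aj;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(t, i) * ddi + y[j] * K(t, j) * ddj);
  }

  // rho from the KKT conditions: average y_i*G_i over free SVs (libsvm rule)
  double rsum = 0.0; int nfree = 0;
  double ub = R_PosInf, lb = -R_PosInf;
  for (int t = 0; t < n; ++t) {
    double yg = y[t] * G[t];
    if (alpha[t] > 0 && alpha[t] < C) { rsum += yg; ++nfree; }
    else if ((y[t] > 0 && alpha[t] == 0) || (y[t] < 0 && alpha[t] == C)) ub = std::min(ub, yg);
    else lb = std::max(lb, yg);
  }
  double rho = nfree > 0 ? rsum / nfree : (ub + lb) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho);
}
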