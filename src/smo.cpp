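#include <Rcpp.h>
using namespace Rcpp;

// SMO-type solver for the soft-margin SVM dual
//
//   max_a W(a) = sum_i a_i - 1/2 sum_ij y_i y_j a_i a_j K_ij
//   s.t. 0 <= a_i <= C,  sum_i a_i y_i = 0
//
// Maximal-violating-pair working-set selection (Keerthi-style): with
// F_i = y_i - f_i, f_i = sum_j a_j y_j K_ij, the pair (argmax_{I_up} F,
// argmin_{I_low} F) is updated analytically until the KKT violation
// max_{I_up} F - min_{I_low} F drops below `tol`. Every pairwise update
// moves along a_i += y_i t, a_j -= y_j t, which preserves the equality
// constraint exactly. The bias is the mean of F over free support vectors
// (0 < a < C), falling back to the midpoint of the KKT interval when none
// is free.
// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double tol = 1e-3, int max_iter = 1000000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n)
    stop("kernel matrix and labels have inconsistent sizes");
  std::vector<double> a(n, 0.0), f(n, 0.0);
  int iter = 0;
  bool converged = false;
  double viol = 0.0;

  while (iter < max_iter) {
    // maximal violating pair
    int i = -1, j = -1;
    double Fup = R_NegInf, Flow = R_PosInf;
    for (int t = 0; t < n; ++t) {
      const double Ft = y[t] - f[t];
      const bool up  = (y[t] > 0) ? (a[t] < C) : (a[t] > 0);
      const bool low = (y[t] > 0) ? (a[t] > 0) : (a[t] < C);
      if (up && Ft > Fup)   { Fup = Ft;  i = t; }
      if (low && Ft < Flow) { Flow = Ft; j = t; }
    }
    if (i < 0 || j < 0) { converged = true; viol = 0.0; break; }
    viol = Fup - Flow;
    if (viol <= tol) { converged = true; break; }

    // analytic step t >= 0 along (a_i += y_i t, a_j -= y_j t)
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta < 1e-12) eta = 1e-12;            // PSD guard for duplicate points
    const double cap_i = (y[i] > 0) ? (C - a[i]) : a[i];
    const double cap_j = (y[j] > 0) ? a[j] : (C - a[j]);
    double step = viol / eta;
    const double tmax = std::min(cap_i, cap_j);
    if (step > tmax) step = tmax;

    a[i] += (y[i] > 0 ? step : -step);
    a[j] -= (y[j] > 0 ? step : -step);
    for (int t = 0; t < n; ++t) f[t] += step * (K(t, i) - K(t, j));
    ++iter;
  }

  // bias from free support vectors, else KKT-interval midpoint
  double bsum = 0.0; int bfree = 0;
  const double bnd = 1e-8 * std::max(C, 1.0);
  for (int t = 0; t < n; ++t)
    if (a[t] > bnd && a[t] < C - bnd) { bsum += y[t] - f[t]; ++bfree; }
  double b;
  if (bfree > 0) b = bsum / bfree;
  else {
    double Fup = R_NegInf, Flow = R_PosInf;
    for (int t = 0; t < n; ++t) {
      const double Ft = y[t] - f[t];
      const bool up  = (y[t] > 0) ? (a[t] < C) : (a[t] > 0);
      const bool low = (y[t] > 0) ? (a[t] > 0) : (a[t] < C);
      if (up && Ft > Fup) Fup = Ft;
      if (low && Ft < Flow) Flow = Ft;
    }
    if (!R_finite(Fup)) Fup = Flow;
    if (!R_finite(Flow)) Flow = Fup;
    b = (Fup + Flow) / 2.0;
  }

  // dual objective W(a) = sum a - 1/2 sum a_i y_i f_i
  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += a[t] - 0.5 * a[t] * y[t] * f[t];

  return List::create(_["alpha"] = NumericVector(a.begin(), a.end()),
                      _["b"] = b,
                      _["objective"] = obj,
                      _["iterations"] = iter,
                      _["kkt_violation"] = viol,
                      _["converged"] = converged);
}
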