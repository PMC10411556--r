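// Sequential minimal optimization for epsilon-insensitive SVR on a
// precomputed kernel, with a single shared bias (one equality constraint).
//
// The dual is handled in the standard 2n-variable form z = (alpha, alpha*),
// labels s = (+1,...,+1, -1,...,-1):
//   min  1/2 * beta' K beta + sum_i z_i * (eps - s_i * y_i)
//   s.t. sum_i s_i z_i = 0,  0 <= z_i <= C,   beta_b = alpha_b - alpha*_b.
// Working pair = maximal KKT-violating pair (first-order selection, the
// second index taken at the opposite extreme so the gradient gap |E_i - E_j|
// is maximal); ties break to the lowest index by strict comparison.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".smo_fit")]]
List smo_fit(const arma::mat& K, const arma::vec& y,
             double C, double eps, double tol, double max_iter) {
  const int n = (int) y.n_elem;
  const int m2 = 2 * n;
  const double TAU = 1e-12;

  // z: first n entries alpha, last n entries alpha_star; all start at 0.
  arma::vec z(m2, arma::fill::zeros);
  // gradient of the minimized objective wrt z; beta = 0 initially.
  arma::vec G(m2);
  for (int i = 0; i < n; ++i) {
    G[i]     = eps - y[i];   // s = +1
    G[i + n] = eps + y[i];   // s = -1
  }

  auto s_of = [n](int i) -> double { return i < n ? 1.0 : -1.0; };
  auto base = [n](int i) -> int { return i < n ? i : i - n; };

  double iter = 0;
  bool converged = false;
  double mval = 0.0, Mval = 0.0;

  while (iter < max_iter) {
    // working-set selection (maximal violating pair)
    int i_sel = -1, j_sel = -1;
    mval = -arma::datum::inf;
    Mval = arma::datum::inf;
    for (int k = 0; k < m2; ++k) {
      const double sk = s_of(k);
      const double v = -sk * G[k];
      const bool in_up  = (sk > 0.0) ? (z[k] < C) : (z[k] > 0.0);
      const bool in_low = (sk > 0.0) ? (z[k] > 0.0) : (z[k] < C);
      if (in_up && v > mval)  { mval = v; i_sel = k; }
      if (in_low && v < Mval) { Mval = v; j_sel = k; }
    }
    if (i_sel < 0 || j_sel < 0 || mval - Mval < tol) { converged = true; break; }

    const int bi = base(i_sel), bj = base(j_sel);
    const double si = s_of(i_sel), sj = s_of(j_sel);

    // one-dimensional subproblem along z_i += si*t, z_j -= sj*t
    double a = K(bi, bi) + K(bj, bj) - 2.0 * K(bi, bj);
    if (a <= 0.0) a = TAU;
    double t = (mval - Mval) / a;  // = -(si*G_i - sj*G_j)/a > 0

    // box limits on t
    double t_hi_i = (si > 0.0) ? (C - z[i_sel]) : z[i_sel];
    double t_hi_j = (sj > 0.0) ? z[j_sel] : (C - z[j_sel]);
    double t_max = std::min(t_hi_i, t_hi_j);
    if (t > t_max) t = t_max;

    z[i_sel] += si * t;
    z[j_sel] -= sj * t;

    // gradient update: d(beta) = t * (e_bi - e_bj)
    for (int k = 0; k < m2; ++k) {
      const int bk = base(k);
      G[k] += s_of(k) * t * (K(bk, bi) - K(bk, bj));
    }
    iter += 1;
  }

  arma::vec beta = z.head(n) - z.tail(n);

  // bias: average over free variables; else midpoint of the violation gap
  double b0 = 0.0;
  int n_free = 0;
  for (int k = 0; k < m2; ++k) {
    if (z[k] > 0.0 && z[k] < C) { b0 += -s_of(k) * G[k]; n_free += 1; }
  }
  if (n_free > 0) b0 /= n_free; else b0 = 0.5 * (mval + Mval);

  // dual objective on the maximization scale of the stacked problem
  arma::vec Kb = K * beta;
  double obj = -0.5 * arma::dot(beta, Kb)
               - eps * arma::accu(z)
               + arma::dot(y, beta);

  return List::create(
    _["beta"] = beta,
    _["b0"] = b0,
    _["objective"] = obj,
    _["iterations"] = iter,
    _["converged"] = converged,
    _["kkt_gap"] = mval - Mval,
    _["fitted_raw"] = Kb + b0);
}
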