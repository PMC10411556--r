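// Conjugate Gibbs samplers for single- and multi-trait Bayesian kernel
// mixed models (GBLUP / RKHS form):
//   ST:  y = 1 mu + u + e,  u ~ N(0, K su2),  e ~ N(0, I se2)
//   MT:  Y = 1 mu' + U_g + E,  vec(U_g) ~ N(0, Sigma_u x K),
//        rows of E ~ N(0, Sigma_e)
// The kernel enters through its eigendecomposition K = V diag(d) V'
// (computed once in R); genetic values are sampled in the eigenbasis where
// components decouple. Missing phenotypes are imputed by data augmentation
// each sweep, which keeps all full conditionals conjugate; augmented records
// carry no external information (they are redrawn from the model).
// All randomness flows through R's RNG so set.seed() governs the chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double rnorm1() { return R::norm_rand(); }

// Wishart(df, S) via Bartlett; returns a draw given chol_S = chol(S, "lower")
static arma::mat rwishart(double df, const arma::mat& chol_S) {
  const int t = (int) chol_S.n_rows;
  arma::mat A(t, t, arma::fill::zeros);
  for (int i = 0; i < t; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = rnorm1();
  }
  arma::mat LA = chol_S * A;
  return LA * LA.t();
}

// inverse-Wishart(scale, df)
static arma::mat rinvwishart(double df, const arma::mat& scale) {
  arma::mat S_inv = arma::inv_sympd(arma::symmatu(scale));
  arma::mat cl = arma::chol(arma::symmatu(S_inv), "lower");
  arma::mat W = rwishart(df, cl);
  return arma::inv_sympd(arma::symmatu(W));
}

// [[Rcpp::export(name = ".gibbs_st")]]
List gibbs_st(const arma::mat& V, const arma::vec& d, const arma::vec& y_in,
              const arma::uvec& miss, double m_mu,
              double Su, double dfu, double Se, double dfe,
              int n_iter, int burn_in, int thin,
              bool fix_var, double su2_fix, double se2_fix) {
  const int N = (int) y_in.n_elem;
  const double dtol = 1e-8 * d.max();
  arma::uvec keep = arma::find(d > dtol);
  const int rk = (int) keep.n_elem;

  arma::vec y = y_in;
  arma::uvec obs = arma::find(miss == 0);
  double mu = arma::mean(y.elem(obs));
  y.elem(arma::find(miss == 1)).fill(mu);

  double vy = arma::var(y.elem(obs));
  double su2 = fix_var ? su2_fix : 0.5 * vy;
  double se2 = fix_var ? se2_fix : 0.5 * vy;

  arma::vec u(N, arma::fill::zeros);
  arma::vec ustar(N, arma::fill::zeros);

  const int n_draw = (n_iter - burn_in) / thin;
  arma::vec mu_d(n_draw), su_d(n_draw), se_d(n_draw);
  arma::vec u_mean(N, arma::fill::zeros);
  int stored = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // augment missing records
    for (int i = 0; i < N; ++i)
      if (miss[i] == 1) y[i] = mu + u[i] + std::sqrt(se2) * rnorm1();

    // intercept
    {
      double prec = N / se2 + 1.0 / m_mu;
      double mean = arma::accu(y - u) / se2 / prec;
      mu = mean + rnorm1() / std::sqrt(prec);
    }

    // genetic values in the eigenbasis
    arma::vec rstar = V.t() * (y - mu);
    ustar.zeros();
    for (int k = 0; k < rk; ++k) {
      const int j = (int) keep[k];
      double prec = 1.0 / (d[j] * su2) + 1.0 / se2;
      double mean = rstar[j] / se2 / prec;
      ustar[j] = mean + rnorm1() / std::sqrt(prec);
    }
    u = V * ustar;

    if (!fix_var) {
      double ssu = 0.0;
      for (int k = 0; k < rk; ++k) {
        const int j = (int) keep[k];
        ssu += ustar[j] * ustar[j] / d[j];
      }
      su2 = (Su * dfu + ssu) / R::rchisq(dfu + rk);
      arma::vec e = y - mu - u;
      se2 = (Se * dfe + arma::dot(e, e)) / R::rchisq(dfe + N);
    }

    if (it > burn_in && (it - burn_in) % thin == 0) {
      mu_d[stored] = mu; su_d[stored] = su2; se_d[stored] = se2;
      u_mean += u;
      stored += 1;
    }
  }
  if (stored > 0) u_mean /= stored;

  return List::create(_["mu"] = mu_d, _["sigma2_u"] = su_d,
                      _["sigma2_e"] = se_d, _["u_mean"] = u_mean,
                      _["n_draws"] = stored);
}

// [[Rcpp::export(name = ".gibbs_mt")]]
List gibbs_mt(const arma::mat& V, const arma::vec& d, const arma::mat& Y_in,
              const arma::umat& miss, double m_mu,
              const arma::mat& Su_prior, double dfu,
              const arma::mat& Se_prior, double dfe,
              int n_iter, int burn_in, int thin,
              bool fix_var, const arma::mat& Su_fix, const arma::mat& Se_fix) {
  const int N = (int) Y_in.n_rows;
  const int t = (int) Y_in.n_cols;
  const double dtol = 1e-8 * d.max();
  arma::uvec keep = arma::find(d > dtol);
  const int rk = (int) keep.n_elem;

  arma::mat Y = Y_in;
  arma::vec mu(t);
  for (int k = 0; k < t; ++k) {
    arma::uvec ok = arma::find(miss.col(k) == 0);
    mu[k] = arma::mean(Y.col(k).eval().elem(ok));
    for (int i = 0; i < N; ++i) if (miss(i, k) == 1) Y(i, k) = mu[k];
  }

  arma::mat Su = fix_var ? Su_fix : Su_prior;
  arma::mat Se = fix_var ? Se_fix : Se_prior;
  arma::mat Ug(N, t, arma::fill::zeros);
  arma::mat Ustar(N, t, arma::fill::zeros);

  const int n_draw = (n_iter - burn_in) / thin;
  arma::mat mu_d(n_draw, t), su_d(n_draw, t * t), se_d(n_draw, t * t);
  arma::mat U_mean(N, t, arma::fill::zeros);
  int stored = 0;

  // which individuals have any missing record (augmentation targets)
  std::vector<int> aug_rows;
  for (int i = 0; i < N; ++i)
    if (arma::accu(miss.row(i)) > 0) aug_rows.push_back(i);

  for (int it = 1; it <= n_iter; ++it) {
    arma::mat Se_inv = arma::inv_sympd(arma::symmatu(Se));
    arma::mat Su_inv = arma::inv_sympd(arma::symmatu(Su));

    // augment missing records from the conditional given observed traits
    for (int i : aug_rows) {
      arma::uvec M = arma::find(miss.row(i).t() == 1);
      arma::uvec O = arma::find(miss.row(i).t() == 0);
      arma::vec cmean(M.n_elem);
      arma::mat cvar;
      if (O.n_elem == 0) {
        for (arma::uword a = 0; a < M.n_elem; ++a)
          cmean[a] = mu[M[a]] + Ug(i, M[a]);
        cvar = Se.submat(M, M);
      } else {
        arma::vec rO(O.n_elem);
        for (arma::uword a = 0; a < O.n_elem; ++a)
          rO[a] = Y(i, O[a]) - mu[O[a]] - Ug(i, O[a]);
        arma::mat SOO_inv = arma::inv_sympd(arma::symmatu(Se.submat(O, O)));
        arma::mat SMO = Se.submat(M, O);
        arma::vec adj = SMO * SOO_inv * rO;
        for (arma::uword a = 0; a < M.n_elem; ++a)
          cmean[a] = mu[M[a]] + Ug(i, M[a]) + adj[a];
        cvar = Se.submat(M, M) - SMO * SOO_inv * SMO.t();
      }
      arma::mat cl = arma::chol(arma::symmatu(cvar) +
                                1e-12 * arma::eye(M.n_elem, M.n_elem), "lower");
      arma::vec zz(M.n_elem);
      for (arma::uword a = 0; a < M.n_elem; ++a) zz[a] = rnorm1();
      arma::vec draw = cmean + cl * zz;
      for (arma::uword a = 0; a < M.n_elem; ++a) Y(i, M[a]) = draw[a];
    }

    // intercepts (joint across traits)
    {
      arma::mat P = N * Se_inv + (1.0 / m_mu) * arma::eye(t, t);
      arma::vec rhs = Se_inv * arma::sum(Y - Ug, 0).t();
      arma::mat Pc = arma::inv_sympd(arma::symmatu(P));
      arma::vec mean = Pc * rhs;
      arma::mat cl = arma::chol(arma::symmatu(Pc), "lower");
      arma::vec zz(t);
      for (int k = 0; k < t; ++k) zz[k] = rnorm1();
      mu = mean + cl * zz;
    }

    // genetic values in the eigenbasis: rows decouple
    arma::mat R = Y;
    R.each_row() -= mu.t();
    arma::mat Rstar = V.t() * R;
    Ustar.zeros();
    for (int kk = 0; kk < rk; ++kk) {
      const int j = (int) keep[kk];
      arma::mat Pj = Su_inv / d[j] + Se_inv;
      arma::mat Vj = arma::inv_sympd(arma::symmatu(Pj));
      arma::vec mean = Vj * (Se_inv * Rstar.row(j).t());
      arma::mat cl = arma::chol(arma::symmatu(Vj), "lower");
      arma::vec zz(t);
      for (int k = 0; k < t; ++k) zz[k] = rnorm1();
      Ustar.row(j) = (mean + cl * zz).t();
    }
    Ug = V * Ustar;

    if (!fix_var) {
      arma::mat Sg(t, t, arma::fill::zeros);
      for (int kk = 0; kk < rk; ++kk) {
        const int j = (int) keep[kk];
        Sg += Ustar.row(j).t() * Ustar.row(j) / d[j];
      }
      Su = rinvwishart(dfu + rk, Su_prior + Sg);
      arma::mat E = R - Ug;
      Se = rinvwishart(dfe + N, Se_prior + E.t() * E);
    }

    if (it > burn_in && (it - burn_in) % thin == 0) {
      mu_d.row(stored) = mu.t();
      su_d.row(stored) = arma::vectorise(Su).t();
      se_d.row(stored) = arma::vectorise(Se).t();
      U_mean += Ug;
      stored += 1;
    }
  }
  if (stored > 0) U_mean /= stored;

  return List::create(_["mu"] = mu_d, _["Sigma_u"] = su_d,
                      _["Sigma_e"] = se_d, _["U_mean"] = U_mean,
                      _["n_draws"] = stored);
}
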