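// Gibbs sampler for the multivariate probit JSDM and the GHK
// orthant-probability simulator.  All randomness comes from R's own RNG
// (unif_rand / norm_rand and friends) so that results are reproducible
// from set.seed() on the R side; the order in which variates are consumed
// is fixed (column-major over taxa, sites ascending).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Draw from a univariate normal truncated to (0, Inf) when positive,
// (-Inf, 0] otherwise, by inversion.  Guards keep the draw on the correct
// side of zero in extreme tails (z = 0 counts as absence).
static double rtnorm0(double mean, double sd, bool positive) {
  double plo = R::pnorm(0.0, mean, sd, 1, 0); // P(z <= 0)
  double u = unif_rand();
  double p;
  if (positive) {
    p = plo + u * (1.0 - plo);
    if (p >= 1.0) p = 1.0 - 1e-16;
    if (p <= plo) p = plo + (1.0 - plo) * 1e-16;
  } else {
    p = u * plo;
    if (p <= 0.0) p = std::min(plo, 1e-300);
  }
  double z = R::qnorm(p, mean, sd, 1, 0);
  if (positive && !(z > 0.0)) z = 1e-10;
  if (!positive && z > 0.0) z = 0.0;
  return z;
}

// One full sweep of the latent-variable update.  Taxa are visited in index
// order; because sites are mutually independent given (B, R), updating all
// sites of taxon j at once is the same conditioning as the per-site sweep.
static void latent_sweep(arma::mat& Z, const arma::imat& Y,
                         const arma::mat& Mu, const arma::mat& Omega) {
  const arma::uword n = Z.n_rows, T = Z.n_cols;
  for (arma::uword j = 0; j < T; ++j) {
    const double ojj = Omega(j, j);
    const double csd = std::sqrt(1.0 / ojj);
    arma::vec w = Omega.col(j);
    w(j) = 0.0;
    arma::vec cmean = Mu.col(j) - ((Z - Mu) * w) / ojj;
    for (arma::uword i = 0; i < n; ++i)
      Z(i, j) = rtnorm0(cmean(i), csd, Y(i, j) == 1);
  }
}

// Full-conditional moments of the stacked included coefficients (SUR form).
// Returns the posterior precision (dense, q x q) and mean.
static void coef_moments(const arma::mat& Z, const arma::mat& X,
                         const arma::mat& XtX, const arma::mat& Omega,
                         const std::vector<arma::uvec>& idx,
                         double prior_prec,
                         arma::mat& P, arma::vec& m) {
  const arma::uword T = Z.n_cols;
  arma::uword q = 0;
  std::vector<arma::uword> off(T);
  for (arma::uword j = 0; j < T; ++j) { off[j] = q; q += idx[j].n_elem; }
  P.zeros(q, q);
  arma::vec rhs(q, arma::fill::zeros);
  arma::mat G = X.t() * (Z * Omega); // K x T
  for (arma::uword j = 0; j < T; ++j) {
    for (arma::uword k = 0; k < T; ++k) {
      if (Omega(j, k) == 0.0 && j != k) continue;
      arma::mat block = Omega(j, k) * XtX.submat(idx[j], idx[k]);
      P.submat(off[j], off[k], off[j] + idx[j].n_elem - 1,
               off[k] + idx[k].n_elem - 1) += block;
    }
    arma::vec gj = G.col(j);
    rhs.subvec(off[j], off[j] + idx[j].n_elem - 1) = gj.elem(idx[j]);
  }
  P.diag() += prior_prec;
  m = arma::solve(P, rhs, arma::solve_opts::likely_sympd);
}

// Draw B from its full conditional; structural zeros are preserved by
// only sampling the included entries.
static arma::mat coef_draw(const arma::mat& Z, const arma::mat& X,
                           const arma::mat& XtX, const arma::mat& Omega,
                           const std::vector<arma::uvec>& idx,
                           double prior_prec, arma::uword K) {
  const arma::uword T = Z.n_cols;
  arma::mat P; arma::vec m;
  coef_moments(Z, X, XtX, Omega, idx, prior_prec, P, m);
  arma::mat U = arma::chol(P); // upper: U'U = P
  arma::vec v(m.n_elem);
  for (arma::uword i = 0; i < v.n_elem; ++i) v(i) = norm_rand();
  arma::vec beta = m + arma::solve(arma::trimatu(U), v);
  arma::mat B(K, T, arma::fill::zeros);
  arma::uword pos = 0;
  for (arma::uword j = 0; j < T; ++j)
    for (arma::uword r = 0; r < idx[j].n_elem; ++r)
      B(idx[j](r), j) = beta(pos++);
  return B;
}

// Wishart(df, S) via Bartlett decomposition (fixed column-major RNG order).
static arma::mat rwishart(double df, const arma::mat& S) {
  const arma::uword p = S.n_rows;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (arma::uword j = 0; j < p; ++j) {
    A(j, j) = std::sqrt(R::rchisq(df - (double)j));
    for (arma::uword i = j + 1; i < p; ++i) A(i, j) = norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// Parameter-expanded correlation update: draw an unconstrained covariance
// from IW(nu0 + n, S0 + E'E) and rescale to a correlation matrix.  The
// matching latent/coefficient rescaling (columns divided by d) is applied
// by the caller.
static void corr_draw(const arma::mat& E, double nu0, arma::mat& Rout,
                      arma::vec& dout) {
  const arma::uword T = E.n_cols;
  arma::mat S = arma::eye(T, T) + E.t() * E;
  double df = nu0 + (double)E.n_rows;
  arma::mat W = rwishart(df, arma::inv_sympd(S)); // Sigma^{-1}
  arma::mat Sigma = arma::inv_sympd(W);
  arma::vec d = arma::sqrt(Sigma.diag());
  Rout = Sigma / (d * d.t());
  Rout.diag().ones();
  Rout = arma::symmatu(Rout);
  dout = d;
}

static std::vector<arma::uvec> mask_index(const arma::umat& mask) {
  std::vector<arma::uvec> idx(mask.n_cols);
  for (arma::uword j = 0; j < mask.n_cols; ++j)
    idx[j] = arma::find(mask.col(j) == 1);
  return idx;
}

// [[Rcpp::export(name = ".latent_sweep_cpp")]]
arma::mat latent_sweep_cpp(const arma::imat& Y, const arma::mat& Mu,
                           const arma::mat& R, const arma::mat& Z0) {
  arma::mat Z = Z0;
  arma::mat Omega = arma::inv_sympd(R);
  latent_sweep(Z, Y, Mu, Omega);
  return Z;
}

// [[Rcpp::export(name = ".coef_draw_cpp")]]
arma::mat coef_draw_cpp(const arma::mat& Z, const arma::mat& X,
                        const arma::mat& R, const arma::umat& mask,
                        double prior_prec) {
  arma::mat XtX = X.t() * X;
  arma::mat Omega = arma::inv_sympd(R);
  std::vector<arma::uvec> idx = mask_index(mask);
  return coef_draw(Z, X, XtX, Omega, idx, prior_prec, X.n_cols);
}

// [[Rcpp::export(name = ".coef_moments_cpp")]]
Rcpp::List coef_moments_cpp(const arma::mat& Z, const arma::mat& X,
                            const arma::mat& R, const arma::umat& mask,
                            double prior_prec) {
  arma::mat XtX = X.t() * X;
  arma::mat Omega = arma::inv_sympd(R);
  std::vector<arma::uvec> idx = mask_index(mask);
  arma::mat P; arma::vec m;
  coef_moments(Z, X, XtX, Omega, idx, prior_prec, P, m);
  arma::mat Bmean(X.n_cols, Z.n_cols, arma::fill::zeros);
  arma::uword pos = 0;
  for (arma::uword j = 0; j < Z.n_cols; ++j)
    for (arma::uword r = 0; r < idx[j].n_elem; ++r)
      Bmean(idx[j](r), j) = m(pos++);
  return Rcpp::List::create(Rcpp::Named("mean") = Bmean,
                            Rcpp::Named("precision") = P);
}

// [[Rcpp::export(name = ".corr_draw_cpp")]]
Rcpp::List corr_draw_cpp(const arma::mat& E, double nu0) {
  arma::mat R; arma::vec d;
  corr_draw(E, nu0, R, d);
  return Rcpp::List::create(Rcpp::Named("R") = R, Rcpp::Named("d") = d);
}

// [[Rcpp::export(name = ".gibbs_chain_cpp")]]
Rcpp::List gibbs_chain_cpp(const arma::imat& Y, const arma::mat& X,
                           const arma::umat& mask, bool estimate_R,
                           int n_iter, int n_burn, int thin,
                           double prior_prec, double nu0) {
  const arma::uword n = Y.n_rows, T = Y.n_cols, K = X.n_cols;
  arma::mat XtX = X.t() * X;
  std::vector<arma::uvec> idx = mask_index(mask);

  arma::mat B(K, T, arma::fill::zeros);
  arma::mat R = arma::eye(T, T);
  arma::mat Omega = arma::eye(T, T);
  arma::mat Z(n, T, arma::fill::zeros);
  arma::mat Mu(n, T, arma::fill::zeros);
  latent_sweep(Z, Y, Mu, Omega); // initialise latents at B = 0, R = I

  int n_keep = (n_iter - n_burn) / thin;
  arma::cube Bdraws(K, T, n_keep);
  arma::cube Rdraws(estimate_R ? T : 0, estimate_R ? T : 0,
                    estimate_R ? n_keep : 0);

  int kept = 0;
  for (int it = 1; it <= n_iter; ++it) {
    Mu = X * B;
    latent_sweep(Z, Y, Mu, Omega);
    B = coef_draw(Z, X, XtX, Omega, idx, prior_prec, K);
    if (estimate_R) {
      arma::mat E = Z - X * B;
      arma::vec d;
      corr_draw(E, nu0, R, d);
      Omega = arma::inv_sympd(R);
      // contract latents and coefficients back to the correlation scale
      for (arma::uword j = 0; j < T; ++j) {
        Z.col(j) /= d(j);
        B.col(j) /= d(j);
      }
    }
    if (it > n_burn && (it - n_burn) % thin == 0 && kept < n_keep) {
      Bdraws.slice(kept) = B;
      if (estimate_R) Rdraws.slice(kept) = R;
      ++kept;
    }
  }
  return Rcpp::List::create(Rcpp::Named("B") = Bdraws,
                            Rcpp::Named("R") = Rdraws);
}

// --- GHK simulator -------------------------------------------------------

// One-site GHK estimate of P(sign pattern y) for MVN(mu, R) with L the
// lower Cholesky factor of R.  Antithetic pairs (u, 1 - u) are used when
// requested; M is the total number of replicates.
static double ghk_site(const arma::vec& mu, const arma::mat& L,
                       const arma::ivec& y, int M, bool antithetic) {
  const arma::uword T = mu.n_elem;
  arma::vec eta(T), ucur(T);
  double acc = 0.0;
  for (int m = 0; m < M; ++m) {
    double w = 1.0;
    bool anti = antithetic && (m % 2 == 1);
    for (arma::uword j = 0; j < T; ++j) {
      double c = mu(j);
      for (arma::uword k = 0; k < j; ++k) c += L(j, k) * eta(k);
      double a = -c / L(j, j);
      double u = anti ? (1.0 - ucur(j)) : unif_rand();
      if (!anti) ucur(j) = u;
      double Fa = R::pnorm(a, 0.0, 1.0, 1, 0);
      double pj, p;
      if (y(j) == 1) {
        pj = 1.0 - Fa;
        p = Fa + u * pj;
      } else {
        pj = Fa;
        p = u * Fa;
      }
      if (pj <= 0.0) { w = 0.0; break; }
      if (p >= 1.0) p = 1.0 - 1e-16;
      if (p <= 0.0) p = 1e-300;
      eta(j) = R::qnorm(p, 0.0, 1.0, 1, 0);
      w *= pj;
    }
    acc += w;
  }
  return acc / (double)M;
}

// [[Rcpp::export(name = ".ghk_orthant_cpp")]]
double ghk_orthant_cpp(const arma::vec& mu, const arma::mat& R,
                       const arma::ivec& y, int M, bool antithetic) {
  arma::mat L = arma::chol(R, "lower");
  return ghk_site(mu, L, y, M, antithetic);
}

// Joint deviance -2 * sum_i log P(y_i | mu_i, R) by GHK.
// [[Rcpp::export(name = ".ghk_deviance_cpp")]]
double ghk_deviance_cpp(const arma::mat& Mu, const arma::mat& R,
                        const arma::imat& Y, int M, bool antithetic) {
  arma::mat L = arma::chol(R, "lower");
  double dev = 0.0;
  for (arma::uword i = 0; i < Y.n_rows; ++i) {
    double p = ghk_site(Mu.row(i).t(), L, Y.row(i).t(), M, antithetic);
    if (p < 1e-300) p = 1e-300;
    dev += -2.0 * std::log(p);
  }
  return dev;
}

// Per-taxon conditional deviance: -2 sum_i log P(y_ij | y_{i,-j}) with
// P(y_ij | y_{i,-j}) = P(y_i) / P(y_{i,-j}); both orthant probabilities
// estimated by GHK.
// [[Rcpp::export(name = ".ghk_pertaxon_cpp")]]
arma::vec ghk_pertaxon_cpp(const arma::mat& Mu, const arma::mat& R,
                           const arma::imat& Y, int M, bool antithetic) {
  const arma::uword T = Y.n_cols;
  arma::mat L = arma::chol(R, "lower");
  std::vector<arma::mat> Lsub(T);
  std::vector<arma::uvec> keep(T);
  for (arma::uword j = 0; j < T; ++j) {
    arma::uvec k(T - 1);
    arma::uword pos = 0;
    for (arma::uword t = 0; t < T; ++t) if (t != j) k(pos++) = t;
    keep[j] = k;
    Lsub[j] = arma::chol(R.submat(k, k), "lower");
  }
  arma::vec dev(T, arma::fill::zeros);
  for (arma::uword i = 0; i < Y.n_rows; ++i) {
    arma::vec mu = Mu.row(i).t();
    arma::ivec y = Y.row(i).t();
    double pj = ghk_site(mu, L, y, M, antithetic);
    if (pj < 1e-300) pj = 1e-300;
    for (arma::uword j = 0; j < T; ++j) {
      arma::vec mum = mu.elem(keep[j]);
      arma::ivec ym = y.elem(keep[j]);
      double pm = ghk_site(mum, Lsub[j], ym, M, antithetic);
      if (pm < 1e-300) pm = 1e-300;
      double pcond = pj / pm;
      if (pcond < 1e-300) pcond = 1e-300;
      dev(j) += -2.0 * std::log(pcond);
    }
  }
  return dev;
}
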