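// Gibbs kernels for the pseudo-posterior sampler and the FCS imputation
// sweep.  Conventions match the 0/1-coded Ising model: the conditional
// log-odds of item j is s_jj/2 + sum_{k != j} s_jk y_k, so design rows carry
// the constant 1/2 on the own-item (diagonal) coordinate.
//
// All randomness is drawn from R's RNG (RNGScope via Rcpp attributes), in a
// fixed order: augmentation variables in row order, then the Gaussian draw,
// then (for sweeps) imputation uniforms in row order.  The R wrappers rely
// on this order being identical between the composed single-step functions
// and the fused sweep.
//
// cpp_fcs_sweep_inplace mutates its y/betas arguments; the R callers pass
// matrices they own exclusively (duplicated beforehand when needed).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

double rpg1(double c);  // pg_sampler.cpp

// 0-based position of s_{rc} (r >= c) in vech order (s11,...,sJ1,s22,...)
static inline int vech_index(int r, int c, int J) {
  if (r < c) std::swap(r, c);
  return c * J - c * (c - 1) / 2 + (r - c);
}

static inline double logistic(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// Draw from N(mu, P^{-1}) where P * mu = lin; 'what' names the caller for
// the diagnostic raised if the Cholesky factorization fails.
static arma::vec mvn_precision_draw(const arma::mat& P, const arma::vec& lin,
                                    const char* what) {
  arma::mat R_;
  if (!arma::chol(R_, P))
    stop("Cholesky factorization of the precision matrix failed in %s", what);
  arma::vec mu = arma::solve(P, lin, arma::solve_opts::likely_sympd);
  arma::vec z(P.n_rows);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = R::norm_rand();
  return mu + arma::solve(arma::trimatu(R_), z);
}

// One Polya-Gamma sweep of a Bayesian logistic regression: augment, then
// draw the coefficient vector from its Gaussian full conditional.
// [[Rcpp::export]]
arma::vec cpp_pg_logistic_update(const arma::mat& X, const arma::vec& u,
                                 const arma::vec& prior_mean,
                                 const arma::vec& prior_var,
                                 const arma::vec& beta) {
  int n = X.n_rows;
  arma::mat P = arma::diagmat(1.0 / prior_var);
  arma::vec lin = prior_mean / prior_var;
  if (n > 0) {
    arma::vec eta = X * beta;
    for (int i = 0; i < n; ++i) {
      double om = rpg1(eta(i));
      P += om * (X.row(i).t() * X.row(i));
      lin += (u(i) - 0.5) * X.row(i).t();
    }
  }
  return mvn_precision_draw(P, lin, "the logistic coefficient update");
}

// beta update for one item on a fully imputed matrix (in-place on betas);
// hot loop: accumulates the lower triangle of X'OmegaX without temporaries
static void beta_step(const IntegerMatrix& y, NumericMatrix& betas, int j,
                      double pv_intercept, double pv_slope) {
  int N = y.nrow(), J = y.ncol();
  std::vector<double> x(J);
  arma::vec lin(J, arma::fill::zeros);
  arma::mat P(J, J, arma::fill::zeros);
  std::vector<double> bj(J);
  for (int k = 0; k < J; ++k) bj[k] = betas(j, k);
  for (int i = 0; i < N; ++i) {
    double eta = 0.5 * bj[j];
    for (int k = 0; k < J; ++k) {
      if (k == j) { x[k] = 0.5; continue; }
      x[k] = y(i, k);
      if (x[k] != 0.0) eta += bj[k];
    }
    double om = rpg1(eta);
    double kap = y(i, j) - 0.5;
    for (int a = 0; a < J; ++a) {
      double xa = x[a];
      if (xa == 0.0) continue;
      lin(a) += kap * xa;
      double oxa = om * xa;
      for (int b = 0; b <= a; ++b)
        if (x[b] != 0.0) P(a, b) += oxa * x[b];
    }
  }
  P = arma::symmatl(P);
  for (int k = 0; k < J; ++k)
    P(k, k) += 1.0 / (k == j ? pv_intercept : pv_slope);
  arma::vec bnew =
      mvn_precision_draw(P, lin, "the auxiliary-coefficient update");
  for (int k = 0; k < J; ++k) betas(j, k) = bnew(k);
}

// redraw the missing cells of column j from Bernoulli(logistic(eta))
static void impute_step(IntegerMatrix& y, const IntegerMatrix& mask,
                        const NumericMatrix& betas, int j) {
  int N = y.nrow(), J = y.ncol();
  for (int i = 0; i < N; ++i) {
    if (mask(i, j)) continue;  // observed cells are never touched
    double eta = 0.5 * betas(j, j);
    for (int k = 0; k < J; ++k)
      if (k != j && y(i, k)) eta += betas(j, k);
    y(i, j) = (R::unif_rand() < logistic(eta)) ? 1 : 0;
  }
}

// One full-conditional-specification sweep, mutating y and betas in place:
// for each item in 'order' (0-based), refresh its auxiliary logistic
// coefficients, then redraw its missing cells given the most recent values
// of all other items.
// [[Rcpp::export]]
void cpp_fcs_sweep_inplace(IntegerMatrix y, const IntegerMatrix& mask,
                           NumericMatrix betas, const IntegerVector& order,
                           double pv_intercept, double pv_slope) {
  for (int s = 0; s < order.size(); ++s) {
    int j = order[s];
    beta_step(y, betas, j, pv_intercept, pv_slope);
    impute_step(y, mask, betas, j);
  }
}

// Joint update of alpha = vech(S) from the pseudo-posterior: one PG sweep
// over the N*J stacked pseudo-observations (row order: observation-major,
// item within observation), streaming X'OmegaX without materializing the
// N*J x J(J+1)/2 design.
// [[Rcpp::export]]
arma::vec cpp_sample_alpha(const IntegerMatrix& y, const arma::vec& alpha,
                           const arma::vec& prior_mean,
                           const arma::vec& prior_var) {
  int N = y.nrow(), J = y.ncol();
  int M = J * (J + 1) / 2;
  if ((int)alpha.n_elem != M)
    stop("alpha has length %d; expected J(J+1)/2 = %d", alpha.n_elem, M);
  // unvech into S for linear predictors
  arma::mat S(J, J);
  for (int c = 0; c < J; ++c)
    for (int r = c; r < J; ++r)
      S(r, c) = S(c, r) = alpha(vech_index(r, c, J));

  arma::mat P = arma::diagmat(1.0 / prior_var);
  arma::vec lin = prior_mean / prior_var;
  std::vector<int> idx(J);
  std::vector<double> coef(J);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < J; ++j) {
      double eta = 0.5 * S(j, j);
      int nz = 0;
      idx[nz] = vech_index(j, j, J);
      coef[nz++] = 0.5;
      for (int k = 0; k < J; ++k) {
        if (k == j || !y(i, k)) continue;
        eta += S(j, k);
        idx[nz] = vech_index(j, k, J);
        coef[nz++] = 1.0;
      }
      double om = rpg1(eta);
      double kap = y(i, j) - 0.5;
      for (int a = 0; a < nz; ++a) {
        lin(idx[a]) += kap * coef[a];
        double oca = om * coef[a];
        for (int b = 0; b < nz; ++b)
          P(idx[a], idx[b]) += oca * coef[b];
      }
    }
  }
  return mvn_precision_draw(P, lin, "the joint vech(S) update");
}

// Systematic-scan Gibbs sampler for the Ising model itself (fallback for
// J too large to enumerate).  Returns n retained rows after 'burnin' full
// scans, keeping every 'thin'-th scan.
// [[Rcpp::export]]
IntegerMatrix cpp_ising_gibbs(const arma::mat& S, int n, int burnin, int thin) {
  int J = S.n_cols;
  IntegerMatrix out(n, J);
  arma::ivec y(J);
  for (int k = 0; k < J; ++k) y(k) = (R::unif_rand() < 0.5) ? 1 : 0;
  auto scan = [&]() {
    for (int j = 0; j < J; ++j) {
      double eta = 0.5 * S(j, j);
      for (int k = 0; k < J; ++k)
        if (k != j && y(k)) eta += S(j, k);
      y(j) = (R::unif_rand() < logistic(eta)) ? 1 : 0;
    }
  };
  for (int b = 0; b < burnin; ++b) scan();
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < thin; ++t) scan();
    for (int k = 0; k < J; ++k) out(i, k) = y(k);
  }
  return out;
}
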