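// Gibbs sampler for the normal linear mixed model with bounded uniform
// priors on fixed effects and variance components, and a single
// animal-level random intercept:
//   y = X beta + Z u + e,  u ~ N(0, var_a I),  e ~ N(0, var_e I)
// Full conditionals: each beta_j is normal truncated to its prior bounds
// (inverse-CDF draw); u_i is normal (normal prior, no truncation);
// variances are inverse-gamma truncated to their bounds. Uses R's RNG so
// chains are reproducible through set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static double rtnorm(double m, double s, double lo, double hi) {
  double plo = R::pnorm(lo, m, s, 1, 0);
  double phi = R::pnorm(hi, m, s, 1, 0);
  if (phi - plo < 1e-14)
    Rcpp::stop("truncation region holds no posterior mass; widen the prior bounds");
  double u = plo + R::unif_rand() * (phi - plo);
  double x = R::qnorm(u, m, s, 1, 0);
  if (x < lo) x = lo;
  if (x > hi) x = hi;
  return x;
}

// sigma2 ~ InvGamma(shape, rate) restricted to [lo, hi]; drawn through
// the Gamma(shape, rate) distribution of 1/sigma2 by inverse CDF.
static double rtinvgamma(double shape, double rate, double lo, double hi) {
  double glo = 1.0 / hi;
  bool hi_finite = lo > 0.0;
  double ghi = hi_finite ? 1.0 / lo : 0.0;
  double scale = 1.0 / rate;
  double plo = R::pgamma(glo, shape, scale, 1, 0);
  double phi = hi_finite ? R::pgamma(ghi, shape, scale, 1, 0) : 1.0;
  if (phi - plo < 1e-14)
    Rcpp::stop("variance truncation region holds no posterior mass; widen the prior bounds");
  double u = plo + R::unif_rand() * (phi - plo);
  double g = R::qgamma(u, shape, scale, 1, 0);
  if (g < glo) g = glo;
  if (hi_finite && g > ghi) g = ghi;
  return 1.0 / g;
}

// [[Rcpp::export]]
arma::mat gibbs_lmm_cpp(const arma::mat& X, const arma::ivec& animal,
                        int n_animals, const arma::vec& y,
                        const arma::vec& beta_lo, const arma::vec& beta_hi,
                        const arma::vec& beta_init,
                        double var_a_lo, double var_a_hi,
                        double var_e_lo, double var_e_hi,
                        double var_a_init, double var_e_init,
                        int n_iter, int burn_in, int thin,
                        double fix_var_e, bool include_animal) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int q = include_animal ? n_animals : 0;

  arma::vec xtx(p);
  for (int j = 0; j < p; ++j) xtx(j) = arma::dot(X.col(j), X.col(j));

  std::vector<arma::uvec> rows(q);
  if (include_animal) {
    std::vector<std::vector<arma::uword>> tmp(q);
    for (int i = 0; i < n; ++i) tmp[animal(i)].push_back(i);
    for (int g = 0; g < q; ++g) rows[g] = arma::uvec(tmp[g]);
  }

  arma::vec beta = beta_init;
  arma::vec u(std::max(q, 1), arma::fill::zeros);
  double var_a = var_a_init, var_e = var_e_init;
  if (fix_var_e > 0.0) var_e = fix_var_e;

  arma::vec r = y - X * beta;
  if (include_animal)
    for (int g = 0; g < q; ++g) r.elem(rows[g]) -= u(g);

  const int n_keep = (n_iter - burn_in) / thin;
  const int ncol_out = p + q + (include_animal ? 1 : 0) + 1;
  arma::mat out(n_keep, ncol_out);

  int keep = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    for (int j = 0; j < p; ++j) {
      r += X.col(j) * beta(j);
      double m = arma::dot(X.col(j), r) / xtx(j);
      double s = std::sqrt(var_e / xtx(j));
      beta(j) = rtnorm(m, s, beta_lo(j), beta_hi(j));
      r -= X.col(j) * beta(j);
    }
    if (include_animal) {
      for (int g = 0; g < q; ++g) {
        r.elem(rows[g]) += u(g);
        double ng = rows[g].n_elem;
        double prec = ng / var_e + 1.0 / var_a;
        double mean = (arma::accu(r.elem(rows[g])) / var_e) / prec;
        u(g) = mean + R::norm_rand() / std::sqrt(prec);
        r.elem(rows[g]) -= u(g);
      }
      var_a = rtinvgamma(q / 2.0 - 1.0, arma::dot(u, u) / 2.0,
                         var_a_lo, var_a_hi);
    }
    if (fix_var_e <= 0.0) {
      var_e = rtinvgamma(n / 2.0 - 1.0, arma::dot(r, r) / 2.0,
                         var_e_lo, var_e_hi);
    }
    if (iter > burn_in && (iter - burn_in) % thin == 0 && keep < n_keep) {
      int c = 0;
      for (int j = 0; j < p; ++j) out(keep, c++) = beta(j);
      if (include_animal) {
        for (int g = 0; g < q; ++g) out(keep, c++) = u(g);
        out(keep, c++) = var_a;
      }
      out(keep, c++) = var_e;
      ++keep;
    }
  }
  return out;
}
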