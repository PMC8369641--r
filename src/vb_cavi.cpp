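// Coordinate-ascent variational inference for the spike-and-slab
// multiple-QTL model (vBayesB):
//   y_i = mu + sum_j x_ij delta_j a_j + f_{fam(i)} + e_i
//   delta_j ~ Bern(pi), a_j | s2a_j ~ N(0, s2a_j),
//   s2a_j ~ scaled-inv-chi2(nu, S2), f_k ~ N(0, sigma2_f),
//   e_i ~ N(0, sigma2_e).
// q(delta_j, a_j) is spike-and-slab (gamma_j, N(at_j, vt_j)), q(f_k) normal;
// mu, sigma2_e, sigma2_f are optimised and each s2a_j is the exact
// coordinate maximiser of the ELBO under its scaled-inv-chi2 prior, so every
// update is an exact ascent step and the ELBO is non-decreasing.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double log_sinvchi2(double x, double nu, double s2) {
  return 0.5 * nu * std::log(0.5 * nu * s2) - std::lgamma(0.5 * nu)
       - (1.0 + 0.5 * nu) * std::log(x) - 0.5 * nu * s2 / x;
}

static double xlogx(double x) {
  return (x <= 0.0) ? 0.0 : x * std::log(x);
}

// [[Rcpp::export]]
List vb_cavi_cpp(const arma::vec& y, const arma::mat& X,
                 const arma::ivec& fam, const int n_fam,
                 const double pi_prior, const double nu, const double s2,
                 const int max_iter, const double tol,
                 const bool shuffle, const int seed,
                 const arma::uvec& base_order) {
  const int n = y.n_elem;
  const int m = X.n_cols;
  const double logit_pi = std::log(pi_prior) - std::log1p(-pi_prior);

  arma::vec sxx(m);
  for (int j = 0; j < m; ++j) sxx(j) = arma::dot(X.col(j), X.col(j));

  double mu = arma::mean(y);
  arma::vec gam(m, arma::fill::value(pi_prior));
  arma::vec at(m, arma::fill::zeros);
  arma::vec vt(m, arma::fill::ones);
  arma::vec s2a(m, arma::fill::value(nu * s2 / (nu + 2.0)));
  arma::vec ft(std::max(n_fam, 1), arma::fill::zeros);
  arma::vec vf(std::max(n_fam, 1), arma::fill::zeros);
  arma::vec nk(std::max(n_fam, 1), arma::fill::zeros);
  if (n_fam > 0) for (int i = 0; i < n; ++i) nk(fam(i)) += 1.0;

  double vy = arma::var(y, 1);
  double sig2e = vy > 0 ? vy : 1.0;
  double sig2f = n_fam > 0 ? 0.1 * sig2e : 0.0;

  arma::vec r = y - mu;                 // residual excluding all model terms
  std::vector<int> order(m);
  for (int j = 0; j < m; ++j) {
    order[j] = (base_order.n_elem == static_cast<unsigned>(m))
      ? static_cast<int>(base_order(j)) : j;
  }
  std::mt19937 rng(static_cast<unsigned>(seed));

  std::vector<double> elbo_trace;
  double elbo_prev = -std::numeric_limits<double>::infinity();
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    if (shuffle) std::shuffle(order.begin(), order.end(), rng);

    // --- spike-and-slab factors and per-SNP variances ---
    for (int jj = 0; jj < m; ++jj) {
      const int j = order[jj];
      const double old_b = gam(j) * at(j);
      const double xr = arma::dot(X.col(j), r) + sxx(j) * old_b;
      const double v = sig2e / (sxx(j) + sig2e / s2a(j));
      const double a = v * xr / sig2e;
      const double lambda = logit_pi + 0.5 * std::log(v / s2a(j))
                          + 0.5 * a * a / v;
      const double g = 1.0 / (1.0 + std::exp(-lambda));
      const double new_b = g * a;
      if (new_b != old_b) r += X.col(j) * (old_b - new_b);
      gam(j) = g; at(j) = a; vt(j) = v;
      s2a(j) = (nu * s2 + g * (a * a + v)) / (nu + g + 2.0);
    }

    // --- intercept ---
    const double dmu = arma::mean(r);
    mu += dmu;
    r -= dmu;

    // --- family (progeny) effects ---
    if (n_fam > 0) {
      arma::vec rsum(n_fam, arma::fill::zeros);
      for (int i = 0; i < n; ++i) rsum(fam(i)) += r(i);
      for (int k = 0; k < n_fam; ++k) {
        const double denom = nk(k) + sig2e / std::max(sig2f, 1e-10);
        const double fnew = (rsum(k) + nk(k) * ft(k)) / denom;
        const double shift = ft(k) - fnew;
        if (shift != 0.0) {
          for (int i = 0; i < n; ++i) if (fam(i) == k) r(i) += shift;
        }
        ft(k) = fnew;
        vf(k) = sig2e / denom;
      }
      sig2f = std::max((arma::dot(ft, ft) + arma::accu(vf.head(n_fam))) / n_fam, 1e-10);
    }

    // --- residual variance ---
    double extra = 0.0;
    for (int j = 0; j < m; ++j) {
      extra += sxx(j) * (gam(j) * (at(j) * at(j) + vt(j))
                         - gam(j) * gam(j) * at(j) * at(j));
    }
    if (n_fam > 0) extra += arma::dot(nk.head(n_fam), vf.head(n_fam));
    const double ssr = arma::dot(r, r) + extra;
    sig2e = std::max(ssr / n, 1e-12);

    // --- ELBO ---
    double elbo = -0.5 * n * std::log(2.0 * M_PI * sig2e) - 0.5 * ssr / sig2e;
    for (int j = 0; j < m; ++j) {
      const double g = gam(j);
      elbo += g * std::log(pi_prior) + (1.0 - g) * std::log1p(-pi_prior)
            - xlogx(g) - xlogx(1.0 - g);
      elbo += g * 0.5 * (1.0 + std::log(vt(j) / s2a(j))
                         - (at(j) * at(j) + vt(j)) / s2a(j));
      elbo += log_sinvchi2(s2a(j), nu, s2);
    }
    if (n_fam > 0) {
      for (int k = 0; k < n_fam; ++k) {
        elbo += 0.5 * (1.0 + std::log(vf(k) / sig2f)
                       - (ft(k) * ft(k) + vf(k)) / sig2f);
      }
    }
    elbo_trace.push_back(elbo);
    if (std::isfinite(elbo_prev) &&
        elbo < elbo_prev - 1e-6 * (std::abs(elbo_prev) + 1.0)) {
      stop("internal error: ELBO decreased at iteration %d", iter);
    }
    if (std::isfinite(elbo_prev) &&
        std::abs(elbo - elbo_prev) < tol * (std::abs(elbo) + 1.0)) {
      converged = true;
      break;
    }
    elbo_prev = elbo;
  }

  return List::create(
    _["mu"] = mu, _["gamma"] = gam, _["atilde"] = at, _["vtilde"] = vt,
    _["sigma2_a"] = s2a,
    _["family_effects"] = (n_fam > 0) ? NumericVector(ft.begin(), ft.begin() + n_fam)
                                      : NumericVector(0),
    _["family_vars"] = (n_fam > 0) ? NumericVector(vf.begin(), vf.begin() + n_fam)
                                   : NumericVector(0),
    _["sigma2_e"] = sig2e, _["sigma2_f"] = sig2f,
    _["elbo"] = elbo_trace, _["converged"] = converged,
    _["n_iter"] = std::min(iter, max_iter));
}
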