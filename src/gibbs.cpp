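#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// inverse-gamma(shape, scale) via the reciprocal of a gamma(shape, rate = scale)
static inline double rinvgamma(double shape, double scale) {
  return 1.0 / R::rgamma(shape, 1.0 / scale);
}

// One Gibbs chain for y = X beta + u[field] + v[year] + eps with
// beta_j ~ N(0, beta_sd^2), u ~ N(0, s2f), v ~ N(0, s2y),
// all variances ~ IG(ig_shape, ig_scale). All conditionals are conjugate.
// field/year are 1-based row indices; pass length-0 vectors (n_field = 0)
// to drop a random effect entirely. Uses R's RNG, so results are
// reproducible under set.seed().
// [[Rcpp::export(name = ".gibbs_chain")]]
List gibbs_chain(const arma::vec& y,
                 const arma::mat& X,
                 const arma::ivec& field,
                 const arma::ivec& year,
                 const int n_field,
                 const int n_year,
                 const double beta_sd,
                 const double ig_shape,
                 const double ig_scale,
                 const int n_iter,
                 const int n_burn,
                 arma::vec beta,
                 arma::vec u,
                 arma::vec v,
                 double sigma2,
                 double sigma2_field,
                 double sigma2_year,
                 const bool fix_sigma2,
                 const double sigma2_fixed,
                 const bool recenter,
                 const int intercept_col) {
  const arma::uword n = y.n_elem;
  const arma::uword p = X.n_cols;
  const double prior_prec = 1.0 / (beta_sd * beta_sd);
  const double VAR_FLOOR = 1e-12;
  const int n_keep = n_iter - n_burn;
  int floor_hits = 0;

  const arma::mat XtX = X.t() * X;

  std::vector< std::vector<arma::uword> > frows(n_field), yrows(n_year);
  for (arma::uword i = 0; i < field.n_elem; ++i) frows[field[i] - 1].push_back(i);
  for (arma::uword i = 0; i < year.n_elem; ++i) yrows[year[i] - 1].push_back(i);

  arma::vec zu(n, arma::fill::zeros), wv(n, arma::fill::zeros);
  if (n_field > 0) for (arma::uword i = 0; i < n; ++i) zu[i] = u[field[i] - 1];
  if (n_year > 0) for (arma::uword i = 0; i < n; ++i) wv[i] = v[year[i] - 1];
  if (fix_sigma2) sigma2 = sigma2_fixed;

  arma::mat beta_out(n_keep, p);
  arma::mat u_out(n_keep, n_field > 0 ? n_field : 0);
  arma::mat v_out(n_keep, n_year > 0 ? n_year : 0);
  arma::vec s2_out(n_keep);
  arma::vec s2f_out(n_field > 0 ? n_keep : 0);
  arma::vec s2y_out(n_year > 0 ? n_keep : 0);

  arma::vec xb(n);

  for (int it = 1; it <= n_iter; ++it) {
    // beta | rest : N(mean, A^-1), A = X'X/s2 + I/beta_sd^2
    arma::vec r = y - zu - wv;
    arma::mat A = XtX / sigma2;
    A.diag() += prior_prec;
    arma::mat U;
    if (!arma::chol(U, A))
      stop("beta full conditional not positive definite (collinear design?) at iteration %d", it);
    arma::vec b = X.t() * r / sigma2;
    arma::vec m = arma::solve(arma::trimatu(U),
                              arma::solve(arma::trimatl(U.t()), b));
    arma::vec z(p);
    for (arma::uword j = 0; j < p; ++j) z[j] = R::norm_rand();
    beta = m + arma::solve(arma::trimatu(U), z);
    xb = X * beta;

    // u_j | rest : each field effect from its Gaussian conditional
    if (n_field > 0) {
      arma::vec r2 = y - xb - wv;
      for (int j = 0; j < n_field; ++j) {
        const std::vector<arma::uword>& rows = frows[j];
        double s = 0.0;
        for (size_t k = 0; k < rows.size(); ++k) s += r2[rows[k]];
        double prec = rows.size() / sigma2 + 1.0 / sigma2_field;
        u[j] = (s / sigma2) / prec + R::norm_rand() / std::sqrt(prec);
      }
      if (recenter && intercept_col > 0) {
        double ubar = arma::mean(u);
        u -= ubar;
        beta[intercept_col - 1] += ubar;
        xb = X * beta;
      }
      for (arma::uword i = 0; i < n; ++i) zu[i] = u[field[i] - 1];
    }

    // v_k | rest
    if (n_year > 0) {
      arma::vec r3 = y - xb - zu;
      for (int k = 0; k < n_year; ++k) {
        const std::vector<arma::uword>& rows = yrows[k];
        double s = 0.0;
        for (size_t q = 0; q < rows.size(); ++q) s += r3[rows[q]];
        double prec = rows.size() / sigma2 + 1.0 / sigma2_year;
        v[k] = (s / sigma2) / prec + R::norm_rand() / std::sqrt(prec);
      }
      if (recenter && intercept_col > 0) {
        double vbar = arma::mean(v);
        v -= vbar;
        beta[intercept_col - 1] += vbar;
        xb = X * beta;
      }
      for (arma::uword i = 0; i < n; ++i) wv[i] = v[year[i] - 1];
    }

    // variances | rest
    arma::vec resid = y - xb - zu - wv;
    if (!fix_sigma2) {
      sigma2 = rinvgamma(ig_shape + n / 2.0,
                         ig_scale + arma::dot(resid, resid) / 2.0);
      if (sigma2 < VAR_FLOOR) { sigma2 = VAR_FLOOR; ++floor_hits; }
    }
    if (n_field > 0) {
      sigma2_field = rinvgamma(ig_shape + n_field / 2.0,
                               ig_scale + arma::dot(u, u) / 2.0);
      if (sigma2_field < VAR_FLOOR) { sigma2_field = VAR_FLOOR; ++floor_hits; }
    }
    if (n_year > 0) {
      sigma2_year = rinvgamma(ig_shape + n_year / 2.0,
                              ig_scale + arma::dot(v, v) / 2.0);
      if (sigma2_year < VAR_FLOOR) { sigma2_year = VAR_FLOOR; ++floor_hits; }
    }

    if (!beta.is_finite())
      stop("non-finite beta at iteration %d", it);
    if (!std::isfinite(sigma2) ||
        (n_field > 0 && (!u.is_finite() || !std::isfinite(sigma2_field))) ||
        (n_year > 0 && (!v.is_finite() || !std::isfinite(sigma2_year))))
      stop("non-finite variance or random-effect state at iteration %d", it);

    if (it > n_burn) {
      const int row = it - n_burn - 1;
      beta_out.row(row) = beta.t();
      if (n_field > 0) u_out.row(row) = u.t();
      if (n_year > 0) v_out.row(row) = v.t();
      s2_out[row] = sigma2;
      if (n_field > 0) s2f_out[row] = sigma2_field;
      if (n_year > 0) s2y_out[row] = sigma2_year;
    }
  }

  return List::create(_["beta"] = beta_out,
                      _["u"] = u_out,
                      _["v"] = v_out,
                      _["sigma2"] = s2_out,
                      _["sigma2_field"] = s2f_out,
                      _["sigma2_year"] = s2y_out,
                      _["floor_hits"] = floor_hits);
}
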