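// EM for bivariate Gaussian mixtures under five covariance families.
// Specialized to d = 2 (lumen diameter, wall thickness): covariances are
// handled in closed form, the inner loop avoids matrix temporaries.
// Family codes: 1 spherical-shared, 2 spherical-free, 3 diagonal-free,
//               4 full-shared, 5 full-free.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List em_gmm_cpp(const arma::mat &X, arma::mat Z, int family,
                      int max_iter, double tol, const arma::vec &floor_diag) {
  const uword n = X.n_rows, k = Z.n_cols;
  const double log2pi = std::log(2.0 * M_PI);
  const vec x1 = X.col(0), x2 = X.col(1);
  vec w(k), m1(k), m2(k), s11(k), s22(k), s12(k), nj(k);
  mat logdens(n, k);
  vec d1(n), d2(n), mrow(n), rs(n);
  std::vector<double> trace_ll;
  trace_ll.reserve(64);
  double ll = -datum::inf, ll_old = -datum::inf;
  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    // M-step from current responsibilities
    for (uword j = 0; j < k; ++j) {
      const vec zj = Z.col(j);
      nj(j) = std::max(accu(zj), 1e-10);
      m1(j) = dot(zj, x1) / nj(j);
      m2(j) = dot(zj, x2) / nj(j);
      d1 = x1 - m1(j);
      d2 = x2 - m2(j);
      s11(j) = dot(zj % d1, d1) / nj(j);
      s22(j) = dot(zj % d2, d2) / nj(j);
      s12(j) = dot(zj % d1, d2) / nj(j);
    }
    w = nj / static_cast<double>(n);
    // constrain to the covariance family
    switch (family) {
    case 1: { // shared spherical
      double s2 = dot(w, (s11 + s22) / 2.0);
      s11.fill(s2); s22.fill(s2); s12.zeros();
      break;
    }
    case 2: { // per-component spherical
      vec s2 = (s11 + s22) / 2.0;
      s11 = s2; s22 = s2; s12.zeros();
      break;
    }
    case 3: // per-component diagonal
      s12.zeros();
      break;
    case 4: { // shared full
      double p11 = dot(w, s11), p22 = dot(w, s22), p12 = dot(w, s12);
      s11.fill(p11); s22.fill(p22); s12.fill(p12);
      break;
    }
    default: // 5: unrestricted
      break;
    }
    // variance floor, then force positive definiteness by shrinking the
    // off-diagonal if the determinant collapses
    for (uword j = 0; j < k; ++j) {
      if (s11(j) < floor_diag(0)) s11(j) = floor_diag(0);
      if (s22(j) < floor_diag(1)) s22(j) = floor_diag(1);
      double lim = 0.999 * std::sqrt(s11(j) * s22(j));
      if (std::abs(s12(j)) > lim) s12(j) = s12(j) > 0 ? lim : -lim;
    }
    // E-step: component log-densities via the closed-form 2x2 inverse
    for (uword j = 0; j < k; ++j) {
      double det = s11(j) * s22(j) - s12(j) * s12(j);
      double cst = std::log(w(j)) - log2pi - 0.5 * std::log(det);
      double a = s22(j) / det, b = s12(j) / det, c = s11(j) / det;
      d1 = x1 - m1(j);
      d2 = x2 - m2(j);
      logdens.col(j) = cst - 0.5 * (a * square(d1) - 2.0 * b * (d1 % d2) +
                                    c * square(d2));
    }
    mrow = max(logdens, 1);
    Z = exp(logdens.each_col() - mrow);
    rs = sum(Z, 1);
    ll = accu(mrow + log(rs));
    Z.each_col() /= rs;
    trace_ll.push_back(ll);
    if (std::isfinite(ll_old) && (ll - ll_old) < tol * (1.0 + std::abs(ll))) {
      converged = true;
      break;
    }
    ll_old = ll;
  }
  mat M(2, k);
  M.row(0) = m1.t();
  M.row(1) = m2.t();
  cube S(2, 2, k);
  for (uword j = 0; j < k; ++j) {
    S(0, 0, j) = s11(j); S(1, 1, j) = s22(j);
    S(0, 1, j) = s12(j); S(1, 0, j) = s12(j);
  }
  return Rcpp::List::create(
      Rcpp::Named("status") = 0, Rcpp::Named("weights") = w,
      Rcpp::Named("means") = M, Rcpp::Named("covariances") = S,
      Rcpp::Named("loglik") = ll, Rcpp::Named("responsibilities") = Z,
      Rcpp::Named("trace") = trace_ll, Rcpp::Named("iterations") = it,
      Rcpp::Named("converged") = converged);
}
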