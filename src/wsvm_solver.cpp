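// Sequential minimal optimization for the four-weight soft-margin linear SVM.
//
// Solves   min_{w,b,xi}  1/2 ||w||^2 + sum_i C_i xi_i
//          s.t.          y_i (w.x_i + b) >= 1 - xi_i,  xi_i >= 0
// through its dual
//          min_a  1/2 a' Q a - 1'a   s.t.  y'a = 0,  0 <= a_i <= C_i
// with Q_ij = y_i y_j x_i.x_j.  Per-sample costs C_i carry the RP/LP/LN/RN
// set weights.  Working-set selection is second order (the maximal violator
// paired with the partner of steepest feasible decrease, as in libsvm);
// the stopping criterion is the violation surrogate m(a) - M(a) <= tol,
// which bounds every sample's KKT residual by tol.  The gradient is
// refreshed from scratch periodically to keep incremental rounding from
// accumulating over long runs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Upper bound (in doubles) on the cached kernel matrix: 6000^2 * 8B = 288 MB.
static const arma::uword KERNEL_CACHE_MAX_N = 6000;

// [[Rcpp::export]]
List wsvm_smo(const arma::mat& X, const arma::vec& y, const arma::vec& C,
              double tol, int max_iter) {
  const arma::uword n = X.n_rows;
  if (y.n_elem != n || C.n_elem != n)
    stop("X, y and C must agree in length");

  const bool cache = n <= KERNEL_CACHE_MAX_N;
  arma::mat K;
  arma::vec Kdiag(n);
  if (cache) {
    K = X * X.t();
    Kdiag = K.diag();
  } else {
    for (arma::uword t = 0; t < n; ++t)
      Kdiag(t) = arma::dot(X.row(t), X.row(t));
  }

  arma::vec alpha(n, arma::fill::zeros);
  arma::vec G(n, arma::fill::value(-1.0));  // grad of dual at alpha = 0

  auto kcol = [&](arma::uword j) -> arma::vec {
    if (cache) return K.col(j);
    return X * X.row(j).t();
  };

  const double tau = 1e-12;
  const int refresh_every = 100000;
  int iter = 0;
  double gap = R_PosInf;

  for (iter = 0; iter < max_iter; ++iter) {
    if (iter > 0 && iter % refresh_every == 0) {
      // recompute G = Q alpha - 1 exactly
      arma::vec v = alpha % y;
      arma::vec Xv = X.t() * v;
      G = y % (X * Xv) - 1.0;
    }

    // i: maximal violator in I_up; M: tightest bound in I_low
    double m_up = -R_PosInf, m_low = R_PosInf;
    arma::sword i = -1;
    for (arma::uword t = 0; t < n; ++t) {
      const double v = -y(t) * G(t);
      const bool up  = (y(t) > 0 && alpha(t) < C(t)) || (y(t) < 0 && alpha(t) > 0);
      const bool low = (y(t) > 0 && alpha(t) > 0)    || (y(t) < 0 && alpha(t) < C(t));
      if (up && v > m_up) { m_up = v; i = t; }
      if (low && v < m_low) m_low = v;
    }
    gap = m_up - m_low;
    if (i < 0 || gap <= tol) break;

    const arma::vec Ki = kcol((arma::uword)i);

    // j: second-order selection among I_low with v_j < v_i
    arma::sword j = -1;
    double best = 0.0, vj_best = 0.0;
    for (arma::uword t = 0; t < n; ++t) {
      const bool low = (y(t) > 0 && alpha(t) > 0) || (y(t) < 0 && alpha(t) < C(t));
      if (!low) continue;
      const double v = -y(t) * G(t);
      const double bdiff = m_up - v;
      if (bdiff <= 0) continue;
      double eta = Kdiag((arma::uword)i) + Kdiag(t) - 2.0 * Ki(t);
      if (eta < tau) eta = tau;
      const double score = -(bdiff * bdiff) / eta;
      if (j < 0 || score < best) { best = score; j = t; vj_best = v; }
    }
    if (j < 0) break;

    const arma::vec Kj = kcol((arma::uword)j);

    // step t along (d alpha_i, d alpha_j) = (y_i t, -y_j t)
    double eta = Kdiag((arma::uword)i) + Kdiag((arma::uword)j)
      - 2.0 * Ki((arma::uword)j);
    if (eta < tau) eta = tau;
    double step = (m_up - vj_best) / eta;

    const double ti = (y((arma::uword)i) > 0)
      ? C((arma::uword)i) - alpha((arma::uword)i) : alpha((arma::uword)i);
    const double tj = (y((arma::uword)j) > 0)
      ? alpha((arma::uword)j) : C((arma::uword)j) - alpha((arma::uword)j);
    if (step > ti) step = ti;
    if (step > tj) step = tj;

    alpha((arma::uword)i) += y((arma::uword)i) * step;
    alpha((arma::uword)j) -= y((arma::uword)j) * step;
    // dG_t = y_t * step * (K_ti - K_tj)
    G += (y % (Ki - Kj)) * step;
  }

  const bool converged = gap <= tol;

  // bias: average -y_t G_t over free support vectors, else midpoint of bounds
  double b = 0.0; arma::uword nfree = 0;
  for (arma::uword t = 0; t < n; ++t) {
    if (alpha(t) > 0 && alpha(t) < C(t)) { b += -y(t) * G(t); ++nfree; }
  }
  if (nfree > 0) {
    b /= (double)nfree;
  } else {
    double ub = -R_PosInf, lb = R_PosInf;
    for (arma::uword t = 0; t < n; ++t) {
      const double v = -y(t) * G(t);
      const bool up  = (y(t) > 0 && alpha(t) < C(t)) || (y(t) < 0 && alpha(t) > 0);
      const bool low = (y(t) > 0 && alpha(t) > 0)    || (y(t) < 0 && alpha(t) < C(t));
      if (up && v > ub) ub = v;
      if (low && v < lb) lb = v;
    }
    b = (std::isfinite(ub) && std::isfinite(lb)) ? (ub + lb) / 2.0 : 0.0;
  }

  arma::vec w = X.t() * (alpha % y);

  return List::create(_["alpha"] = alpha, _["w"] = w, _["b"] = b,
                      _["iterations"] = iter, _["gap"] = gap,
                      _["converged"] = converged);
}
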