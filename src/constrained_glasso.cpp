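// Coordinate-descent graphical lasso with structural zeros.
//
// Solves  max_Theta  log det(Theta) - tr(S Theta) - rho * sum_ij |Theta_ij|
// subject to Theta_ij = 0 for every entry forbidden by `mask`
// (mask(i,j) = 1 means the edge is permitted; the diagonal is always free).
// Forbidden entries are excluded from every lasso subproblem, so they come
// out exactly zero, not merely shrunk. The diagonal is penalized, i.e. the
// working covariance starts at W = S + rho I, the usual glasso convention.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export]]
Rcpp::List cglasso_cpp(const arma::mat& S, double rho, const arma::imat& mask,
                       double tol, int max_iter) {
  const int p = S.n_rows;
  mat W = S + rho * eye(p, p);
  mat B = zeros(p, p);               // B(i, j): lasso coefficient of var i for column j

  // convergence scale: mean absolute off-diagonal of S (glasso's criterion)
  double sbar = 0.0;
  if (p > 1) {
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j)
        if (i != j) sbar += std::abs(S(i, j));
    sbar /= (double)(p * (p - 1));
  }
  double thr = tol * (sbar > 0 ? sbar : 1.0);
  double inner_thr = thr / 10.0;

  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    double sweep_delta = 0.0;
    for (int j = 0; j < p; ++j) {
      // permitted partners of column j
      std::vector<int> idx;
      idx.reserve(p);
      for (int i = 0; i < p; ++i)
        if (i != j && mask(i, j) != 0) idx.push_back(i);

      vec w_old = W.col(j);

      if (idx.empty()) {
        for (int i = 0; i < p; ++i)
          if (i != j) { W(i, j) = 0.0; W(j, i) = 0.0; }
      } else {
        const int m = (int)idx.size();
        // V = W11 restricted to permitted partners, s = S12 restricted
        mat V(m, m);
        vec s(m), beta(m);
        for (int a = 0; a < m; ++a) {
          s(a) = S(idx[a], j);
          beta(a) = B(idx[a], j);
          for (int b = 0; b < m; ++b) V(a, b) = W(idx[a], idx[b]);
        }
        // lasso by cyclic coordinate descent
        for (int it2 = 0; it2 < 1000; ++it2) {
          double dmax = 0.0;
          for (int a = 0; a < m; ++a) {
            double r = s(a);
            for (int b = 0; b < m; ++b)
              if (b != a) r -= V(a, b) * beta(b);
            double bnew = soft(r, rho) / V(a, a);
            double d = std::abs(bnew - beta(a));
            if (d > dmax) dmax = d;
            beta(a) = bnew;
          }
          if (dmax < inner_thr) break;
        }
        // w12 = W11 * beta over ALL other coordinates
        for (int i = 0; i < p; ++i) {
          if (i == j) continue;
          double wi = 0.0;
          for (int a = 0; a < m; ++a) wi += W(i, idx[a]) * beta(a);
          W(i, j) = wi;
          W(j, i) = wi;
        }
        for (int a = 0; a < m; ++a) B(idx[a], j) = beta(a);
      }
      sweep_delta += mean(abs(W.col(j) - w_old));
    }
    sweep_delta /= (double)p;
    if (sweep_delta < thr) { converged = true; break; }
  }

  // back out the precision matrix; forbidden entries are exactly zero
  mat Theta = zeros(p, p);
  for (int j = 0; j < p; ++j) {
    double dot = 0.0;
    for (int i = 0; i < p; ++i)
      if (i != j) dot += W(i, j) * B(i, j);
    double tjj = 1.0 / (W(j, j) - dot);
    Theta(j, j) = tjj;
    for (int i = 0; i < p; ++i)
      if (i != j && mask(i, j) != 0) Theta(i, j) = -B(i, j) * tjj;
  }
  // numerical symmetrization (zeros on forbidden entries are preserved:
  // the mask is symmetric, so both halves are exactly zero there)
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(
    Rcpp::Named("theta") = Theta,
    Rcpp::Named("w") = W,
    Rcpp::Named("n_iter") = iter > max_iter ? max_iter : iter,
    Rcpp::Named("converged") = converged);
}
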