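// Sequential minimal optimization for the soft-margin linear SVM dual:
//   min 1/2 a' Q a - e' a   s.t. 0 <= a_i <= C,  y' a = 0,
// with Q_ij = y_i y_j x_i . x_j. The working pair is chosen by
// second-order selection (maximal violator paired with the partner of
// greatest guaranteed decrease); the explicit weight vector
// w = sum a_i y_i x_i keeps each iteration O(n d). Deterministic for a
// fixed data order.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List smo_linear_svm(const arma::mat& X, const arma::vec& y,
                          double C, double eps, int max_iter) {
  const uword n = X.n_rows;
  const double tau = 1e-12;
  vec alpha(n, fill::zeros);
  vec w(X.n_cols, fill::zeros);
  vec f(n, fill::zeros);          // f_i = w . x_i
  vec xsq(n);
  for (uword i = 0; i < n; ++i) xsq(i) = dot(X.row(i), X.row(i));

  double gap = datum::inf;
  int it = 0;
  for (; it < max_iter; ++it) {
    // violation values v_k = y_k - f_k (= b at optimal free vectors)
    double up = -datum::inf, lo = datum::inf;
    sword iu = -1;
    for (uword k = 0; k < n; ++k) {
      const double v = y(k) - f(k);
      const bool in_up = (y(k) > 0 && alpha(k) < C) ||
                         (y(k) < 0 && alpha(k) > 0);
      const bool in_lo = (y(k) > 0 && alpha(k) > 0) ||
                         (y(k) < 0 && alpha(k) < C);
      if (in_up && v > up) { up = v; iu = k; }
      if (in_lo && v < lo) lo = v;
    }
    gap = up - lo;
    if (iu < 0 || gap < eps) break;
    const uword i = (uword)iu;
    const vec qi = X * X.row(i).t();     // K_i. column
    // partner: minimize -(v_i - v_j)^2 / a_ij over violating j
    sword jl = -1;
    double best = 0.0;
    for (uword k = 0; k < n; ++k) {
      const bool in_lo = (y(k) > 0 && alpha(k) > 0) ||
                         (y(k) < 0 && alpha(k) < C);
      if (!in_lo) continue;
      const double vk = y(k) - f(k);
      const double diff = up - vk;
      if (diff <= 0) continue;
      double a = xsq(i) + xsq(k) - 2.0 * qi(k);
      if (a < tau) a = tau;
      const double score = -(diff * diff) / a;
      if (score < best) { best = score; jl = k; }
    }
    if (jl < 0) break;
    const uword j = (uword)jl;
    double eta = xsq(i) + xsq(j) - 2.0 * qi(j);
    if (eta < tau) eta = tau;
    const double s = y(i) * y(j);
    const double ai = alpha(i), aj = alpha(j);
    // unconstrained step along the equality constraint, then clip
    double aj_new = aj + y(j) * ((f(i) - y(i)) - (f(j) - y(j))) / eta;
    double L, H;
    if (s < 0) { L = std::max(0.0, aj - ai); H = std::min(C, C + aj - ai); }
    else       { L = std::max(0.0, ai + aj - C); H = std::min(C, ai + aj); }
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
    double ai_new = ai + s * (aj - aj_new);
    // snap to exact bounds so float residue cannot keep a variable in
    // the working set at a bound it has effectively reached
    const double snap = 1e-12 * C;
    if (aj_new < snap) aj_new = 0.0; else if (C - aj_new < snap) aj_new = C;
    if (ai_new < snap) ai_new = 0.0; else if (C - ai_new < snap) ai_new = C;
    const double di = (ai_new - ai) * y(i), dj = (aj_new - aj) * y(j);
    if (std::abs(di) < 1e-16 && std::abs(dj) < 1e-16) break; // numerically stuck
    alpha(i) = ai_new; alpha(j) = aj_new;
    w += di * X.row(i).t() + dj * X.row(j).t();
    if ((it + 1) % 20000 == 0) {
      f = X * w;                  // periodic exact refresh against drift
    } else {
      f += di * qi + dj * (X * X.row(j).t());
    }
  }

  f = X * w;
  // bias from free support vectors, else midpoint of the violating bounds
  double b;
  uvec free_sv = find(alpha > 1e-10 * C && alpha < C * (1 - 1e-10));
  if (free_sv.n_elem > 0) {
    b = mean(y(free_sv) - f(free_sv));
  } else {
    double up = -datum::inf, lo = datum::inf;
    for (uword k = 0; k < n; ++k) {
      const double v = y(k) - f(k);
      const bool in_up = (y(k) > 0 && alpha(k) < C) ||
                         (y(k) < 0 && alpha(k) > 0);
      const bool in_lo = (y(k) > 0 && alpha(k) > 0) ||
                         (y(k) < 0 && alpha(k) < C);
      if (in_up && v > up) up = v;
      if (in_lo && v < lo) lo = v;
    }
    b = (up + lo) / 2.0;
  }

  return Rcpp::List::create(
      Rcpp::Named("alpha") = alpha,
      Rcpp::Named("w") = w,
      Rcpp::Named("b") = b,
      Rcpp::Named("iterations") = it,
      Rcpp::Named("gap") = gap,
      Rcpp::Named("converged") = gap < eps);
}
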