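// Weighted least-absolute-deviations regression through the origin:
// minimize sum_j w_j |y_j - x_j' theta|.
//
// Hot loop of the median estimator's parametric bootstrap, hence C++.
// Strategy: scale rows by w (w > 0), run IRLS on the smoothed objective,
// then polish exactly by enumerating K-subsets of the rows with smallest
// absolute residuals (an LAD optimum interpolates K rows), keeping the
// vertex with the lowest objective.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double lad_objective(const mat& Xs, const vec& ys, const vec& theta) {
  return sum(abs(ys - Xs * theta));
}

// [[Rcpp::export(name = ".lad_fit_cpp")]]
Rcpp::List lad_fit_cpp(const arma::mat& X, const arma::vec& y,
                       const arma::vec& w, int max_iter = 100,
                       double tol = 1e-12, int polish_extra = 4,
                       Rcpp::Nullable<Rcpp::NumericVector> theta_init =
                           R_NilValue) {
  const uword p = X.n_rows, K = X.n_cols;
  mat Xs = X.each_col() % w;
  vec ys = y % w;

  vec theta;
  if (theta_init.isNotNull()) {
    theta = Rcpp::as<vec>(theta_init.get());
  } else {
    if (!solve(theta, Xs, ys)) theta = zeros<vec>(K);
  }
  vec r = ys - Xs * theta;
  double f_old = sum(abs(r));

  for (int it = 0; it < max_iter; ++it) {
    vec wi = 1.0 / clamp(abs(r), 1e-10, datum::inf);
    mat Xw = Xs.each_col() % wi;
    vec theta_new;
    if (!solve(theta_new, Xw.t() * Xs, Xw.t() * ys)) break;
    vec r_new = ys - Xs * theta_new;
    double f_new = sum(abs(r_new));
    if (f_new <= f_old) {
      theta = theta_new;
      r = r_new;
    }
    if (std::abs(f_old - f_new) <= tol * std::max(1.0, f_old)) break;
    f_old = std::min(f_old, f_new);
  }
  double best_obj = sum(abs(r));
  vec best_theta = theta;

  // exact vertex polish over K-subsets of the m smallest |residuals|
  const uword m = std::min<uword>(p, K + (uword)polish_extra);
  uvec ord = sort_index(abs(r));
  uvec cand = ord.head(m);

  std::vector<uword> comb(K);
  for (uword i = 0; i < K; ++i) comb[i] = i;
  mat A(K, K);
  vec b(K), th(K);
  while (true) {
    for (uword i = 0; i < K; ++i) {
      A.row(i) = Xs.row(cand[comb[i]]);
      b[i] = ys[cand[comb[i]]];
    }
    if (solve(th, A, b, solve_opts::no_approx)) {
      double obj = lad_objective(Xs, ys, th);
      if (obj < best_obj) {
        best_obj = obj;
        best_theta = th;
      }
    }
    // next K-combination of {0..m-1}
    int i = (int)K - 1;
    while (i >= 0 && comb[i] == m - K + i) --i;
    if (i < 0) break;
    ++comb[i];
    for (uword j = i + 1; j < K; ++j) comb[j] = comb[j - 1] + 1;
  }

  return Rcpp::List::create(Rcpp::Named("theta") = best_theta,
                            Rcpp::Named("objective") = best_obj);
}
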