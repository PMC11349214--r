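// Newton/IRLS fits of binary and multinomial logit models, the inner loop of
// the likelihood-ratio conditional independence tests. Returns the deviance
// (2 * negative log-likelihood) and the coefficients for warm starts.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static double nll_binary(const vec& eta, const vec& y) {
  vec a = clamp(eta, 0.0, datum::inf);  // max(eta, 0), stable log1pexp
  return accu(a + log(exp(-a) + exp(eta - a))) - dot(y, eta);
}

// [[Rcpp::export(name = ".mlogit_newton")]]
Rcpp::List mlogit_newton(const arma::mat& X, const arma::mat& Yind,
                         Rcpp::Nullable<Rcpp::NumericMatrix> start,
                         int max_iter = 30, double tol = 1e-9) {
  const int n = X.n_rows, q = X.n_cols, L = Yind.n_cols;
  (void)n;
  if (L < 2 || q == 0)
    return Rcpp::List::create(Rcpp::Named("dev") = 0.0,
                              Rcpp::Named("beta") = R_NilValue);
  if (L == 2) {
    vec y = Yind.col(1);
    vec beta(q, fill::zeros);
    if (start.isNotNull()) beta = Rcpp::as<vec>(start.get());
    vec eta = X * beta;
    double cur = nll_binary(eta, y);
    for (int it = 0; it < max_iter; ++it) {
      vec p = 1.0 / (1.0 + exp(-eta));
      vec w = clamp(p % (1.0 - p), 1e-10, 0.25);
      vec g = X.t() * (y - p);
      mat H = X.t() * (X.each_col() % w);
      H.diag() += 1e-9;
      vec step;
      if (!solve(step, H, g, solve_opts::fast + solve_opts::no_approx))
        step = g * 0.1;
      double shrink = 1.0, val = cur;
      vec cand = beta, eta2 = eta;
      while (true) {
        cand = beta + shrink * step;
        eta2 = X * cand;
        val = nll_binary(eta2, y);
        if (std::isfinite(val) && val <= cur + 1e-12) break;
        shrink /= 2.0;
        if (shrink < 1e-6) { cand = beta; eta2 = eta; val = cur; break; }
      }
      bool conv = std::fabs(cur - val) <= tol * std::max(std::fabs(cur), 1.0);
      beta = cand; eta = eta2; cur = val;
      if (conv) break;
    }
    return Rcpp::List::create(Rcpp::Named("dev") = 2.0 * cur,
                              Rcpp::Named("beta") = mat(beta));
  }

  mat beta(q, L - 1, fill::zeros);
  if (start.isNotNull()) beta = Rcpp::as<mat>(start.get());
  auto nll = [&](const mat& b) -> double {
    mat eta(X.n_rows, L, fill::zeros);
    eta.cols(1, L - 1) = X * b;
    vec m = max(eta, 1);
    vec lse = m + log(sum(exp(eta.each_col() - m), 1));
    return accu(lse) - accu(eta % Yind);
  };
  double cur = nll(beta);
  const int d = q * (L - 1);
  for (int it = 0; it < max_iter; ++it) {
    mat eta(X.n_rows, L, fill::zeros);
    eta.cols(1, L - 1) = X * beta;
    vec m = max(eta, 1);
    mat P = exp(eta.each_col() - m);
    P.each_col() /= sum(P, 1);
    mat grad = X.t() * (P.cols(1, L - 1) - Yind.cols(1, L - 1));
    mat H(d, d);
    for (int l = 0; l < L - 1; ++l)
      for (int mcol = 0; mcol < L - 1; ++mcol) {
        vec w = (l == mcol) ? vec(P.col(l + 1) % (1.0 - P.col(l + 1)))
                            : vec(-P.col(l + 1) % P.col(mcol + 1));
        H.submat(l * q, mcol * q, (l + 1) * q - 1, (mcol + 1) * q - 1) =
            X.t() * (X.each_col() % w);
      }
    H.diag() += 1e-8;
    vec step;
    if (!solve(step, H, vectorise(grad), solve_opts::fast + solve_opts::no_approx))
      step = vectorise(grad) * 0.1;
    double shrink = 1.0, val = cur;
    mat cand = beta;
    while (true) {
      cand = beta - shrink * reshape(step, q, L - 1);
      val = nll(cand);
      if (std::isfinite(val) && val <= cur + 1e-12) break;
      shrink /= 2.0;
      if (shrink < 1e-6) { cand = beta; val = cur; break; }
    }
    bool conv = std::fabs(cur - val) <= tol * std::max(std::fabs(cur), 1.0);
    beta = cand; cur = val;
    if (conv) break;
  }
  return Rcpp::List::create(Rcpp::Named("dev") = 2.0 * cur,
                            Rcpp::Named("beta") = beta);
}
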