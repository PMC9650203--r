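#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Multiplicative updates (Frobenius loss) for X ~ W * C with W, C >= 0.
// SSE is monitored every `check_every` iterations; the run stops when the
// relative SSE decrease over that window falls below `tol`.
// [[Rcpp::export]]
Rcpp::List nnmf_mu_cpp(const arma::mat& X, arma::mat W, arma::mat C,
                       int max_iter, double tol, int check_every) {
  const double eps = 1e-12;
  double sse_prev = accu(square(X - W * C));
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    C %= (W.t() * X) / (W.t() * W * C + eps);
    W %= (X * C.t()) / (W * C * C.t() + eps);
    if (it % check_every == 0) {
      double sse = accu(square(X - W * C));
      if (sse_prev - sse < tol * std::max(sse_prev, eps)) {
        sse_prev = sse;
        break;
      }
      sse_prev = sse;
    }
  }
  double sse = accu(square(X - W * C));
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("C") = C,
                            Rcpp::Named("sse") = sse,
                            Rcpp::Named("iters") = it);
}
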