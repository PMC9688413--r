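#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Generalized Kullback-Leibler divergence D(V || WH).
// Terms with V == 0 contribute WH only (x log x -> 0 limit).
static double kl_div(const mat& V, const mat& WH) {
  double d = 0.0;
  const double* v = V.memptr();
  const double* w = WH.memptr();
  const uword n = V.n_elem;
  for (uword i = 0; i < n; ++i) {
    double wh = w[i] > 1e-300 ? w[i] : 1e-300;
    if (v[i] > 0.0) d += v[i] * std::log(v[i] / wh) - v[i] + wh;
    else d += wh;
  }
  return d;
}

// Multiplicative-update NMF for the generalized KL divergence
// (Lee & Seung updates, Brunet-style). Initial factors are supplied by the
// caller so all randomness stays under R's RNG.
// trace_every controls how often the objective is evaluated (and the
// stopping rule applied); 1 records the full per-iteration trace.
// [[Rcpp::export(name = ".nmf_kl_cpp")]]
Rcpp::List nmf_kl_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol, int trace_every = 1) {
  const double eps = 1e-12;
  if (trace_every < 1) trace_every = 1;
  mat WH = W * H;
  std::vector<double> trace;
  trace.reserve(max_iter / trace_every + 2);
  double obj = kl_div(V, WH);
  trace.push_back(obj);

  for (int it = 0; it < max_iter; ++it) {
    // H update: H <- H .* (W' (V ./ WH)) ./ colsum(W)'
    mat Q = V / (WH + eps);
    vec wcol = sum(W, 0).t() + eps;
    H %= (W.t() * Q);
    H.each_col() /= wcol;

    // W update with refreshed quotient
    WH = W * H;
    Q = V / (WH + eps);
    vec hrow = sum(H, 1) + eps;
    W %= (Q * H.t());
    W.each_row() /= hrow.t();

    WH = W * H;
    if ((it + 1) % trace_every == 0 || it + 1 == max_iter) {
      double obj_new = kl_div(V, WH);
      trace.push_back(obj_new);
      double rel = std::fabs(obj - obj_new) / (std::fabs(obj) + eps);
      obj = obj_new;
      if (rel < tol) break;
    }
  }

  // Scale W columns to unit L1, compensating in H.
  rowvec s = sum(W, 0);
  for (uword k = 0; k < W.n_cols; ++k) {
    double sk = s(k) > eps ? s(k) : eps;
    W.col(k) /= sk;
    H.row(k) *= sk;
  }

  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("H") = H,
                            Rcpp::Named("trace") = trace);
}
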