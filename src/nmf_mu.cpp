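#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Kullback-Leibler (generalized I-) divergence D(V || WH).
// Entries of WH that are exactly zero against V > 0 give +Inf (the limit);
// otherwise WH is floored at eps inside the log/division only.
static double kl_div(const mat& V, const mat& WH, const double eps) {
  double s = 0.0;
  const uword n = V.n_elem;
  for (uword i = 0; i < n; ++i) {
    const double v = V(i);
    const double wh = WH(i);
    if (v > 0.0) {
      if (wh == 0.0) return R_PosInf;
      const double whf = (wh < eps) ? eps : wh;
      s += v * (std::log(v) - std::log(whf)) - v + wh;
    } else {
      s += wh;
    }
  }
  return s;
}

// [[Rcpp::export(name = ".kl_divergence_cpp")]]
double kl_divergence_cpp(const arma::mat& V, const arma::mat& W,
                         const arma::mat& H, const double eps) {
  return kl_div(V, W * H, eps);
}

// Multiplicative-update loop for KL-divergence NMF: H is updated first
// with the current W, then W with the new H; both factors and the WH
// denominators are floored at eps.  Stops when the relative divergence
// improvement over one full step drops below tol, or after max_iter steps.
// [[Rcpp::export(name = ".nmf_mu_cpp")]]
Rcpp::List nmf_mu_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      const int max_iter, const double tol,
                      const double eps, const bool track) {
  std::vector<double> trace;
  if (track) trace.reserve(max_iter);

  mat WH = W * H;
  double d_prev = kl_div(V, WH, eps);
  int it = 0;
  bool converged = false;
  double d = d_prev;

  for (it = 0; it < max_iter; ++it) {
    // H update
    WH = clamp(W * H, eps, datum::inf);
    H %= W.t() * (V / WH);
    H.each_col() /= sum(W, 0).t();
    H = clamp(H, eps, datum::inf);

    // W update with the fresh H
    WH = clamp(W * H, eps, datum::inf);
    W %= (V / WH) * H.t();
    W.each_row() /= sum(H, 1).t();
    W = clamp(W, eps, datum::inf);

    d = kl_div(V, W * H, eps);
    if (track) trace.push_back(d);
    if (d_prev > 0.0 && (d_prev - d) / d_prev < tol) {
      ++it;
      converged = true;
      break;
    }
    if (d_prev == 0.0) { ++it; converged = true; break; }
    d_prev = d;
  }
  if (!converged) it = max_iter;

  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("H") = H,
      Rcpp::Named("iterations") = it,
      Rcpp::Named("divergence") = d,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("trace") = trace);
}
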