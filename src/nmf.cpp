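#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Gaussian (Frobenius) NMF by multiplicative updates.
// Per iteration: H <- H % (W'V) / (W'W H), then W <- W % (V H') / (W H H'),
// in that order; denominators floored at 1e-12. R^2 between V and WH is
// evaluated once per iteration, after both updates. Convergence fires when
// the spread (max - min) of the last `window` R^2 values falls below
// rel_tol times the current R^2.
// [[Rcpp::export]]
Rcpp::List nmf_mu_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, int window, double rel_tol) {
  const double floor_eps = 1e-12;
  const double v2 = accu(square(V));
  const double vmean = accu(V) / V.n_elem;
  const double sst = accu(square(V - vmean));

  std::vector<double> r2_trace;
  r2_trace.reserve(max_iter);
  int iter = 0;
  double r2 = 0.0;

  for (iter = 1; iter <= max_iter; ++iter) {
    // H update
    mat WtV = W.t() * V;
    mat denH = (W.t() * W) * H;
    denH.transform([floor_eps](double d) { return d < floor_eps ? floor_eps : d; });
    H %= WtV / denH;

    // W update (H already advanced)
    mat VHt = V * H.t();
    mat HHt = H * H.t();
    mat denW = W * HHt;
    denW.transform([floor_eps](double d) { return d < floor_eps ? floor_eps : d; });
    W %= VHt / denW;

    // R^2 of the current (W, H) without forming W H explicitly:
    // SSE = ||V||^2 - 2 tr(V' W H) + tr((W'W)(H H'))
    double sse = v2 - 2.0 * accu(W % VHt) + accu((W.t() * W) % HHt);
    if (sse < 0.0) sse = 0.0;  // guard tiny negative round-off
    r2 = 1.0 - sse / sst;
    if (!std::isfinite(r2) || !W.is_finite() || !H.is_finite()) {
      Rcpp::stop("non-finite values at iteration %d", iter);
    }
    r2_trace.push_back(r2);

    if ((int)r2_trace.size() >= window) {
      double lo = r2_trace[r2_trace.size() - window];
      double hi = lo;
      for (size_t k = r2_trace.size() - window; k < r2_trace.size(); ++k) {
        lo = std::min(lo, r2_trace[k]);
        hi = std::max(hi, r2_trace[k]);
      }
      if ((hi - lo) < rel_tol * std::abs(r2)) break;
    }
  }
  if (iter > max_iter) iter = max_iter;

  return Rcpp::List::create(
      Rcpp::Named("W") = W,
      Rcpp::Named("H") = H,
      Rcpp::Named("r_squared") = r2,
      Rcpp::Named("iterations") = iter,
      Rcpp::Named("r2_trace") = r2_trace);
}
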