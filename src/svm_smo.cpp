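// SMO dual solver core: second-order working-set selection over a
// precomputed Gram matrix. Deterministic; no RNG.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".svm_smo_cpp")]]
Rcpp::List svm_smo_cpp(const arma::mat& K, const arma::vec& y, double C,
                       double tol, int max_iter) {
  const arma::uword n = y.n_elem;
  const double eps_a = 1e-12;
  arma::vec alpha(n, arma::fill::zeros);
  arma::vec E = -y;  // E_i = sum_j alpha_j y_j K_ij - y_i
  arma::vec diagK = K.diag();

  int iter = 0;
  double gap = arma::datum::inf;
  bool converged = false;

  while (true) {
    // I_up / I_low membership and the maximal violating pair bound
    double m_up = -arma::datum::inf, m_lo = arma::datum::inf;
    arma::uword i_best = 0;
    for (arma::uword t = 0; t < n; ++t) {
      double mE = -E(t);
      bool up = (alpha(t) < C - eps_a && y(t) > 0) ||
                (alpha(t) > eps_a && y(t) < 0);
      bool lo = (alpha(t) < C - eps_a && y(t) < 0) ||
                (alpha(t) > eps_a && y(t) > 0);
      if (up && mE > m_up) { m_up = mE; i_best = t; }
      if (lo && mE < m_lo) m_lo = mE;
    }
    gap = m_up - m_lo;
    if (gap <= tol) { converged = true; break; }
    if (++iter > max_iter) break;
    if (iter % 2048 == 0) E = K * (alpha % y) - y;  // drift refresh

    // second-order choice of j among I_low with negative progress bound;
    // a numerically blocked pair falls through to the next-best partner
    arma::uword i = i_best;
    double mEi = -E(i);
    std::vector<char> tried(n, 0);
    bool moved = false;
    for (int attempt = 0; attempt < 10 && !moved; ++attempt) {
      double best_gain = -1.0;
      arma::uword j = n;
      for (arma::uword t = 0; t < n; ++t) {
        if (tried[t]) continue;
        bool lo = (alpha(t) < C - eps_a && y(t) < 0) ||
                  (alpha(t) > eps_a && y(t) > 0);
        if (!lo) continue;
        double diff = mEi - (-E(t));
        if (diff <= 1e-12) continue;
        double eta = diagK(i) + diagK(t) - 2.0 * K(t, i);
        if (eta < 1e-12) eta = 1e-12;
        double gain = diff * diff / eta;
        if (gain > best_gain) { best_gain = gain; j = t; }
      }
      if (j == n) break;  // no partner can make progress
      tried[j] = 1;

      // analytic two-variable update with box clipping
      double s = y(i) * y(j);
      double L, H;
      if (s > 0) {
        L = std::max(0.0, alpha(i) + alpha(j) - C);
        H = std::min(C, alpha(i) + alpha(j));
      } else {
        L = std::max(0.0, alpha(j) - alpha(i));
        H = std::min(C, C + alpha(j) - alpha(i));
      }
      if (H - L < eps_a) continue;
      double eta = std::max(diagK(i) + diagK(j) - 2.0 * K(i, j), 1e-12);
      double aj_new = alpha(j) + y(j) * (E(i) - E(j)) / eta;
      aj_new = std::min(std::max(aj_new, L), H);
      if (std::abs(aj_new - alpha(j)) < eps_a) continue;
      double ai_new = alpha(i) + s * (alpha(j) - aj_new);
      E += y(i) * (ai_new - alpha(i)) * K.col(i) +
           y(j) * (aj_new - alpha(j)) * K.col(j);
      alpha(i) = ai_new;
      alpha(j) = aj_new;
      moved = true;
    }
    if (!moved) break;  // progress floor reached; gap is near tolerance
  }

  return Rcpp::List::create(Rcpp::Named("alpha") = alpha,
                            Rcpp::Named("iterations") = iter,
                            Rcpp::Named("gap") = gap,
                            Rcpp::Named("converged") = converged);
}
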