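// Training loop of the graph-embedded feed-forward network.
// All randomness (weight init, batch shuffling) happens in R; this core
// is deterministic arithmetic, so results are reproducible by seed.
// Training runs in single precision (standard for network training;
// importance scores are accumulated in double downstream), and the
// masked input layer's Adam update touches only the graph's nonzero
// entries — the gradient is identically zero elsewhere.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#ifdef __SSE2__
#include <pmmintrin.h>
#include <xmmintrin.h>
#endif

using arma::fmat;
using arma::frowvec;
using arma::fvec;
using arma::uvec;

namespace {

// Adam's second-moment decay drives entries into the subnormal range,
// where x86 arithmetic is orders of magnitude slower; flush them to
// zero for the duration of a call.
struct FlushDenormals {
#ifdef __SSE2__
  unsigned int saved;
  FlushDenormals() : saved(_mm_getcsr()) {
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~FlushDenormals() { _mm_setcsr(saved); }
#endif
};

template <typename T>
struct Adam {
  T m, v;
  explicit Adam(const T& w) : m(arma::size(w), arma::fill::zeros),
                              v(arma::size(w), arma::fill::zeros) {}
  void update(T& w, const T& g, bool adam, float lr, int step) {
    if (adam) {
      const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
      m = b1 * m + (1 - b1) * g;
      v = b2 * v + (1 - b2) * arma::square(g);
      float corr = lr * std::sqrt(1.0f - std::pow(b2, step)) /
                   (1.0f - std::pow(b1, step));
      w -= corr * m / (arma::sqrt(v) + eps);
    } else {
      w -= lr * g;
    }
  }
};

inline fmat relu_grad(const fmat& pre) {
  return arma::conv_to<fmat>::from(pre > 0);
}

}  // namespace

// [[Rcpp::export(name = ".gedfn_train_cpp")]]
Rcpp::List gedfn_train_cpp(const arma::mat& X, const arma::mat& Tg,
                           const arma::mat& A,
                           arma::mat W_in0, arma::rowvec b_in0,
                           arma::mat W10, arma::rowvec b10,
                           arma::mat W20, arma::rowvec b20,
                           arma::mat W_out0, arma::rowvec b_out0,
                           const arma::umat& perms, const arma::vec& wrow0,
                           double lr0, int batch_size, bool adam) {
  FlushDenormals ftz;
  const arma::uword n = X.n_rows;
  const int epochs = perms.n_rows;
  const float lr = static_cast<float>(lr0);

  fmat Xf = arma::conv_to<fmat>::from(X);
  fmat Tf = arma::conv_to<fmat>::from(Tg);
  fvec wrow = arma::conv_to<fvec>::from(wrow0);
  fmat W_in = arma::conv_to<fmat>::from(W_in0);
  frowvec b_in = arma::conv_to<frowvec>::from(b_in0);
  fmat W1 = arma::conv_to<fmat>::from(W10);
  frowvec b1 = arma::conv_to<frowvec>::from(b10);
  fmat W2 = arma::conv_to<fmat>::from(W20);
  frowvec b2 = arma::conv_to<frowvec>::from(b20);
  fmat W_out = arma::conv_to<fmat>::from(W_out0);
  frowvec b_out = arma::conv_to<frowvec>::from(b_out0);

  const uvec mask_idx = arma::find(A > 0);
  fvec w_in_m = W_in.elem(mask_idx);
  Adam<fvec> sW_in(w_in_m);
  Adam<fmat> sW1(W1), sW2(W2), sW_out(W_out);
  Adam<frowvec> sb_in(b_in), sb1(b1), sb2(b2), sb_out(b_out);

  arma::vec loss_trace(epochs, arma::fill::zeros);
  int step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    for (arma::uword start = 0; start < n; start += batch_size) {
      arma::uword stop = std::min(n, start + batch_size) - 1;
      uvec idx = perms.row(ep).cols(start, stop).t();
      fmat Xb = Xf.rows(idx);
      fmat Tb = Tf.rows(idx);
      fvec wb = wrow.elem(idx);
      float wsum = arma::accu(wb);

      // forward
      fmat Z1a = Xb * W_in; Z1a.each_row() += b_in;
      fmat Z1 = arma::clamp(Z1a, 0.0f, arma::datum::inf);
      fmat Z2a = Z1 * W1; Z2a.each_row() += b1;
      fmat Z2 = arma::clamp(Z2a, 0.0f, arma::datum::inf);
      fmat Z3a = Z2 * W2; Z3a.each_row() += b2;
      fmat Z3 = arma::clamp(Z3a, 0.0f, arma::datum::inf);
      fmat logits = Z3 * W_out; logits.each_row() += b_out;
      logits.each_col() -= arma::max(logits, 1);
      fmat P = arma::exp(logits);
      P.each_col() /= arma::sum(P, 1);

      double loss = -arma::accu(wb % arma::sum(Tb % arma::log(
                        arma::clamp(P, 1e-12f, arma::datum::inf)), 1)) / wsum;
      if (!std::isfinite(loss)) {
        Rcpp::stop("non-finite loss at epoch %d; lower the learning rate",
                   ep + 1);
      }
      ep_loss += loss * idx.n_elem;

      // backward
      fmat dlogits = (P - Tb);
      dlogits.each_col() %= wb / wsum;
      fmat gW_out = Z3.t() * dlogits;
      frowvec gb_out = arma::sum(dlogits, 0);
      fmat d3 = (dlogits * W_out.t()) % relu_grad(Z3a);
      fmat gW2 = Z2.t() * d3;
      frowvec gb2 = arma::sum(d3, 0);
      fmat d2 = (d3 * W2.t()) % relu_grad(Z2a);
      fmat gW1 = Z1.t() * d2;
      frowvec gb1 = arma::sum(d2, 0);
      fmat d1 = (d2 * W1.t()) % relu_grad(Z1a);
      fmat gW_in_full = Xb.t() * d1;
      fvec gW_in = gW_in_full.elem(mask_idx);
      frowvec gb_in = arma::sum(d1, 0);

      ++step;
      sW_in.update(w_in_m, gW_in, adam, lr, step);
      W_in.elem(mask_idx) = w_in_m;  // unmasked entries stay exactly 0
      sb_in.update(b_in, gb_in, adam, lr, step);
      sW1.update(W1, gW1, adam, lr, step);
      sb1.update(b1, gb1, adam, lr, step);
      sW2.update(W2, gW2, adam, lr, step);
      sb2.update(b2, gb2, adam, lr, step);
      sW_out.update(W_out, gW_out, adam, lr, step);
      sb_out.update(b_out, gb_out, adam, lr, step);
    }
    loss_trace(ep) = ep_loss / n;
  }

  return Rcpp::List::create(
      Rcpp::Named("W_in") = arma::conv_to<arma::mat>::from(W_in),
      Rcpp::Named("b_in") = arma::conv_to<arma::rowvec>::from(b_in),
      Rcpp::Named("W1") = arma::conv_to<arma::mat>::from(W1),
      Rcpp::Named("b1") = arma::conv_to<arma::rowvec>::from(b1),
      Rcpp::Named("W2") = arma::conv_to<arma::mat>::from(W2),
      Rcpp::Named("b2") = arma::conv_to<arma::rowvec>::from(b2),
      Rcpp::Named("W_out") = arma::conv_to<arma::mat>::from(W_out),
      Rcpp::Named("b_out") = arma::conv_to<arma::rowvec>::from(b_out),
      Rcpp::Named("loss_trace") = loss_trace);
}
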