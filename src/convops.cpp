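// 1-D valid convolution (stride 1, no padding) forward and backward passes
// for small spectral regression networks. Activations live in channels-first
// layout: a batch is a (C, L, n) cube (channels x length x samples), so the
// kernel-offset decomposition of the convolution works on contiguous column
// views and every product maps onto a plain BLAS gemm without im2col copies:
//
//   out(f, p) = b(f) + sum_k sum_c W(c, f, k) * X(c, p + k)
//
// Weights are a (C, F, K) cube (input channels x filters x kernel position).
// Activation functions are applied in R; these routines return
// pre-activations and exact gradients.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".conv1d_forward")]]
arma::cube conv1d_forward(const arma::cube& X, const arma::cube& W,
                          const arma::vec& b) {
  const int n = X.n_slices;
  const int K = W.n_slices;
  const int F = W.n_cols;
  const int Lo = X.n_cols - K + 1;
  if (Lo < 1) Rcpp::stop("input shorter than the convolution kernel");
  if (X.n_rows != W.n_rows) Rcpp::stop("channel mismatch");
  cube out(F, Lo, n);
  mat acc(Lo, F);
  for (int s = 0; s < n; ++s) {
    acc.zeros();
    for (int k = 0; k < K; ++k) {
      acc += X.slice(s).cols(k, k + Lo - 1).t() * W.slice(k);
    }
    out.slice(s) = acc.t();
    out.slice(s).each_col() += b;
  }
  return out;
}

// [[Rcpp::export(name = ".conv1d_backward")]]
Rcpp::List conv1d_backward(const arma::cube& X, const arma::cube& W,
                           const arma::cube& dOut, bool need_dx) {
  const int n = X.n_slices;
  const int K = W.n_slices;
  const int F = W.n_cols;
  const int Lo = dOut.n_cols;
  cube dW(W.n_rows, F, K, fill::zeros);
  vec db(F, fill::zeros);
  cube dX;
  if (need_dx) dX.zeros(X.n_rows, X.n_cols, n);
  for (int s = 0; s < n; ++s) {
    const mat dT = dOut.slice(s).t();          // Lo x F
    db += sum(dOut.slice(s), 1);
    for (int k = 0; k < K; ++k) {
      dW.slice(k) += X.slice(s).cols(k, k + Lo - 1) * dT;
      if (need_dx) {
        dX.slice(s).cols(k, k + Lo - 1) += W.slice(k) * dOut.slice(s);
      }
    }
  }
  if (need_dx) {
    return Rcpp::List::create(Rcpp::Named("dW") = dW,
                              Rcpp::Named("db") = db,
                              Rcpp::Named("dX") = dX);
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
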