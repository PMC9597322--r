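// Multi-head softmax attention kernels for the growth model encoder.
// Activations arrive as (N * n_tok) x D matrices of doubles; each of the N
// token blocks is attended independently per head. The forward returns the
// mixed values plus the softmax probabilities the backward needs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List attn_fwd_cpp(const arma::mat& q, const arma::mat& k, const arma::mat& v,
                  int n_tok, int heads) {
  const int n_all = q.n_rows, D = q.n_cols;
  const int N = n_all / n_tok, dh = D / heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  arma::mat o(n_all, D);
  arma::cube attn(n_tok, n_tok, N * heads);
  for (int n = 0; n < N; ++n) {
    const int r0 = n * n_tok, r1 = r0 + n_tok - 1;
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * dh, c1 = c0 + dh - 1;
      arma::mat s = q.submat(r0, c0, r1, c1) *
                    k.submat(r0, c0, r1, c1).t() * scale;
      s.each_col() -= arma::max(s, 1);
      s = arma::exp(s);
      s.each_col() /= arma::sum(s, 1);
      attn.slice(n * heads + h) = s;
      o.submat(r0, c0, r1, c1) = s * v.submat(r0, c0, r1, c1);
    }
  }
  return List::create(_["o"] = o, _["attn"] = attn);
}

// [[Rcpp::export]]
List attn_bwd_cpp(const arma::mat& dout, const arma::mat& q,
                  const arma::mat& k, const arma::mat& v,
                  const arma::cube& attn, int n_tok, int heads) {
  const int n_all = q.n_rows, D = q.n_cols;
  const int N = n_all / n_tok, dh = D / heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  arma::mat dq(n_all, D), dk(n_all, D), dv(n_all, D);
  for (int n = 0; n < N; ++n) {
    const int r0 = n * n_tok, r1 = r0 + n_tok - 1;
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * dh, c1 = c0 + dh - 1;
      const arma::mat& a = attn.slice(n * heads + h);
      arma::mat doh = dout.submat(r0, c0, r1, c1);
      arma::mat da = doh * v.submat(r0, c0, r1, c1).t();
      dv.submat(r0, c0, r1, c1) = a.t() * doh;
      arma::vec rs = arma::sum(da % a, 1);
      da.each_col() -= rs;
      arma::mat ds = a % da;
      dq.submat(r0, c0, r1, c1) = ds * k.submat(r0, c0, r1, c1) * scale;
      dk.submat(r0, c0, r1, c1) = ds.t() * q.submat(r0, c0, r1, c1) * scale;
    }
  }
  return List::create(_["dq"] = dq, _["dk"] = dk, _["dv"] = dv);
}

// y = x + row-broadcast bias, without an R-side allocation per call
// [[Rcpp::export]]
arma::mat add_rowvec_cpp(const arma::mat& x, const arma::rowvec& b) {
  arma::mat y = x;
  y.each_row() += b;
  return y;
}

// y = x * diag(g) + row-broadcast b (the layer-norm affine part)
// [[Rcpp::export]]
arma::mat scale_shift_rows_cpp(const arma::mat& x, const arma::rowvec& g,
                               const arma::rowvec& b) {
  arma::mat y = x;
  y.each_row() %= g;
  y.each_row() += b;
  return y;
}

// y = x * diag(g)
// [[Rcpp::export]]
arma::mat mul_rowvec_cpp(const arma::mat& x, const arma::rowvec& g) {
  arma::mat y = x;
  y.each_row() %= g;
  return y;
}

// row-wise layer normalisation: y = g * (x - mu) / sigma + b
// [[Rcpp::export]]
List layernorm_fwd_cpp(const arma::mat& x, const arma::rowvec& g,
                       const arma::rowvec& b, double eps) {
  arma::vec mu = arma::mean(x, 1);
  arma::mat xc = x.each_col() - mu;
  arma::vec inv = 1.0 / arma::sqrt(arma::mean(xc % xc, 1) + eps);
  arma::mat xhat = xc.each_col() % inv;
  arma::mat y = xhat;
  y.each_row() %= g;
  y.each_row() += b;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export]]
List layernorm_bwd_cpp(const arma::mat& dy, const arma::mat& xhat,
                       const arma::vec& inv, const arma::rowvec& g) {
  arma::mat dxhat = dy;
  dxhat.each_row() %= g;
  arma::rowvec dg = arma::sum(dy % xhat, 0);
  arma::rowvec db = arma::sum(dy, 0);
  arma::vec m1 = arma::mean(dxhat, 1);
  arma::vec m2 = arma::mean(dxhat % xhat, 1);
  arma::mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= inv;
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}

// GELU (sigmoid approximation) and its derivative
// [[Rcpp::export]]
arma::mat gelu_cpp(const arma::mat& x) {
  arma::mat s = 1.0 / (1.0 + arma::exp(-1.702 * x));
  return x % s;
}

// [[Rcpp::export]]
arma::mat gelu_grad_cpp(const arma::mat& x) {
  arma::mat s = 1.0 / (1.0 + arma::exp(-1.702 * x));
  return s % (1.0 + 1.702 * x % (1.0 - s));
}

// fused AdamW update, in place on p/m/v (freshly owned R vectors)
// [[Rcpp::export]]
void adamw_update_cpp(NumericVector p, NumericVector g, NumericVector m,
                      NumericVector v, double lr, double wd, double beta1,
                      double beta2, double eps, double bc1, double bc2) {
  const R_xlen_t n = p.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = beta1 * m[i] + (1 - beta1) * g[i];
    v[i] = beta2 * v[i] + (1 - beta2) * g[i] * g[i];
    p[i] -= lr * ((m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps) + wd * p[i]);
  }
}
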