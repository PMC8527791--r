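// Compiled kernels for the neural-network engine hot paths: dilated 1D
// convolution (im2col + GEMM), batch normalisation, ReLU and the fused Adam
// step. Shapes mirror the R side: convolutional activations are (channels,
// length, batch) cubes, dense activations (features, batch) matrices; R's
// column-major layout matches Armadillo's, so data crosses the boundary
// without copies beyond what Rcpp requires.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Build the im2col matrix (C*k rows, L*B cols) of a zero-padded dilated
// convolution with "same" padding, stride 1.
static arma::mat im2col_dilated(const arma::cube& x, int k, int dil) {
  const int C = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int pad = (k - 1) / 2 * dil;
  arma::mat xc(C * k, (size_t)L * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const double* xb = x.slice_colptr(b, 0);
    for (int kk = 0; kk < k; ++kk) {
      const int off = kk * dil - pad;  // source l = l_out + off
      const int lo = std::max(0, -off), hi = std::min(L, L - off);
      for (int l = lo; l < hi; ++l) {
        std::memcpy(xc.colptr((size_t)b * L + l) + (size_t)kk * C,
                    xb + (size_t)(l + off) * C, sizeof(double) * C);
      }
    }
  }
  return xc;
}

// [[Rcpp::export]]
List cpp_conv1d_fwd(const arma::cube& x, const arma::mat& w,
                    const arma::vec& b, int k, int dil) {
  const int L = x.n_cols, B = x.n_slices, out_ch = w.n_rows;
  arma::mat xc = im2col_dilated(x, k, dil);
  arma::mat y = w * xc;
  y.each_col() += b;
  arma::cube out(y.memptr(), out_ch, L, B);
  return List::create(_["out"] = out, _["xc"] = xc);
}

// [[Rcpp::export]]
List cpp_conv1d_bwd(const arma::cube& dout, const arma::mat& xc,
                    const arma::mat& w, int C, int k, int dil) {
  const int out_ch = dout.n_rows, L = dout.n_cols, B = dout.n_slices;
  const int pad = (k - 1) / 2 * dil;
  arma::mat dmat(const_cast<double*>(dout.memptr()), out_ch, (size_t)L * B,
                 false, true);
  arma::mat dW = dmat * xc.t();
  arma::vec db = arma::sum(dmat, 1);
  arma::mat dxc = w.t() * dmat;            // (C*k, L*B)
  arma::cube dx(C, L, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    double* dxb = dx.slice_colptr(b, 0);
    for (int kk = 0; kk < k; ++kk) {
      const int off = kk * dil - pad;
      const int lo = std::max(0, -off), hi = std::min(L, L - off);
      for (int l = lo; l < hi; ++l) {
        const double* src = dxc.colptr((size_t)b * L + l) + (size_t)kk * C;
        double* dst = dxb + (size_t)(l + off) * C;
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// Batch norm over a (C, N) matrix view of the activations, N = length*batch.
// Channel counts are small relative to N, so accumulation runs in explicit
// column-major loops rather than per-column vector views.
// [[Rcpp::export]]
List cpp_bn_fwd(const arma::mat& x, const arma::vec& gamma,
                const arma::vec& beta, double eps) {
  const arma::uword C = x.n_rows, N = x.n_cols;
  arma::vec mu(C, arma::fill::zeros), v(C, arma::fill::zeros);
  const double* px = x.memptr();
  for (arma::uword j = 0; j < N; ++j) {
    const double* col = px + j * C;
    for (arma::uword c = 0; c < C; ++c) mu[c] += col[c];
  }
  mu /= (double)N;
  for (arma::uword j = 0; j < N; ++j) {
    const double* col = px + j * C;
    for (arma::uword c = 0; c < C; ++c) {
      const double d = col[c] - mu[c];
      v[c] += d * d;
    }
  }
  v /= (double)N;
  arma::vec invstd = 1.0 / arma::sqrt(v + eps);
  arma::mat xhat(C, N), out(C, N);
  double* ph = xhat.memptr(); double* po = out.memptr();
  for (arma::uword j = 0; j < N; ++j) {
    const double* col = px + j * C;
    double* hc = ph + j * C; double* oc = po + j * C;
    for (arma::uword c = 0; c < C; ++c) {
      hc[c] = (col[c] - mu[c]) * invstd[c];
      oc[c] = gamma[c] * hc[c] + beta[c];
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["mu"] = mu, _["var"] = v);
}

// [[Rcpp::export]]
List cpp_bn_bwd(const arma::mat& dout, const arma::mat& xhat,
                const arma::vec& invstd, const arma::vec& gamma) {
  const arma::uword C = dout.n_rows, N = dout.n_cols;
  arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  const double* pd = dout.memptr(); const double* ph = xhat.memptr();
  for (arma::uword j = 0; j < N; ++j) {
    const double* dc = pd + j * C; const double* hc = ph + j * C;
    for (arma::uword c = 0; c < C; ++c) {
      dgamma[c] += dc[c] * hc[c];
      dbeta[c] += dc[c];
    }
  }
  // means of dxhat and dxhat*xhat per channel, dxhat = gamma * dout
  arma::vec m1 = gamma % dbeta / (double)N;
  arma::vec m2 = gamma % dgamma / (double)N;
  arma::mat dx(C, N);
  double* pdx = dx.memptr();
  for (arma::uword j = 0; j < N; ++j) {
    const double* dc = pd + j * C; const double* hc = ph + j * C;
    double* xc = pdx + j * C;
    for (arma::uword c = 0; c < C; ++c)
      xc[c] = invstd[c] * (gamma[c] * dc[c] - m1[c] - hc[c] * m2[c]);
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector out(clone(x));
  const R_xlen_t n = out.size();
  double* p = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
  out.attr("dim") = x.attr("dim");
  return out;
}

// Backward uses the forward output: gradient passes where out > 0.
// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dout, NumericVector out) {
  NumericVector dx(clone(dout));
  const R_xlen_t n = dx.size();
  double* p = REAL(dx);
  const double* o = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) if (o[i] <= 0) p[i] = 0;
  dx.attr("dim") = dout.attr("dim");
  return dx;
}

// One fused Adam step. The parameter vector is cloned because callers
// snapshot parameter states (early-stopping checkpoints must not alias the
// live weights); the moment buffers are owned solely by the optimiser state
// and are updated in place.
// [[Rcpp::export]]
List cpp_adam_step(NumericVector p, NumericVector m, NumericVector v,
                   NumericVector g, double lr_t, double beta1, double beta2,
                   double eps) {
  const R_xlen_t n = p.size();
  NumericVector p2(clone(p));
  double* pp = REAL(p2); double* pm = REAL(m); double* pv = REAL(v);
  const double* pg = REAL(g);
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = beta1 * pm[i] + (1 - beta1) * pg[i];
    pv[i] = beta2 * pv[i] + (1 - beta2) * pg[i] * pg[i];
    pp[i] -= lr_t * pm[i] / (std::sqrt(pv[i]) + eps);
  }
  p2.attr("dim") = p.attr("dim");
  return List::create(_["p"] = p2, _["m"] = m, _["v"] = v);
}
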