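// Hot kernels for the 1D CNN: im2col convolution (fused with ReLU)
// forward/backward and max-pool-of-4, on channel-major (C, L, B)
// activation vectors.
//
// Layout conventions (0-based):
//   activation element (c, l, b)   -> x[c + l*C + b*C*L]
//   weight matrix W: F x (C*K), column index c + k*C
//   conv output: (F, L_out, B) layout, i.e. y[f + p*F + b*F*L_out]
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::vec& x, int C, int L, int B, int K) {
  const int Lo = L - K + 1;
  arma::mat Xcol(C * K, (size_t)Lo * B);
  for (int b = 0; b < B; ++b) {
    const double* xb = x.memptr() + (size_t)b * C * L;
    for (int p = 0; p < Lo; ++p) {
      double* col = Xcol.colptr((size_t)b * Lo + p);
      std::memcpy(col, xb + (size_t)p * C, sizeof(double) * C * K);
    }
  }
  return Xcol;
}

// convolution + bias + optional ReLU; returns the activated output (as a
// flat (F, L_out, B) vector) and the im2col matrix for the backward pass
// [[Rcpp::export(name = ".conv_relu_fwd")]]
List conv_relu_fwd(const arma::vec& x, const arma::mat& W,
                   const arma::vec& bias, int C, int L, int B, int K,
                   bool relu) {
  arma::mat Xcol = im2col(x, C, L, B, K);
  arma::mat Y = W * Xcol;
  Y.each_col() += bias;
  if (relu) Y.transform([](double v) { return v > 0.0 ? v : 0.0; });
  return List::create(_["out"] = arma::vec(Y.memptr(), Y.n_elem),
                      _["Xcol"] = Xcol);
}

// backward through ReLU (mask = out > 0) and the convolution
// [[Rcpp::export(name = ".conv_relu_bwd")]]
List conv_relu_bwd(const arma::vec& dout, const arma::vec& out,
                   const arma::mat& Xcol, const arma::mat& W,
                   int C, int L, int B, int K, bool relu, bool need_dx) {
  const int Lo = L - K + 1;
  const int F = W.n_rows;
  arma::mat dY(F, (size_t)Lo * B);
  if (relu) {
    for (size_t i = 0; i < dout.n_elem; ++i) {
      dY[i] = out[i] > 0.0 ? dout[i] : 0.0;
    }
  } else {
    std::memcpy(dY.memptr(), dout.memptr(), sizeof(double) * dout.n_elem);
  }
  arma::mat dW = dY * Xcol.t();
  arma::vec db = arma::sum(dY, 1);
  if (!need_dx) {
    return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = R_NilValue);
  }
  arma::mat dXcol = W.t() * dY;           // (C*K, Lo*B)
  arma::vec dx((size_t)C * L * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    double* xb = dx.memptr() + (size_t)b * C * L;
    for (int p = 0; p < Lo; ++p) {
      const double* col = dXcol.colptr((size_t)b * Lo + p);
      double* dst = xb + (size_t)p * C;
      for (int i = 0; i < C * K; ++i) dst[i] += col[i];
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dx);
}

// [[Rcpp::export(name = ".pool4_fwd")]]
List pool4_fwd_cpp(const arma::vec& x, int C, int L, int B) {
  const int Lp = L / 4;
  arma::vec out((size_t)C * Lp * B);
  IntegerVector amax((size_t)C * Lp * B);   // 0-based index into x
  size_t o = 0;
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < Lp; ++j) {
      const size_t base = (size_t)b * C * L + (size_t)j * 4 * C;
      for (int c = 0; c < C; ++c, ++o) {
        size_t best = base + c;
        double mv = x[best];
        for (int k = 1; k < 4; ++k) {
          const size_t idx = base + (size_t)k * C + c;
          if (x[idx] > mv) { mv = x[idx]; best = idx; }
        }
        out[o] = mv;
        amax[o] = (int)best;
      }
    }
  }
  return List::create(_["out"] = out, _["amax"] = amax);
}

// [[Rcpp::export(name = ".pool4_bwd")]]
arma::vec pool4_bwd_cpp(const arma::vec& dy, const IntegerVector& amax,
                        int len) {
  arma::vec dx(len, arma::fill::zeros);
  for (int i = 0; i < (int)dy.n_elem; ++i) dx[amax[i]] += dy[i];
  return dx;
}
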