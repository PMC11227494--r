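#include <Rcpp.h>
using namespace Rcpp;

// Activation tensors are R arrays with dim = (H, W, T, N, C).
// im2col unrolls every output position of a 3D convolution into a row of a
// matrix whose columns run over (kh, kw, kt, c_in) in column-major order, so
// that  Y = im2col(x) %*% matrix(W, kh*kw*kt*Cin, Cout)  gives an array with
// dim = (oH, oW, oT, N, Cout) after a single dim<- assignment.

// [[Rcpp::export]]
NumericMatrix im2col3d(NumericVector x, IntegerVector xdim, IntegerVector kdim,
                       IntegerVector stride, IntegerVector pad) {
  const int H = xdim[0], W = xdim[1], T = xdim[2], N = xdim[3], C = xdim[4];
  const int kh = kdim[0], kw = kdim[1], kt = kdim[2];
  const int sh = stride[0], sw = stride[1], st = stride[2];
  const int ph = pad[0], pw = pad[1], pt = pad[2];
  const int oH = (H + 2 * ph - kh) / sh + 1;
  const int oW = (W + 2 * pw - kw) / sw + 1;
  const int oT = (T + 2 * pt - kt) / st + 1;
  const R_xlen_t nrow = (R_xlen_t)oH * oW * oT * N;
  const R_xlen_t ncol = (R_xlen_t)kh * kw * kt * C;
  NumericMatrix out((int)nrow, (int)ncol);
  const double* xp = REAL(x);
  double* op = REAL(out);
  const R_xlen_t strW = H, strT = (R_xlen_t)H * W;
  const R_xlen_t strN = (R_xlen_t)H * W * T, strC = (R_xlen_t)H * W * T * N;
  for (int c = 0; c < C; ++c) {
    for (int dt = 0; dt < kt; ++dt) {
      for (int dw = 0; dw < kw; ++dw) {
        for (int dh = 0; dh < kh; ++dh) {
          const R_xlen_t col = dh + (R_xlen_t)kh * (dw + (R_xlen_t)kw * (dt + (R_xlen_t)kt * c));
          double* ocol = op + col * nrow;
          R_xlen_t r = 0;
          for (int n = 0; n < N; ++n) {
            const R_xlen_t basen = (R_xlen_t)n * strN + (R_xlen_t)c * strC;
            for (int ot = 0; ot < oT; ++ot) {
              const int it = ot * st + dt - pt;
              const bool tok = (it >= 0 && it < T);
              for (int ow = 0; ow < oW; ++ow) {
                const int iw = ow * sw + dw - pw;
                const bool wok = tok && (iw >= 0 && iw < W);
                const R_xlen_t base = basen + (R_xlen_t)it * strT + (R_xlen_t)iw * strW;
                for (int oh = 0; oh < oH; ++oh) {
                  const int ih = oh * sh + dh - ph;
                  ocol[r++] = (wok && ih >= 0 && ih < H) ? xp[base + ih] : 0.0;
                }
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add adjoint of im2col3d: accumulates a (positions x kelems) gradient
// matrix back into an input-shaped gradient tensor.

// [[Rcpp::export]]
NumericVector col2im3d(NumericMatrix cols, IntegerVector xdim, IntegerVector kdim,
                       IntegerVector stride, IntegerVector pad) {
  const int H = xdim[0], W = xdim[1], T = xdim[2], N = xdim[3], C = xdim[4];
  const int kh = kdim[0], kw = kdim[1], kt = kdim[2];
  const int sh = stride[0], sw = stride[1], st = stride[2];
  const int ph = pad[0], pw = pad[1], pt = pad[2];
  const int oH = (H + 2 * ph - kh) / sh + 1;
  const int oW = (W + 2 * pw - kw) / sw + 1;
  const int oT = (T + 2 * pt - kt) / st + 1;
  const R_xlen_t nrow = (R_xlen_t)oH * oW * oT * N;
  NumericVector gx((R_xlen_t)H * W * T * N * C);
  double* gp = REAL(gx);
  const double* cp = REAL(cols);
  const R_xlen_t strW = H, strT = (R_xlen_t)H * W;
  const R_xlen_t strN = (R_xlen_t)H * W * T, strC = (R_xlen_t)H * W * T * N;
  for (int c = 0; c < C; ++c) {
    for (int dt = 0; dt < kt; ++dt) {
      for (int dw = 0; dw < kw; ++dw) {
        for (int dh = 0; dh < kh; ++dh) {
          const R_xlen_t col = dh + (R_xlen_t)kh * (dw + (R_xlen_t)kw * (dt + (R_xlen_t)kt * c));
          const double* ccol = cp + col * nrow;
          R_xlen_t r = 0;
          for (int n = 0; n < N; ++n) {
            const R_xlen_t basen = (R_xlen_t)n * strN + (R_xlen_t)c * strC;
            for (int ot = 0; ot < oT; ++ot) {
              const int it = ot * st + dt - pt;
              const bool tok = (it >= 0 && it < T);
              for (int ow = 0; ow < oW; ++ow) {
                const int iw = ow * sw + dw - pw;
                const bool wok = tok && (iw >= 0 && iw < W);
                const R_xlen_t base = basen + (R_xlen_t)it * strT + (R_xlen_t)iw * strW;
                for (int oh = 0; oh < oH; ++oh, ++r) {
                  const int ih = oh * sh + dh - ph;
                  if (wok && ih >= 0 && ih < H) gp[base + ih] += ccol[r];
                }
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  return gx;
}
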