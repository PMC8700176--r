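// Valid (no-padding) 2-D cross-correlation primitives for the deblurring
// networks.  Batched NHWC-like layout in R's column-major order:
//   x : (H, W, Cin, N)    w : (kh, kw, Cin, Cout)    y : (OH, OW, Cout, N)
// Forward and backward are implemented as im2col + GEMM so that BLAS
// carries the arithmetic; samples are grouped into chunks sharing one
// lowered matrix so the GEMMs stay large.  Gradients follow the same
// lowering: gw = Xcol' * Gy, gx = col2im(Gy * W').

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void get_dims4(const NumericVector &a, int d[4]) {
  IntegerVector dim = a.attr("dim");
  if (dim.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

// Fill rows [n0*P, (n0+cnt)*P) of the lowered matrix Xc ((cnt*P) x K) from
// samples n0 .. n0+cnt-1.  P = OH*OW indexed p = oh + OH*ow; K = kh*kw*Cin
// indexed k = i + kh*(j + kw*c).
static void im2col_chunk(const double *x, int H, int W, int C,
                         int n0, int cnt, int kh, int kw, int OH, int OW,
                         arma::mat &Xc) {
  const int P = OH * OW;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int k = i + kh * (j + kw * c);
        double *col = Xc.colptr(k);
        for (int s = 0; s < cnt; ++s) {
          const double *xn = x + (std::size_t)(n0 + s) * H * W * C +
            (std::size_t)c * H * W;
          double *dst = col + (std::size_t)s * P;
          for (int ow = 0; ow < OW; ++ow)
            std::memcpy(dst + (std::size_t)ow * OH,
                        xn + (std::size_t)(ow + j) * H + i,
                        sizeof(double) * OH);
        }
      }
}

// Scatter-add the lowered gradient Gx ((cnt*P) x K) back into samples
// n0 .. n0+cnt-1 of the input-gradient array.
static void col2im_chunk(const arma::mat &Gx, double *gx, int H, int W, int C,
                         int n0, int cnt, int kh, int kw, int OH, int OW) {
  const int P = OH * OW;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int k = i + kh * (j + kw * c);
        const double *col = Gx.colptr(k);
        for (int s = 0; s < cnt; ++s) {
          double *gn = gx + (std::size_t)(n0 + s) * H * W * C +
            (std::size_t)c * H * W;
          const double *src = col + (std::size_t)s * P;
          for (int ow = 0; ow < OW; ++ow) {
            double *dst = gn + (std::size_t)(ow + j) * H + i;
            const double *sc = src + (std::size_t)ow * OH;
            for (int oh = 0; oh < OH; ++oh) dst[oh] += sc[oh];
          }
        }
      }
}


// The lowered GEMM result has rows (sample, pixel) interleaved; scatter it
// back to the (OH, OW, Cout, N) array layout (and gather for gradients).
static void scatter_y(const arma::mat &Yt, double *y, int n0, int cnt,
                      int P, int Cout) {
  for (int s = 0; s < cnt; ++s)
    for (int co = 0; co < Cout; ++co)
      std::memcpy(y + ((std::size_t)(n0 + s) * Cout + co) * P,
                  Yt.colptr(co) + (std::size_t)s * P, sizeof(double) * P);
}

static void gather_gy(const double *gy, arma::mat &Gt, int n0, int cnt,
                      int P, int Cout) {
  for (int s = 0; s < cnt; ++s)
    for (int co = 0; co < Cout; ++co)
      std::memcpy(Gt.colptr(co) + (std::size_t)s * P,
                  gy + ((std::size_t)(n0 + s) * Cout + co) * P,
                  sizeof(double) * P);
}

// Samples per chunk so the lowered matrix stays within ~6e5 doubles (cache-friendly).
static int chunk_size(int N, int P, int K) {
  double cap = 6e5 / ((double)P * K);
  int c = (int)cap;
  if (c < 1) c = 1;
  if (c > N) c = N;
  return c;
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w, NumericVector b) {
  int dx[4], dw[4];
  get_dims4(x, dx); get_dims4(w, dw);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  if (dw[2] != C) stop("input channels (%d) do not match filter channels (%d)", C, dw[2]);
  if (b.size() != Cout) stop("bias length must equal the number of output channels");
  const int OH = H - kh + 1, OW = W - kw + 1;
  if (OH < 1 || OW < 1) stop("input (%dx%d) smaller than filter (%dx%d)", H, W, kh, kw);
  const int P = OH * OW, K = kh * kw * C;

  NumericVector y((std::size_t)P * Cout * N);
  y.attr("dim") = IntegerVector::create(OH, OW, Cout, N);
  arma::mat Wm(const_cast<double *>(w.begin()), K, Cout, false, true);
  const int chunk = chunk_size(N, P, K);
  arma::mat Xc((std::size_t)chunk * P, K), Yt;
  for (int n0 = 0; n0 < N; n0 += chunk) {
    const int cnt = std::min(chunk, N - n0);
    arma::mat Xv(Xc.memptr(), (std::size_t)cnt * P, K, false, true);
    im2col_chunk(x.begin(), H, W, C, n0, cnt, kh, kw, OH, OW, Xv);
    Yt = Xv * Wm;
    for (int co = 0; co < Cout; ++co) Yt.col(co) += b[co];
    scatter_y(Yt, y.begin(), n0, cnt, P, Cout);
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector gy,
                         bool need_gx) {
  int dx[4], dw[4], dy[4];
  get_dims4(x, dx); get_dims4(w, dw); get_dims4(gy, dy);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  const int OH = dy[0], OW = dy[1];
  if (dw[2] != C) stop("filter/input channel mismatch");
  if (dy[2] != Cout || dy[3] != N || OH != H - kh + 1 || OW != W - kw + 1)
    stop("gradient dimensions inconsistent with input and filter");
  const int P = OH * OW, K = kh * kw * C;

  NumericVector gw((std::size_t)K * Cout);
  gw.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  NumericVector gb(Cout);
  NumericVector gx(need_gx ? (std::size_t)H * W * C * N : 1);
  if (need_gx) {
    gx.attr("dim") = IntegerVector::create(H, W, C, N);
    std::fill(gx.begin(), gx.end(), 0.0);
  }

  arma::mat Wm(const_cast<double *>(w.begin()), K, Cout, false, true);
  arma::mat Gw(gw.begin(), K, Cout, false, true);
  arma::vec Gb(gb.begin(), Cout, false, true);
  const int chunk = chunk_size(N, P, K);
  arma::mat Xc((std::size_t)chunk * P, K), Gxc, Gt((std::size_t)chunk * P, Cout);
  if (need_gx) Gxc.set_size((std::size_t)chunk * P, K);
  for (int n0 = 0; n0 < N; n0 += chunk) {
    const int cnt = std::min(chunk, N - n0);
    arma::mat Xv(Xc.memptr(), (std::size_t)cnt * P, K, false, true);
    im2col_chunk(x.begin(), H, W, C, n0, cnt, kh, kw, OH, OW, Xv);
    arma::mat Gy(Gt.memptr(), (std::size_t)cnt * P, Cout, false, true);
    gather_gy(gy.begin(), Gy, n0, cnt, P, Cout);
    Gw += Xv.t() * Gy;
    Gb += arma::sum(Gy, 0).t();
    if (need_gx) {
      arma::mat Gv(Gxc.memptr(), (std::size_t)cnt * P, K, false, true);
      Gv = Gy * Wm.t();
      col2im_chunk(Gv, gx.begin(), H, W, C, n0, cnt, kh, kw, OH, OW);
    }
  }
  if (need_gx)
    return List::create(_["gw"] = gw, _["gb"] = gb, _["gx"] = gx);
  return List::create(_["gw"] = gw, _["gb"] = gb);
}
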