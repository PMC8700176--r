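// Mini-batch momentum-SGD engine for the deblurring networks.
//
// Master weights and velocities are kept in double precision (so a zero
// learning rate is an exact no-op and segmented calls continue exactly);
// activations and GEMMs run in single precision, lowered through im2col
// in cache-sized chunks.  Supports the plain sequential networks and the
// densely connected, deeply supervised variant (center-crop + concat of
// earlier feature maps, 1x1 prediction heads with weighted companion
// losses).  The double-precision R implementation of the same forward /
// backward pass serves as the reference this engine is tested against.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

typedef std::vector<float> fvecbuf;

// im2col on a float (H, W, C, N) buffer restricted to samples
// [n0, n0 + cnt): rows p = oh + OH*ow (+ sample offset), cols
// k = i + kh*(j + kw*c).
static void im2col_f(const float *x, int H, int W, int C, int n0, int cnt,
                     int kh, int kw, int OH, int OW, arma::fmat &Xc) {
  const int P = OH * OW;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int k = i + kh * (j + kw * c);
        float *col = Xc.colptr(k);
        for (int s = 0; s < cnt; ++s) {
          const float *xn = x + (std::size_t)(n0 + s) * H * W * C +
            (std::size_t)c * H * W;
          float *dst = col + (std::size_t)s * P;
          for (int ow = 0; ow < OW; ++ow)
            std::memcpy(dst + (std::size_t)ow * OH,
                        xn + (std::size_t)(ow + j) * H + i,
                        sizeof(float) * OH);
        }
      }
}

static void col2im_f(const arma::fmat &Gx, float *gx, int H, int W, int C,
                     int n0, int cnt, int kh, int kw, int OH, int OW) {
  const int P = OH * OW;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int k = i + kh * (j + kw * c);
        const float *col = Gx.colptr(k);
        for (int s = 0; s < cnt; ++s) {
          float *gn = gx + (std::size_t)(n0 + s) * H * W * C +
            (std::size_t)c * H * W;
          const float *src = col + (std::size_t)s * P;
          for (int ow = 0; ow < OW; ++ow) {
            float *dst = gn + (std::size_t)(ow + j) * H + i;
            const float *sc = src + (std::size_t)ow * OH;
            for (int oh = 0; oh < OH; ++oh) dst[oh] += sc[oh];
          }
        }
      }
}


// Scatter a lowered GEMM result ((cnt*P) x Cout) back to the
// (OH, OW, Cout, N) buffer layout, and gather the reverse for gradients.
static void scatter_y_f(const arma::fmat &Yt, float *y, int n0, int cnt,
                        int P, int Cout) {
  for (int s = 0; s < cnt; ++s)
    for (int co = 0; co < Cout; ++co)
      std::memcpy(y + ((std::size_t)(n0 + s) * Cout + co) * P,
                  Yt.colptr(co) + (std::size_t)s * P, sizeof(float) * P);
}

static void gather_gy_f(const float *gy, arma::fmat &Gt, int n0, int cnt,
                        int P, int Cout) {
  for (int s = 0; s < cnt; ++s)
    for (int co = 0; co < Cout; ++co)
      std::memcpy(Gt.colptr(co) + (std::size_t)s * P,
                  gy + ((std::size_t)(n0 + s) * Cout + co) * P,
                  sizeof(float) * P);
}

static int chunk_size_f(int N, int P, int K) {
  int c = (int)(1.2e6 / ((double)P * K));
  if (c < 1) c = 1;
  if (c > N) c = N;
  return c;
}

// Copy the centered s x s crop of channels of src (S, S, C, N) into dst at
// channel offset c_off of a (s, s, Cdst, N) buffer.
static void crop_into(const float *src, int S, int C, int N, int s,
                      float *dst, int Cdst, int c_off) {
  const int m = (S - s) / 2;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const float *sp = src + ((std::size_t)n * C + c) * S * S;
      float *dp = dst + ((std::size_t)n * Cdst + c_off + c) * s * s;
      for (int col = 0; col < s; ++col)
        std::memcpy(dp + (std::size_t)col * s,
                    sp + (std::size_t)(col + m) * S + m, sizeof(float) * s);
    }
}

// Adjoint of crop_into: add the (s, s, C, N) block at channel offset c_off
// of src back into the center of dst (S, S, C, N).
static void uncrop_add(const float *src, int s, int Csrc, int c_off, int N,
                       float *dst, int S, int C) {
  const int m = (S - s) / 2;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const float *sp = src + ((std::size_t)n * Csrc + c_off + c) * s * s;
      float *dp = dst + ((std::size_t)n * C + c) * S * S;
      for (int col = 0; col < s; ++col) {
        float *d = dp + (std::size_t)(col + m) * S + m;
        const float *so = sp + (std::size_t)col * s;
        for (int r = 0; r < s; ++r) d[r] += so[r];
      }
    }
}

struct ParamF {
  arma::mat Wd;   // master weights, K x Cout, double
  arma::vec bd;
  arma::mat vW;   // velocities
  arma::vec vb;
  arma::fmat Wf;  // float working copy
  arma::fvec bf;
  arma::fmat gW;  // float gradient accumulator
  arma::fvec gb;
  void refresh() {
    Wf = arma::conv_to<arma::fmat>::from(Wd);
    bf = arma::conv_to<arma::fvec>::from(bd);
  }
  void step(double lr, double mom) {
    vW = mom * vW - lr * arma::conv_to<arma::mat>::from(gW);
    vb = mom * vb - lr * arma::conv_to<arma::vec>::from(gb);
    Wd += vW; bd += vb;
    refresh();
  }
};

// [[Rcpp::export(name = ".train_sgd")]]
List train_sgd_cpp(List layer_w, List head_w_in, IntegerVector kernels,
                   IntegerVector channels, IntegerVector in_channels,
                   LogicalVector relu, bool dense, IntegerVector head_stages,
                   NumericVector head_loss_w, NumericVector inputs,
                   NumericVector labels, IntegerMatrix batch_idx,
                   double lr, double momentum, int reduction,
                   Nullable<List> vel_state) {
  const int L = kernels.size();
  const int n_heads = head_stages.size();
  IntegerVector din = inputs.attr("dim");
  IntegerVector dlab = labels.attr("dim");
  const int S0 = din[0], Ntot = din[2];
  const int Klab = dlab[0];
  const int B = batch_idx.nrow();
  const int iters = batch_idx.ncol();

  // layer spatial sizes
  std::vector<int> s_in(L), s_out(L);
  int s = S0;
  for (int l = 0; l < L; ++l) {
    s_in[l] = (l == 0) ? S0 : s_out[l - 1];
    s_out[l] = s_in[l] - kernels[l] + 1;
  }
  if (s_out[L - 1] != Klab)
    stop("label size %d does not match network output %d", Klab, s_out[L - 1]);
  const int s_last = s_out[L - 1];

  // parameters
  std::vector<ParamF> par(L), hpar(n_heads);
  for (int l = 0; l < L; ++l) {
    List lw = layer_w[l];
    NumericVector W = lw["W"], b = lw["b"];
    const int K = kernels[l] * kernels[l] * in_channels[l];
    par[l].Wd = arma::mat(W.begin(), K, channels[l]);
    par[l].bd = arma::vec(b.begin(), channels[l]);
    par[l].vW = arma::zeros(K, channels[l]);
    par[l].vb = arma::zeros(channels[l]);
    par[l].refresh();
  }
  for (int h = 0; h < n_heads; ++h) {
    List hw = head_w_in[h];
    NumericVector W = hw["W"], b = hw["b"];
    const int cin = channels[head_stages[h] - 1];
    hpar[h].Wd = arma::mat(W.begin(), cin, 1);
    hpar[h].bd = arma::vec(b.begin(), 1);
    hpar[h].vW = arma::zeros(cin, 1);
    hpar[h].vb = arma::zeros(1);
    hpar[h].refresh();
  }
  if (vel_state.isNotNull()) {
    List vs(vel_state);
    List vl = vs["layers"];
    for (int l = 0; l < L; ++l) {
      List v = vl[l];
      NumericVector vW = v["W"], vb = v["b"];
      std::copy(vW.begin(), vW.end(), par[l].vW.memptr());
      std::copy(vb.begin(), vb.end(), par[l].vb.memptr());
    }
    List vh = vs["heads"];
    for (int h = 0; h < n_heads; ++h) {
      List v = vh[h];
      NumericVector vW = v["W"], vb = v["b"];
      std::copy(vW.begin(), vW.end(), hpar[h].vW.memptr());
      std::copy(vb.begin(), vb.end(), hpar[h].vb.memptr());
    }
  }

  // dataset in float
  fvecbuf xall(inputs.begin(), inputs.end());
  fvecbuf yall(labels.begin(), labels.end());

  // batch buffers
  fvecbuf xb((std::size_t)S0 * S0 * B), yb((std::size_t)Klab * Klab * B);
  std::vector<fvecbuf> feats(L), gfeat(L), inp(L), ginp(L);
  for (int l = 0; l < L; ++l) {
    feats[l].resize((std::size_t)s_out[l] * s_out[l] * channels[l] * B);
    gfeat[l].resize(feats[l].size());
    if (l > 0 && (dense || true)) {
      inp[l].resize((std::size_t)s_in[l] * s_in[l] * in_channels[l] * B);
      ginp[l].resize(inp[l].size());
    }
  }
  fvecbuf hout((std::size_t)s_last * s_last * B);
  fvecbuf hcrop, ghcrop;

  NumericVector history(iters);
  int diverged_at = 0;

  for (int it = 0; it < iters; ++it) {
    // gather batch
    for (int i = 0; i < B; ++i) {
      const int idx = batch_idx(i, it) - 1;
      std::memcpy(&xb[(std::size_t)i * S0 * S0],
                  &xall[(std::size_t)idx * S0 * S0], sizeof(float) * S0 * S0);
      std::memcpy(&yb[(std::size_t)i * Klab * Klab],
                  &yall[(std::size_t)idx * Klab * Klab],
                  sizeof(float) * Klab * Klab);
    }
    // ---- forward ----
    for (int l = 0; l < L; ++l) {
      const float *src;
      if (l == 0) src = xb.data();
      else if (dense) {
        // concat: [input image, feats 0..l-1] cropped to s_in[l]
        int off = 0;
        crop_into(xb.data(), S0, 1, B, s_in[l], inp[l].data(),
                  in_channels[l], off);
        off += 1;
        for (int q = 0; q < l; ++q) {
          crop_into(feats[q].data(), s_out[q], channels[q], B, s_in[l],
                    inp[l].data(), in_channels[l], off);
          off += channels[q];
        }
        src = inp[l].data();
      } else src = feats[l - 1].data();
      const int H = s_in[l], OH = s_out[l], C = in_channels[l];
      const int kk = kernels[l], P = OH * OH, K = kk * kk * C;
      if (kk == 1) {
        // 1x1 convolution: direct per-sample GEMM, no lowering
        for (int n = 0; n < B; ++n) {
          arma::fmat Xn(const_cast<float *>(src) + (std::size_t)n * P * C,
                        P, C, false, true);
          arma::fmat Yn(feats[l].data() + (std::size_t)n * P * channels[l],
                        P, channels[l], false, true);
          Yn = Xn * par[l].Wf;
          Yn.each_row() += par[l].bf.t();
        }
      } else {
        const int chunk = chunk_size_f(B, P, K);
        arma::fmat Xc((std::size_t)chunk * P, K), Yt;
        for (int n0 = 0; n0 < B; n0 += chunk) {
          const int cnt = std::min(chunk, B - n0);
          arma::fmat Xv(Xc.memptr(), (std::size_t)cnt * P, K, false, true);
          im2col_f(src, H, H, C, n0, cnt, kk, kk, OH, OH, Xv);
          Yt = Xv * par[l].Wf;
          Yt.each_row() += par[l].bf.t();
          scatter_y_f(Yt, feats[l].data(), n0, cnt, P, channels[l]);
        }
      }
      if (relu[l]) {
        float *f = feats[l].data();
        const std::size_t sz = feats[l].size();
        for (std::size_t i = 0; i < sz; ++i) if (f[i] < 0.f) f[i] = 0.f;
      }
    }
    // ---- loss and output gradients ----
    // reduction 0: batch RMSE (self-normalizing gradient), 1: per-pixel
    // mean squared error, 2: per-patch squared-error sum averaged over the
    // batch.
    const std::size_t m_out = (std::size_t)s_last * s_last * B;
    double loss = 0;
    {
      float *o = feats[L - 1].data();
      float *g = gfeat[L - 1].data();
      double ss = 0;
      for (std::size_t i = 0; i < m_out; ++i) {
        const double d = (double)o[i] - (double)yb[i];
        ss += d * d;
        g[i] = (float)d;
      }
      double gs;
      if (reduction == 0) {
        loss = std::sqrt(ss / m_out);
        gs = 1.0 / (m_out * std::max(loss, 1e-12));
      } else if (reduction == 1) {
        loss = ss / m_out;
        gs = 2.0 / m_out;
      } else {
        loss = ss / B;
        gs = 2.0 / B;
      }
      for (std::size_t i = 0; i < m_out; ++i) g[i] *= (float)gs;
      // zero the other gradient accumulators
      for (int l = 0; l < L - 1; ++l)
        std::fill(gfeat[l].begin(), gfeat[l].end(), 0.f);
    }
    // heads: forward, companion loss, and gradient contributions
    for (int h = 0; h < n_heads; ++h) {
      const int st = head_stages[h] - 1;
      const int C = channels[st], P = s_last * s_last;
      hcrop.resize((std::size_t)P * C * B);
      ghcrop.assign((std::size_t)P * C * B, 0.f);
      crop_into(feats[st].data(), s_out[st], C, B, s_last, hcrop.data(), C, 0);
      hpar[h].gW = arma::zeros<arma::fmat>(C, 1);
      hpar[h].gb = arma::zeros<arma::fvec>(1);
      const double wgt = head_loss_w[h];
      hout.assign((std::size_t)P * B, 0.f);
      double ss = 0;
      for (int n = 0; n < B; ++n) {
        arma::fmat Xn(hcrop.data() + (std::size_t)n * P * C, P, C, false, true);
        arma::fvec on = Xn * hpar[h].Wf.col(0) + hpar[h].bf(0);
        const float *yn = &yb[(std::size_t)n * P];
        float *ho = &hout[(std::size_t)n * P];
        for (int i = 0; i < P; ++i) {
          const double d = (double)on(i) - (double)yn[i];
          ss += d * d;
          ho[i] = (float)d;
        }
      }
      double hl, gs;
      if (reduction == 0) {
        hl = std::sqrt(ss / m_out);
        gs = wgt / (m_out * std::max(hl, 1e-12));
      } else if (reduction == 1) {
        hl = ss / m_out;
        gs = wgt * 2.0 / m_out;
      } else {
        hl = ss / B;
        gs = wgt * 2.0 / B;
      }
      loss += wgt * hl;
      for (int n = 0; n < B; ++n) {
        arma::fmat Xn(hcrop.data() + (std::size_t)n * P * C, P, C, false, true);
        arma::fvec gh(P);
        const float *ho = &hout[(std::size_t)n * P];
        for (int i = 0; i < P; ++i) gh(i) = (float)(ho[i] * gs);
        hpar[h].gW += Xn.t() * gh;
        hpar[h].gb(0) += arma::accu(gh);
        arma::fmat Gn(ghcrop.data() + (std::size_t)n * P * C, P, C, false, true);
        Gn = gh * hpar[h].Wf.col(0).t();
      }
      uncrop_add(ghcrop.data(), s_last, C, 0, B, gfeat[st].data(),
                 s_out[st], C);
    }
    if (!std::isfinite(loss)) { diverged_at = it + 1; break; }
    history[it] = loss;
    // ---- backward ----
    for (int l = L - 1; l >= 0; --l) {
      float *g = gfeat[l].data();
      if (relu[l]) {
        const float *f = feats[l].data();
        const std::size_t sz = feats[l].size();
        for (std::size_t i = 0; i < sz; ++i) if (f[i] <= 0.f) g[i] = 0.f;
      }
      const float *src = (l == 0) ? xb.data()
        : (dense ? inp[l].data() : feats[l - 1].data());
      const int H = s_in[l], OH = s_out[l], C = in_channels[l];
      const int kk = kernels[l], P = OH * OH, K = kk * kk * C;
      const bool need_gx = l > 0;
      par[l].gW = arma::zeros<arma::fmat>(K, channels[l]);
      par[l].gb = arma::zeros<arma::fvec>(channels[l]);
      if (need_gx) std::fill(ginp[l].begin(), ginp[l].end(), 0.f);
      if (kk == 1) {
        for (int n = 0; n < B; ++n) {
          arma::fmat Xn(const_cast<float *>(src) + (std::size_t)n * P * C,
                        P, C, false, true);
          arma::fmat Gn(g + (std::size_t)n * P * channels[l], P, channels[l],
                        false, true);
          par[l].gW += Xn.t() * Gn;
          par[l].gb += arma::sum(Gn, 0).t();
          if (need_gx) {
            arma::fmat Gx(ginp[l].data() + (std::size_t)n * P * C, P, C,
                          false, true);
            Gx = Gn * par[l].Wf.t();
          }
        }
      } else {
        const int chunk = chunk_size_f(B, P, K);
        arma::fmat Xc((std::size_t)chunk * P, K), Gxc;
        arma::fmat Gt((std::size_t)chunk * P, channels[l]);
        if (need_gx) Gxc.set_size((std::size_t)chunk * P, K);
        for (int n0 = 0; n0 < B; n0 += chunk) {
          const int cnt = std::min(chunk, B - n0);
          arma::fmat Xv(Xc.memptr(), (std::size_t)cnt * P, K, false, true);
          im2col_f(src, H, H, C, n0, cnt, kk, kk, OH, OH, Xv);
          arma::fmat Gy(Gt.memptr(), (std::size_t)cnt * P, channels[l], false, true);
          gather_gy_f(g, Gy, n0, cnt, P, channels[l]);
          par[l].gW += Xv.t() * Gy;
          par[l].gb += arma::sum(Gy, 0).t();
          if (need_gx) {
            arma::fmat Gv(Gxc.memptr(), (std::size_t)cnt * P, K, false, true);
            Gv = Gy * par[l].Wf.t();
            col2im_f(Gv, ginp[l].data(), H, H, C, n0, cnt, kk, kk, OH, OH);
          }
        }
      }
      if (!need_gx) continue;
      if (dense) {
        // channel blocks: [input image (ignored), feats 0..l-1]
        int off = 1;
        for (int q = 0; q < l; ++q) {
          uncrop_add(ginp[l].data(), s_in[l], in_channels[l], off, B,
                     gfeat[q].data(), s_out[q], channels[q]);
          off += channels[q];
        }
      } else {
        float *dst = gfeat[l - 1].data();
        const float *sg = ginp[l].data();
        const std::size_t sz = gfeat[l - 1].size();
        for (std::size_t i = 0; i < sz; ++i) dst[i] += sg[i];
      }
    }
    if (diverged_at) break;
    // ---- SGD update ----
    for (int l = 0; l < L; ++l) par[l].step(lr, momentum);
    for (int h = 0; h < n_heads; ++h) hpar[h].step(lr, momentum);
  }

  // repackage weights and velocities
  List out_layers(L), out_vel_layers(L);
  for (int l = 0; l < L; ++l) {
    const int kk = kernels[l];
    NumericVector W(par[l].Wd.begin(), par[l].Wd.end());
    W.attr("dim") = IntegerVector::create(kk, kk, in_channels[l], channels[l]);
    NumericVector vW(par[l].vW.begin(), par[l].vW.end());
    vW.attr("dim") = W.attr("dim");
    out_layers[l] = List::create(_["W"] = W,
                                 _["b"] = NumericVector(par[l].bd.begin(),
                                                        par[l].bd.end()));
    out_vel_layers[l] = List::create(_["W"] = vW,
                                     _["b"] = NumericVector(par[l].vb.begin(),
                                                            par[l].vb.end()));
  }
  List out_heads(n_heads), out_vel_heads(n_heads);
  for (int h = 0; h < n_heads; ++h) {
    const int cin = channels[head_stages[h] - 1];
    NumericVector W(hpar[h].Wd.begin(), hpar[h].Wd.end());
    W.attr("dim") = IntegerVector::create(1, 1, cin, 1);
    NumericVector vW(hpar[h].vW.begin(), hpar[h].vW.end());
    vW.attr("dim") = W.attr("dim");
    out_heads[h] = List::create(_["W"] = W,
                                _["b"] = NumericVector(hpar[h].bd.begin(),
                                                       hpar[h].bd.end()));
    out_vel_heads[h] = List::create(_["W"] = vW,
                                    _["b"] = NumericVector(hpar[h].vb.begin(),
                                                           hpar[h].vb.end()));
  }
  return List::create(
    _["layers"] = out_layers, _["heads"] = out_heads,
    _["vel"] = List::create(_["layers"] = out_vel_layers,
                            _["heads"] = out_vel_heads),
    _["history"] = history, _["diverged_at"] = diverged_at);
}
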