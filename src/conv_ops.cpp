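// Convolution inner loops. Feature maps arrive as flat numeric vectors in
// [H, W, N, C] column-major layout (index h + w*H + n*H*W + c*H*W*N).
// im2col builds the patch matrix whose single BLAS product (done from R)
// realizes a stride-1 same-padding convolution; col2im scatter-adds the
// patch gradient back. The depthwise convolution and 2x2 max-pooling are
// plain loops.

#include <Rcpp.h>
using namespace Rcpp;

// patch matrix [H*W*N, k*k*C]; column blocks ordered di fastest, then dj,
// channels fastest inside a block (must match the weight reshape in R)
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int N, int C, int k) {
  const int pad = (k - 1) / 2, HW = H * W;
  const R_xlen_t HWN = (R_xlen_t)HW * N;
  NumericMatrix P(HWN, (R_xlen_t)k * k * C);
  const double* xp = x.begin();
  for (int dj = 0; dj < k; ++dj) {
    for (int di = 0; di < k; ++di) {
      const int a = di - pad, b = dj - pad, o = dj * k + di;
      const int h0 = std::max(0, -a), h1 = std::min(H, H - a);
      const int w0 = std::max(0, -b), w1 = std::min(W, W - b);
      if (h1 <= h0 || w1 <= w0) continue;
      for (int c = 0; c < C; ++c) {
        double* dst = &P(0, (R_xlen_t)(o * C + c));
        const double* src = xp + (R_xlen_t)c * HWN;
        for (int n = 0; n < N; ++n) {
          for (int w2 = w0; w2 < w1; ++w2) {
            const R_xlen_t doff = (R_xlen_t)h0 + (R_xlen_t)w2 * H +
                                  (R_xlen_t)n * HW;
            const R_xlen_t soff = (R_xlen_t)(h0 + a) +
                                  (R_xlen_t)(w2 + b) * H + (R_xlen_t)n * HW;
            std::copy(src + soff, src + soff + (h1 - h0), dst + doff);
          }
        }
      }
    }
  }
  return P;
}

// scatter-add the patch-matrix gradient back to input layout
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dP, int H, int W, int N, int C, int k) {
  const int pad = (k - 1) / 2, HW = H * W;
  const R_xlen_t HWN = (R_xlen_t)HW * N;
  NumericVector dx(HWN * (R_xlen_t)C);
  double* xp = dx.begin();
  for (int dj = 0; dj < k; ++dj) {
    for (int di = 0; di < k; ++di) {
      const int a = di - pad, b = dj - pad, o = dj * k + di;
      const int h0 = std::max(0, -a), h1 = std::min(H, H - a);
      const int w0 = std::max(0, -b), w1 = std::min(W, W - b);
      if (h1 <= h0 || w1 <= w0) continue;
      for (int c = 0; c < C; ++c) {
        const double* gsrc = &dP(0, (R_xlen_t)(o * C + c));
        double* gdst = xp + (R_xlen_t)c * HWN;
        for (int n = 0; n < N; ++n) {
          for (int w2 = w0; w2 < w1; ++w2) {
            const R_xlen_t doff = (R_xlen_t)h0 + (R_xlen_t)w2 * H +
                                  (R_xlen_t)n * HW;
            const R_xlen_t soff = (R_xlen_t)(h0 + a) +
                                  (R_xlen_t)(w2 + b) * H + (R_xlen_t)n * HW;
            for (int h = 0; h < h1 - h0; ++h) gdst[soff + h] += gsrc[doff + h];
          }
        }
      }
    }
  }
  return dx;
}

// depthwise convolution forward: one k x k kernel per channel,
// w laid out [k, k, C]
// [[Rcpp::export]]
NumericVector cpp_dwconv(NumericVector x, NumericVector w, int H, int W,
                         int N, int C, int k) {
  const int pad = (k - 1) / 2, HW = H * W;
  const R_xlen_t HWN = (R_xlen_t)HW * N;
  NumericVector y(HWN * (R_xlen_t)C);
  for (int c = 0; c < C; ++c) {
    const double* src = x.begin() + (R_xlen_t)c * HWN;
    double* dst = y.begin() + (R_xlen_t)c * HWN;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int a = di - pad, b = dj - pad;
        const double wv = w[di + dj * k + c * k * k];
        if (wv == 0) continue;
        const int h0 = std::max(0, -a), h1 = std::min(H, H - a);
        const int w0 = std::max(0, -b), w1 = std::min(W, W - b);
        for (int n = 0; n < N; ++n) {
          for (int w2 = w0; w2 < w1; ++w2) {
            const R_xlen_t doff = (R_xlen_t)h0 + (R_xlen_t)w2 * H +
                                  (R_xlen_t)n * HW;
            const R_xlen_t soff = (R_xlen_t)(h0 + a) +
                                  (R_xlen_t)(w2 + b) * H + (R_xlen_t)n * HW;
            for (int h = 0; h < h1 - h0; ++h)
              dst[doff + h] += wv * src[soff + h];
          }
        }
      }
    }
  }
  return y;
}

// depthwise backward: returns dx and dw given upstream gradient g
// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector x, NumericVector w, NumericVector g,
                    int H, int W, int N, int C, int k) {
  const int pad = (k - 1) / 2, HW = H * W;
  const R_xlen_t HWN = (R_xlen_t)HW * N;
  NumericVector dx(HWN * (R_xlen_t)C), dw((R_xlen_t)k * k * C);
  for (int c = 0; c < C; ++c) {
    const double* xs = x.begin() + (R_xlen_t)c * HWN;
    const double* gs = g.begin() + (R_xlen_t)c * HWN;
    double* dxs = dx.begin() + (R_xlen_t)c * HWN;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int a = di - pad, b = dj - pad;
        const double wv = w[di + dj * k + c * k * k];
        double acc = 0.0;
        const int h0 = std::max(0, -a), h1 = std::min(H, H - a);
        const int w0 = std::max(0, -b), w1 = std::min(W, W - b);
        for (int n = 0; n < N; ++n) {
          for (int w2 = w0; w2 < w1; ++w2) {
            const R_xlen_t doff = (R_xlen_t)h0 + (R_xlen_t)w2 * H +
                                  (R_xlen_t)n * HW;
            const R_xlen_t soff = (R_xlen_t)(h0 + a) +
                                  (R_xlen_t)(w2 + b) * H + (R_xlen_t)n * HW;
            for (int h = 0; h < h1 - h0; ++h) {
              acc += xs[soff + h] * gs[doff + h];
              dxs[soff + h] += wv * gs[doff + h];
            }
          }
        }
        dw[di + dj * k + c * k * k] = acc;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// 2x2 max pooling; returns pooled values and flat argmax indices (1-based
// into the input) for the backward pass
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x, int H, int W, int N, int C) {
  const int Ho = H / 2, Wo = W / 2, HW = H * W, HWo = Ho * Wo;
  const R_xlen_t n_out = (R_xlen_t)HWo * N * C;
  NumericVector y(n_out);
  IntegerVector idx(n_out);
  const double* xp = x.begin();
  R_xlen_t p = 0;
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const R_xlen_t base = ((R_xlen_t)c * N + n) * HW;
      for (int w2 = 0; w2 < Wo; ++w2) {
        for (int h = 0; h < Ho; ++h) {
          R_xlen_t i00 = base + (R_xlen_t)(2 * h) + (R_xlen_t)(2 * w2) * H;
          R_xlen_t best = i00;
          double bv = xp[i00];
          const R_xlen_t cand[3] = {i00 + 1, i00 + H, i00 + H + 1};
          for (int q = 0; q < 3; ++q) {
            if (xp[cand[q]] > bv) { bv = xp[cand[q]]; best = cand[q]; }
          }
          y[p] = bv;
          idx[p] = (int)(best + 1);
          ++p;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}
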